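#' Build a structure from an atom table
#'
#' Low-level constructor used by the readers and the synthetic generators.
#' The atom table follows PDB conventions: one row per atom, coordinates in
#' Angstrom, residue numbering verbatim (never renumbered).
#'
#' @param atom a data.frame with columns `eleno`, `elety`, `alt`, `resid`,
#'   `chain`, `resno`, `insert`, `x`, `y`, `z`, `o`, `b`, `elesy`, `type`
#'   (missing ones are filled with defaults)
#' @param source optional provenance string (file path or generator name)
#' @return an object of class `structure3d`
#' @export
structure3d <- function(atom, source = NA_character_) {
  defaults <- list(eleno = seq_len(nrow(atom)), elety = "C", alt = "",
                   resid = "UNK", chain = "A", resno = 1L, insert = "",
                   o = 1.00, b = 20.00, elesy = NA_character_, type = "ATOM")
  for (nm in names(defaults))
    if (is.null(atom[[nm]])) atom[[nm]] <- defaults[[nm]]
  for (nm in c("x", "y", "z"))
    if (is.null(atom[[nm]]) || any(!is.finite(atom[[nm]])))
      stop("atom table needs finite '", nm, "' coordinates")
  miss <- is.na(atom$elesy)
  atom$elesy[miss] <- toupper(substr(gsub("[0-9]", "", atom$elety[miss]), 1, 1))
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, atom$alt)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, insert, elety, alt) atom identity")
  rownames(atom) <- NULL
  structure(list(atom = atom, source = source), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  a <- x$atom
  cat(sprintf("Structure: %d atoms, %d residues, chains %s\n",
              nrow(a), length(unique(paste(a$chain, a$resno, a$insert))),
              paste(sort(unique(a$chain)), collapse = "")))
  if (!is.na(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

# coordinates of selected rows as an n x 3 matrix
.xyz <- function(struct, rows = seq_len(nrow(struct$atom))) {
  as.matrix(struct$atom[rows, c("x", "y", "z")])
}

#' Resolve an atom selector
#'
#' Selectors have the form `"chain:resnum[:icode]:atomname"`, e.g.
#' `"A:500:OH"` or `"A:52:A:CA"` for insertion code A.
#'
#' @param struct a [structure3d()]
#' @param selector selector string
#' @return integer row indices into `struct$atom`
#' @export
atom_select <- function(struct, selector) {
  stopifnot(inherits(struct, "structure3d"))
  parts <- strsplit(selector, ":", fixed = TRUE)[[1]]
  if (length(parts) == 3L) parts <- c(parts[1:2], "", parts[3])
  if (length(parts) != 4L)
    stop("selector must be 'chain:resnum[:icode]:atomname', got '", selector, "'")
  a <- struct$atom
  which(a$chain == parts[1] & a$resno == as.integer(parts[2]) &
        (a$insert %in% c(parts[3], if (parts[3] == "") NA)) &
        a$elety == parts[4])
}

.validate_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM/HETATM record at line ", i, ": fewer than 54 columns")
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(ln, fld[1], fld[2])))
      if (is.na(v))
        stop("malformed ATOM/HETATM record at line ", i,
             ": non-numeric coordinate field")
    }
  }
  invisible(TRUE)
}

#' Read a PDB structure
#'
#' Parses ATOM/HETATM/MODEL/TER records (via bio3d) into a [structure3d()].
#' Only the first model is kept; alternate locations are resolved to the
#' highest-occupancy conformer (ties broken alphabetically, so 'A' wins).
#' Other record types are ignored. Malformed ATOM records are rejected with
#' their line number.
#'
#' @param path PDB file
#' @param keep_altloc keep all alternate locations instead of resolving them
#' @return a [structure3d()]
#' @export
read_structure <- function(path, keep_altloc = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  .validate_pdb_lines(readLines(path, warn = FALSE))
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  a <- pdb$atom
  atom <- data.frame(
    eleno = a$eleno, elety = a$elety,
    alt = ifelse(is.na(a$alt), "", a$alt),
    resid = a$resid, chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno, insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, a$o), b = ifelse(is.na(a$b), 0, a$b),
    elesy = a$elesy, type = a$type,
    stringsAsFactors = FALSE)
  if (!keep_altloc && any(atom$alt != "")) {
    key <- paste(atom$chain, atom$resno, atom$insert, atom$elety)
    keep <- unlist(lapply(split(seq_len(nrow(atom)), key), function(rows) {
      if (length(rows) == 1L) return(rows)
      rows[order(-atom$o[rows], atom$alt[rows])][1]
    }), use.names = FALSE)
    atom <- atom[sort(keep), , drop = FALSE]
    atom$alt <- ""
  }
  structure3d(atom, source = path)
}

#' Write a structure in PDB format
#'
#' Deterministic fixed-width formatter (coordinates `%8.3f`, occupancy and
#' B-factor `%6.2f`); atoms are written in table order, with TER records at
#' chain breaks and a final END.
#'
#' @param struct a [structure3d()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_structure <- function(struct, path) {
  stopifnot(inherits(struct, "structure3d"))
  a <- struct$atom
  name4 <- ifelse(nchar(a$elety) >= 4, substr(a$elety, 1, 4),
                  sprintf(" %-3s", a$elety))
  lines <- sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   ifelse(a$type == "HETATM", "HETATM", "ATOM"),
                   a$eleno %% 100000L, name4, substr(a$alt, 1, 1), a$resid,
                   a$chain, a$resno, substr(a$insert, 1, 1),
                   a$x, a$y, a$z, a$o, a$b, a$elesy)
  brk <- which(diff(match(a$chain, unique(a$chain))) != 0)
  out <- character(0)
  prev <- 1L
  for (b in c(brk, nrow(a))) {
    out <- c(out, lines[prev:b], "TER")
    prev <- b + 1L
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}
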