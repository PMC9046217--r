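# Readers/writers for the interchange formats: multi-frame XYZ with an
# E=<value> (and optional s=<value>) token on each comment line, and scan
# curves as CSV with header x,energy[,spin_<fragment>...]. Writers use fixed
# float formatting (energies %.6f, coordinates %.3f) so output is
# byte-stable across runs.

.energy_factor <- function(units) {
  switch(tolower(units),
         "kcal/mol" = , "kcal" = 1,
         "kj/mol" = , "kj" = .KJ_KCAL,
         "hartree" = , "au" = .HARTREE_KCAL,
         stop("unknown energy units '", units,
              "' (use kcal/mol, kJ/mol or hartree)"))
}

#' Read a multi-frame XYZ reaction profile
#'
#' Each frame is `natoms` / comment / atom lines; the comment line must carry
#' an `E=<value>` token (energy in `units`) and may carry `s=<value>` (path
#' coordinate). Energies are converted to kcal/mol and re-zeroed to the
#' first frame.
#'
#' @param path XYZ file
#' @param units energy units in the file: `"kcal/mol"` (default),
#'   `"kJ/mol"`, or `"hartree"`
#' @param donor,h,acceptor optional 1-based atom indices of the transferring
#'   triad
#' @return a [reaction_profile()]
#' @export
read_profile <- function(path, units = "kcal/mol",
                         donor = NULL, h = NULL, acceptor = NULL) {
  fac <- .energy_factor(units)
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  energies <- numeric(); svals <- numeric(); frames <- list()
  elements <- NULL
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L)
      stop("expected an atom count at line ", i)
    frame <- frame + 1L
    comment <- lines[i + 1L]
    em <- regmatches(comment, regexec("E=([-+0-9.eE]+)", comment))[[1]]
    if (length(em) < 2L)
      stop("frame ", frame, ": comment line lacks an E=<value> token")
    energies[frame] <- as.numeric(em[2]) * fac
    sm <- regmatches(comment, regexec("s=([-+0-9.eE]+)", comment))[[1]]
    svals[frame] <- if (length(sm) >= 2L) as.numeric(sm[2]) else NA_real_
    at <- lines[(i + 2L):(i + 1L + nat)]
    tok <- strsplit(trimws(at), "[[:space:]]+")
    el <- vapply(tok, `[`, "", 1L)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      stop("frame ", frame, ": non-numeric coordinates")
    if (is.null(elements)) elements <- el
    else if (!identical(elements, el))
      stop("frame ", frame, ": element list differs from frame 1")
    frames[[frame]] <- xyz
    i <- i + 2L + nat
  }
  if (frame < 2L) stop("profile needs >= 2 frames")
  coords <- array(0, c(length(elements), 3, frame))
  for (k in seq_len(frame)) coords[, , k] <- frames[[k]]
  s <- if (all(is.finite(svals))) svals else seq_len(frame) - 1
  atom_map <- if (!is.null(donor))
    c(donor = as.integer(donor), h = as.integer(h),
      acceptor = as.integer(acceptor)) else NULL
  reaction_profile(energies, s = s, coords = coords, elements = elements,
                   atom_map = atom_map)
}

#' Write a reaction profile as multi-frame XYZ
#'
#' @param profile a [reaction_profile()] carrying geometries
#' @param path output file
#' @return `path`, invisibly
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "reaction_profile"))
  if (is.null(profile$coords)) stop("profile carries no geometries")
  nat <- dim(profile$coords)[1]
  out <- character(0)
  for (k in seq_along(profile$energy)) {
    out <- c(out,
             as.character(nat),
             sprintf("frame %d E=%.6f s=%.6f kcal/mol", k,
                     profile$energy[k], profile$s[k]),
             sprintf("%-2s %8.3f %8.3f %8.3f", profile$elements,
                     profile$coords[, 1, k], profile$coords[, 2, k],
                     profile$coords[, 3, k]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a scan curve from CSV
#'
#' Expects header `x,energy[,spin_<fragment>...]`; spin fragments are
#' registered in column order. A non-monotone `x` column is rejected.
#'
#' @param path CSV file
#' @param kind `"distance"` or `"dihedral"`
#' @param units energy units; default `"kcal/mol"`
#' @return a [scan_curve()]
#' @export
read_curve <- function(path, kind = c("distance", "dihedral"),
                       units = "kcal/mol") {
  kind <- match.arg(kind)
  fac <- .energy_factor(units)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("x", "energy") %in% names(df)))
    stop("CSV must have columns 'x' and 'energy'")
  spin_cols <- grep("^spin_", names(df), value = TRUE)
  spins <- if (length(spin_cols)) as.matrix(df[, spin_cols, drop = FALSE])
           else NULL
  scan_curve(df$x, df$energy * fac, spins = spins, kind = kind)
}

#' Write a scan curve as CSV
#'
#' @param curve a [scan_curve()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "scan_curve"))
  df <- data.frame(x = sprintf("%.6f", curve$x),
                   energy = sprintf("%.6f", curve$energy))
  if (!is.null(curve$spins))
    for (nm in colnames(curve$spins))
      df[[nm]] <- sprintf("%.6f", curve$spins[, nm])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
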