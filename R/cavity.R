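# Bondi van der Waals radii (Angstrom); unknown elements fall back to 1.70
.BONDI <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, FE = 2.00,
            F = 1.47, CL = 1.75, BR = 1.85, SE = 1.90, ZN = 1.39, H = 1.20)

.vdw_radius <- function(elesy, radii = .BONDI) {
  r <- radii[toupper(elesy)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# Multi-source BFS flood fill over a logical 3-D mask with 26-connectivity.
# 'open' is the accessibility array; 'seeds' are linear indices. Returns the
# logical array of voxels reachable from the seeds through open voxels.
.flood26 <- function(open, seeds) {
  dims <- dim(open)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  visited <- array(FALSE, dims)
  seeds <- seeds[open[seeds]]
  if (!length(seeds)) return(visited)
  visited[seeds] <- TRUE
  # frontier as 0-based coordinates for cheap neighbor arithmetic
  idx0 <- seeds - 1L
  fx <- idx0 %% nx
  fy <- (idx0 %/% nx) %% ny
  fz <- idx0 %/% (nx * ny)
  while (length(fx)) {
    nfx <- nfy <- nfz <- integer(0)
    for (k in seq_len(nrow(off))) {
      cx <- fx + off[k, 1]; cy <- fy + off[k, 2]; cz <- fz + off[k, 3]
      ok <- cx >= 0L & cx < nx & cy >= 0L & cy < ny & cz >= 0L & cz < nz
      if (!any(ok)) next
      lin <- cx[ok] + nx * (cy[ok] + ny * cz[ok]) + 1L
      new <- open[lin] & !visited[lin]
      if (!any(new)) next
      lin <- unique(lin[new])
      visited[lin] <- TRUE
      lin0 <- lin - 1L
      nfx <- c(nfx, lin0 %% nx)
      nfy <- c(nfy, (lin0 %/% nx) %% ny)
      nfz <- c(nfz, lin0 %/% (nx * ny))
    }
    if (!length(nfx)) break
    keep <- !duplicated(nfx + nx * (nfy + ny * nfz))
    fx <- nfx[keep]; fy <- nfy[keep]; fz <- nfz[keep]
  }
  visited
}

#' Grid-based cavity and channel map
#'
#' Marks a voxel as probe-accessible when its center lies at least
#' `vdW radius + probe` from every heavy-atom center, then separates
#' accessible space into connected components (26-connectivity). Components
#' reachable from the box boundary are surface-connected (bulk solvent and
#' any open channels); the rest are closed interior cavities. The grid box is
#' the structure's bounding box plus `probe + 2` Angstrom margin.
#'
#' @param struct a [structure3d()]
#' @param probe probe radius, Angstrom; default 1.0
#' @param spacing grid spacing, Angstrom; default 0.4 (must not exceed the
#'   probe radius)
#' @param exclude character vector of residues to strip before the
#'   calculation (ligand removal): residue names (`"TYR"`) or
#'   `"chain:resno"` selectors
#' @param radii named van der Waals radius table, Angstrom; default Bondi
#' @return an object of class `cavity_map`: `components` data.frame
#'   (`id`, `n_voxels`, `volume`, `surface_connected`, bounding box),
#'   `labels` (integer array, 0 = blocked), `origin`, `spacing`, `dims`,
#'   `probe`
#' @export
cavity_map <- function(struct, probe = 1.0, spacing = 0.4, exclude = NULL,
                       radii = .BONDI) {
  stopifnot(inherits(struct, "structure3d"))
  if (spacing > probe)
    stop("grid spacing ", spacing, " exceeds the probe radius ", probe,
         ": the probe would be undersampled")
  a <- struct$atom
  keep <- a$elesy != "H"
  if (!is.null(exclude)) {
    sel <- grepl(":", exclude, fixed = TRUE)
    if (any(!sel)) keep <- keep & !(a$resid %in% exclude[!sel])
    for (s in exclude[sel]) {
      p <- strsplit(s, ":", fixed = TRUE)[[1]]
      keep <- keep & !(a$chain == p[1] & a$resno == as.integer(p[2]))
    }
  }
  if (!any(keep)) stop("no heavy atoms left after exclusions")
  xyz <- .xyz(struct, which(keep))
  rad <- .vdw_radius(a$elesy[keep], radii) + probe
  margin <- probe + 2
  origin <- apply(xyz, 2, min) - margin
  span <- apply(xyz, 2, max) + margin - origin
  dims <- pmax(as.integer(ceiling(span / spacing)) + 1L, 2L)
  open <- array(TRUE, dims)
  # carve out the inflated atoms, one local sub-grid per atom
  for (i in seq_len(nrow(xyz))) {
    ctr <- (xyz[i, ] - origin) / spacing
    r <- rad[i] / spacing
    lo <- pmax(floor(ctr - r) + 1L, 1L)
    hi <- pmin(ceiling(ctr + r) + 1L, dims)
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    dx2 <- (ix - 1 - ctr[1])^2
    dy2 <- (iy - 1 - ctr[2])^2
    dz2 <- (iz - 1 - ctr[3])^2
    blk <- outer(outer(dx2, dy2, "+"), dz2, "+") < r^2
    open[ix, iy, iz] <- open[ix, iy, iz] & !blk
  }
  # exterior: everything reachable from the boundary faces
  bnd <- array(FALSE, dims)
  bnd[c(1, dims[1]), , ] <- TRUE
  bnd[, c(1, dims[2]), ] <- TRUE
  bnd[, , c(1, dims[3])] <- TRUE
  exterior <- .flood26(open, which(bnd))
  labels <- array(0L, dims)
  comp <- list()
  if (any(exterior)) {
    labels[exterior] <- 1L
    comp[[1]] <- list(vis = exterior, surface = TRUE)
  }
  remaining <- open & labels == 0L
  while (any(remaining)) {
    seed <- which(remaining)[1]
    vis <- .flood26(remaining, seed)
    id <- length(comp) + 1L
    labels[vis] <- id
    comp[[id]] <- list(vis = vis, surface = FALSE)
    remaining <- remaining & !vis
  }
  comps <- do.call(rbind, lapply(seq_along(comp), function(id) {
    w <- which(comp[[id]]$vis, arr.ind = TRUE)
    data.frame(id = id, n_voxels = nrow(w),
               volume = nrow(w) * spacing^3,
               surface_connected = comp[[id]]$surface,
               xmin = origin[1] + (min(w[, 1]) - 1) * spacing,
               xmax = origin[1] + (max(w[, 1]) - 1) * spacing,
               ymin = origin[2] + (min(w[, 2]) - 1) * spacing,
               ymax = origin[2] + (max(w[, 2]) - 1) * spacing,
               zmin = origin[3] + (min(w[, 3]) - 1) * spacing,
               zmax = origin[3] + (max(w[, 3]) - 1) * spacing)
  }))
  if (is.null(comps))
    comps <- data.frame(id = integer(), n_voxels = integer(),
                        volume = numeric(), surface_connected = logical())
  # closed cavities sorted by volume (descending), exterior kept first
  if (nrow(comps) > 1L) {
    closed <- comps[!comps$surface_connected, , drop = FALSE]
    closed <- closed[order(-closed$volume), , drop = FALSE]
    surf <- comps[comps$surface_connected, , drop = FALSE]
    relabel <- rbind(surf, closed)
    newlab <- array(0L, dims)
    for (k in seq_len(nrow(relabel))) newlab[labels == relabel$id[k]] <- k
    relabel$id <- seq_len(nrow(relabel))
    labels <- newlab
    comps <- relabel
    rownames(comps) <- NULL
  }
  structure(list(components = comps, labels = labels, origin = origin,
                 spacing = spacing, dims = dims, probe = probe),
            class = "cavity_map")
}

#' @export
print.cavity_map <- function(x, ...) {
  closed <- x$components[!x$components$surface_connected, , drop = FALSE]
  cat(sprintf("Cavity map: probe %.2f A, spacing %.2f A, grid %s\n",
              x$probe, x$spacing, paste(x$dims, collapse = " x ")))
  cat(sprintf("  %d closed cavit%s (total %.1f A^3), %d surface-connected region%s\n",
              nrow(closed), if (nrow(closed) == 1) "y" else "ies",
              sum(closed$volume),
              sum(x$components$surface_connected),
              if (sum(x$components$surface_connected) == 1) "" else "s"))
  invisible(x)
}

# Cartesian centers of a component's voxels
.component_voxels <- function(map, component) {
  w <- which(map$labels == component, arr.ind = TRUE)
  if (!nrow(w)) stop("no component with id ", component)
  sweep((w - 1) * map$spacing, 2, map$origin, "+")
}

#' Residues lining a cavity component
#'
#' Residues owning at least one heavy atom within `shell` of any voxel of the
#' component, sorted by their minimal atom-to-component distance.
#'
#' @param map a [cavity_map()]
#' @param struct the [structure3d()] the map was computed from
#' @param component component id (see `map$components`)
#' @param shell lining shell thickness, Angstrom; default 4.5
#' @return a data.frame with `chain`, `resno`, `resid`, `min_distance`
#' @export
lining_residues <- function(map, struct, component, shell = 4.5) {
  stopifnot(inherits(map, "cavity_map"), inherits(struct, "structure3d"))
  vox <- .component_voxels(map, component)
  a <- struct$atom
  heavy <- which(a$elesy != "H")
  dmin <- vapply(heavy, function(i) {
    d2 <- (vox[, 1] - a$x[i])^2 + (vox[, 2] - a$y[i])^2 + (vox[, 3] - a$z[i])^2
    sqrt(min(d2))
  }, 0)
  hit <- dmin <= shell
  if (!any(hit))
    return(data.frame(chain = character(), resno = integer(),
                      resid = character(), min_distance = numeric()))
  df <- data.frame(chain = a$chain[heavy][hit], resno = a$resno[heavy][hit],
                   resid = a$resid[heavy][hit], min_distance = dmin[hit],
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(min_distance ~ chain + resno + resid, df, min)
  agg[order(agg$min_distance), , drop = FALSE]
}

#' Write a cavity map as an OpenDX scalar field
#'
#' Regular-grid OpenDX text format readable by the usual molecular viewers;
#' values are the component labels (0 = blocked/inaccessible).
#'
#' @param map a [cavity_map()]
#' @param path output file
#' @param what `"labels"` (default) or `"interior"` (closed cavities as 1/0)
#' @return `path`, invisibly
#' @export
write_dx <- function(map, path, what = c("labels", "interior")) {
  what <- match.arg(what)
  d <- map$dims
  vals <- if (what == "labels") as.numeric(map$labels) else {
    closed <- map$components$id[!map$components$surface_connected]
    as.numeric(map$labels %in% closed)
  }
  # OpenDX expects the z index fastest; R arrays are x fastest
  vals <- as.numeric(aperm(array(vals, d), c(3, 2, 1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", map$origin[1], map$origin[2], map$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", map$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", map$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", map$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(vals))), con)
  n3 <- length(vals) - length(vals) %% 3
  if (n3 > 0) {
    m <- matrix(vals[seq_len(n3)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.1f %.1f %.1f", m[, 1], m[, 2], m[, 3]), con)
  }
  if (n3 < length(vals))
    writeLines(paste(sprintf("%.1f", vals[(n3 + 1):length(vals)]),
                     collapse = " "), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Export a cavity component as pseudo-atoms
#'
#' One HETATM pseudo-atom per voxel (occupancy 1.00), for quick visual
#' inspection in a molecular viewer; write with [write_structure()].
#'
#' @param map a [cavity_map()]
#' @param component component id
#' @return a [structure3d()] of `DUM` pseudo-atoms
#' @export
voxels_as_structure <- function(map, component) {
  vox <- .component_voxels(map, component)
  n <- nrow(vox)
  structure3d(data.frame(
    eleno = seq_len(n), elety = "DU", alt = "", resid = "DUM",
    chain = "V", resno = ((seq_len(n) - 1L) %% 9999L) + 1L, insert = "",
    x = vox[, 1], y = vox[, 2], z = vox[, 3],
    o = 1.00, b = 0.00, elesy = "X", type = "HETATM",
    stringsAsFactors = FALSE), source = "cavity_map")
}
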