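# Seeded generators for every input class the pipeline consumes. Each is a
# pure function of its parameters and seed (the caller's RNG state is saved
# and restored), and each attaches a machine-readable ground-truth record as
# attribute "ground_truth" (also written as a JSON sidecar when files are
# requested).

.write_ground_truth <- function(obj, path) {
  gt <- attr(obj, "ground_truth")
  jsonlite::write_json(gt, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(obj)
}

#' Synthetic intrinsic-reaction-coordinate profile
#'
#' Energies are sampled from the asymmetric Eckart curve (barrier top at
#' s = 0) plus optional Gaussian noise; geometries hold a donor-H-acceptor
#' triad in which the hydrogen moves `h_displacement` net across the 5-frame
#' window centered on the transition state (it is stationary outside that
#' window), emulating the short transfer distances of a tightly caged
#' hydrogen abstraction.
#'
#' @param V_forward,V_reverse barrier heights, kcal/mol
#' @param L Eckart characteristic width, Angstrom
#' @param h_displacement net hydrogen displacement across the TS window,
#'   Angstrom
#' @param n_frames odd frame count >= 9; default 21
#' @param noise energy noise s.d., kcal/mol; default 0
#' @param seed RNG seed
#' @param path if given, write a multi-frame XYZ file (plus a
#'   `.truth.json` sidecar) there
#' @return a [reaction_profile()] with attribute `ground_truth`
#' @export
make_irc <- function(V_forward = 20, V_reverse = V_forward, L = 0.15,
                     h_displacement = 0.45, n_frames = 21L, noise = 0,
                     seed = 1L, path = NULL) {
  if (n_frames < 9L || n_frames %% 2L == 0L)
    stop("'n_frames' must be odd and >= 9")
  if (any(c(V_forward, V_reverse, L) <= 0) || noise < 0 || h_displacement < 0)
    stop("invalid generator parameters")
  .with_seed(seed, {
    s <- seq(-8 * L, 8 * L, length.out = n_frames)
    e <- .eckart_curve(s, V_forward, V_reverse, L, s0 = 0)
    if (noise > 0) e <- e + stats::rnorm(n_frames, 0, noise)
    ts <- which.min(abs(s))
    # donor N at origin, acceptor C5' 2.8 A away along x; H migrates along x
    z_h <- rep(1.00, n_frames)
    win <- (ts - 2L):(ts + 2L)
    z_h[win] <- 1.00 + h_displacement * seq(0, 1, length.out = 5L)
    z_h[(ts + 3L):n_frames] <- 1.00 + h_displacement
    elements <- c("N", "H", "C", "C", "O")
    coords <- array(0, c(5, 3, n_frames))
    for (i in seq_len(n_frames)) {
      coords[, , i] <- rbind(c(0, 0, 0),
                             c(z_h[i], 0, 0),
                             c(2.80, 0, 0),
                             c(-1.45, 0.55, 0),   # spectator Calpha
                             c(3.60, 1.10, 0))    # spectator ribose O
    }
    prof <- reaction_profile(e, s = s, coords = coords, elements = elements,
                             atom_map = c(donor = 1L, h = 2L, acceptor = 3L))
    attr(prof, "ground_truth") <- list(
      kind = "irc", V_forward = V_forward, V_reverse = V_reverse, L = L,
      h_displacement = h_displacement, n_frames = n_frames, noise = noise,
      seed = seed, ts_index = ts)
    if (!is.null(path)) {
      write_profile(prof, path)
      .write_ground_truth(prof, path)
    }
    prof
  })
}

#' Synthetic bond-scission distance scan
#'
#' A carbon-carbon distance scan with a prescribed energy minimum (shape
#' `"well"`: the energy turns back up past the minimum, the incomplete-
#' scission signature) or monotonically downhill (shape `"monotone"`, the
#' completed-scission signature), with two fragment spin-population columns
#' summing to one: the leaving-group spin ramps linearly to `endpoint_spin`
#' at the last point.
#'
#' @param minimum_x position of the energy minimum, Angstrom (well shape)
#' @param depth energy drop from the first point to the minimum, kcal/mol
#' @param endpoint_spin leaving-fragment spin population at the endpoint;
#'   `NULL` omits the spin columns
#' @param shape `"well"` or `"monotone"`
#' @param x_range,step scanned range and step, Angstrom
#' @param noise energy noise s.d., kcal/mol
#' @param seed RNG seed
#' @param path if given, write a CSV (plus `.truth.json` sidecar) there
#' @return a [scan_curve()] with attribute `ground_truth`
#' @export
make_scan <- function(minimum_x = 2.70, depth = 4, endpoint_spin = 0.55,
                      shape = c("well", "monotone"),
                      x_range = c(2.2, 3.4), step = 0.05,
                      noise = 0, seed = 1L, path = NULL) {
  shape <- match.arg(shape)
  if (shape == "well" &&
      (minimum_x <= x_range[1] || minimum_x >= x_range[2]))
    stop("'minimum_x' must lie inside 'x_range'")
  .with_seed(seed, {
    x <- seq(x_range[1], x_range[2], by = step)
    e <- if (shape == "well") {
      depth / (minimum_x - x_range[1])^2 * (x - minimum_x)^2
    } else {
      -depth * (x - x_range[1]) / diff(x_range)
    }
    if (noise > 0) e <- e + stats::rnorm(length(x), 0, noise)
    spins <- NULL
    if (!is.null(endpoint_spin)) {
      leav <- 0.5 + (endpoint_spin - 0.5) * (x - x_range[1]) / diff(x_range)
      spins <- cbind(spin_leaving = leav, spin_remaining = 1 - leav)
    }
    cv <- scan_curve(x, e, spins = spins, kind = "distance")
    attr(cv, "ground_truth") <- list(
      kind = "scan", minimum_x = if (shape == "well") minimum_x else x_range[2],
      depth = depth, endpoint_spin = endpoint_spin, shape = shape,
      noise = noise, seed = seed)
    if (!is.null(path)) {
      write_curve(cv, path)
      .write_ground_truth(cv, path)
    }
    cv
  })
}

#' Synthetic dihedral scan with prescribed wells
#'
#' Periodic (degree) scan built as a sum of wrapped Gaussian wells; emulates
#' the amino-group rotation scans whose minima select the productive
#' substrate orientation.
#'
#' @param wells well centers, degrees in (-180, 180]
#' @param depths well depths, kcal/mol (recycled)
#' @param width Gaussian width, degrees
#' @param step grid step, degrees
#' @param noise energy noise s.d., kcal/mol
#' @param seed RNG seed
#' @param path if given, write a CSV (plus `.truth.json` sidecar) there
#' @return a [scan_curve()] of kind `"dihedral"` with attribute `ground_truth`
#' @export
make_dihedral_scan <- function(wells = c(-48, 55), depths = c(6, 3.5),
                               width = 25, step = 5, noise = 0, seed = 1L,
                               path = NULL) {
  depths <- rep_len(depths, length(wells))
  .with_seed(seed, {
    x <- seq(-180, 180 - step, by = step)
    e <- rep(0, length(x))
    for (i in seq_along(wells))
      e <- e - depths[i] * exp(-0.5 * (.angdiff(x, wells[i]) / width)^2)
    e <- e - min(e)
    if (noise > 0) e <- e + stats::rnorm(length(x), 0, noise)
    cv <- scan_curve(x, e, kind = "dihedral")
    attr(cv, "ground_truth") <- list(
      kind = "dihedral-scan", wells = wells, depths = depths, width = width,
      global_well = wells[which.max(depths)], noise = noise, seed = seed)
    if (!is.null(path)) {
      write_curve(cv, path)
      .write_ground_truth(cv, path)
    }
    cv
  })
}

#' Synthetic anion-binding site with square-pyramidal donors
#'
#' A phenolate-like target oxygen at the origin with `n_basal` hydroxyl/amide
#' donors at ideal square-pyramidal positions (basal donors 90 degrees apart
#' in the equatorial plane, optional apical donor on the axis), plus optional
#' isotropic Gaussian jitter on the donor positions. The target's own
#' residue carries two ring-carbon atoms so the same-residue exclusion of
#' [contact_census()] is exercised.
#'
#' @param n_basal basal donor count (0-4)
#' @param basal_distance target-donor distance, Angstrom
#' @param apical add an apical donor; default TRUE
#' @param jitter donor-coordinate noise s.d., Angstrom
#' @param seed RNG seed
#' @param path if given, write a PDB (plus `.truth.json` sidecar) there
#' @return a [structure3d()] with attribute `ground_truth`
#' @export
make_site <- function(n_basal = 4L, basal_distance = 2.8, apical = TRUE,
                      jitter = 0, seed = 1L, path = NULL) {
  if (n_basal < 0L || n_basal > 4L) stop("'n_basal' must be 0..4")
  .with_seed(seed, {
    d <- basal_distance
    basal <- rbind(c(d, 0, 0), c(0, d, 0), c(-d, 0, 0), c(0, -d, 0))
    rows <- list(
      data.frame(elety = "O1", resid = "PHO", resno = 500L,
                 x = 0, y = 0, z = 0, elesy = "O", type = "HETATM"),
      data.frame(elety = c("C1", "C2"), resid = "PHO", resno = 500L,
                 x = c(0.7, -0.7), y = c(1.2, 1.2), z = c(-0.4, -0.4),
                 elesy = "C", type = "HETATM"))
    donors <- list()
    if (n_basal >= 1L) {
      nm <- c("OG", "OG", "OG", "N")[seq_len(n_basal)]
      rs <- c("SER", "SER", "SER", "THR")[seq_len(n_basal)]
      for (i in seq_len(n_basal)) {
        p <- basal[i, ] + if (jitter > 0) stats::rnorm(3, 0, jitter) else 0
        donors[[length(donors) + 1L]] <- data.frame(
          elety = nm[i], resid = rs[i], resno = 300L + i,
          x = p[1], y = p[2], z = p[3],
          elesy = substr(nm[i], 1, 1), type = "ATOM")
      }
    }
    if (apical) {
      p <- c(0, 0, basal_distance) + if (jitter > 0) stats::rnorm(3, 0, jitter) else 0
      donors[[length(donors) + 1L]] <- data.frame(
        elety = "OG1", resid = "THR", resno = 310L,
        x = p[1], y = p[2], z = p[3], elesy = "O", type = "ATOM")
    }
    # a distant spectator residue outside any sane cutoff
    far <- data.frame(elety = c("N", "CA"), resid = "GLY", resno = 350L,
                      x = c(9, 10.2), y = 9, z = 9,
                      elesy = c("N", "C"), type = "ATOM")
    atom <- do.call(rbind, c(rows, donors, list(far)))
    atom$chain <- "A"; atom$alt <- ""; atom$insert <- ""
    atom$o <- 1.00; atom$b <- 20.00
    atom$eleno <- seq_len(nrow(atom))
    st <- structure3d(atom, source = "make_site")
    attr(st, "ground_truth") <- list(
      kind = "site", n_basal = n_basal, basal_distance = basal_distance,
      apical = apical, jitter = jitter, seed = seed,
      n_contacts = n_basal + as.integer(apical),
      target = "A:500:O1")
    if (!is.null(path)) {
      write_structure(st, path)
      .write_ground_truth(st, path)
    }
    st
  })
}

# deterministic helical poly-ALA backbone with one SER; chi1 set exactly
.helix_chain <- function(n_res, ser_at, chi1) {
  per <- 100 * pi / 180
  rot_z <- function(v, th) c(cos(th) * v[1] - sin(th) * v[2],
                             sin(th) * v[1] + cos(th) * v[2], v[3])
  atoms <- list()
  eleno <- 0L
  for (i in seq_len(n_res)) {
    th <- per * i
    ca <- c(2.3 * cos(th), 2.3 * sin(th), 1.5 * i)
    nn <- ca + rot_z(c(1.45, 0, 0), th)
    cb <- ca + rot_z(1.53 * c(cos(110 * pi / 180), sin(110 * pi / 180), 0), th)
    cc <- ca + rot_z(c(-0.55, -0.75, 1.2), th)
    oo <- cc + c(0, 0, 1.23)
    resid <- if (i == ser_at) "SER" else "ALA"
    add <- function(elety, p, elesy)
      atoms[[length(atoms) + 1L]] <<- data.frame(
        elety = elety, resid = resid, resno = i,
        x = p[1], y = p[2], z = p[3], elesy = elesy, type = "ATOM")
    add("N", nn, "N"); add("CA", ca, "C"); add("C", cc, "C")
    add("O", oo, "O"); add("CB", cb, "C")
    if (i == ser_at)
      add("OG", .place_dihedral(nn, ca, cb, 1.42, 110, chi1), "O")
  }
  atom <- do.call(rbind, atoms)
  atom$chain <- "A"; atom$alt <- ""; atom$insert <- ""
  atom$o <- 1.00; atom$b <- 20.00
  atom$eleno <- seq_len(nrow(atom))
  atom
}

# rotation matrix about a unit axis by angle (degrees)
.axis_rotation <- function(axis, angle) {
  u <- axis / .vnorm(axis)
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * tcrossprod(u)
}

#' Synthetic pair of structures related by a rigid motion and a chi1 flip
#'
#' A deterministic helical poly-alanine chain with one serine whose chi1 is
#' set exactly; the second copy gets the other chi1, a rigid
#' rotation/translation, and optional isotropic Gaussian coordinate noise.
#' Emulates a liganded/unliganded structure pair whose only conformational
#' difference is one side-chain rotation.
#'
#' @param n_res residue count; default 30
#' @param rotation rigid rotation applied to copy B, degrees
#' @param axis rotation axis (unnormalized)
#' @param translation translation applied to copy B, Angstrom
#' @param noise coordinate noise s.d. on copy B, Angstrom
#' @param chi1_pair serine chi1 in copies A and B, degrees
#' @param seed RNG seed
#' @param path if given, write `<path>_a.pdb` / `<path>_b.pdb` and a
#'   `.truth.json` sidecar
#' @return list with `a`, `b` ([structure3d()]) and `ground_truth`
#' @export
make_structure_pair <- function(n_res = 30L, rotation = 37,
                                axis = c(1, 2, 0.5),
                                translation = c(5, -3, 2), noise = 0,
                                chi1_pair = c(-60, 50), seed = 1L,
                                path = NULL) {
  .with_seed(seed, {
    ser_at <- max(2L, n_res %/% 2L)
    atom_a <- .helix_chain(n_res, ser_at, chi1_pair[1])
    atom_b <- .helix_chain(n_res, ser_at, chi1_pair[2])
    R <- .axis_rotation(axis, rotation)
    xyz <- as.matrix(atom_b[, c("x", "y", "z")]) %*% t(R)
    xyz <- sweep(xyz, 2, translation, "+")
    if (noise > 0) xyz <- xyz + stats::rnorm(length(xyz), 0, noise)
    atom_b[, c("x", "y", "z")] <- xyz
    a <- structure3d(atom_a, source = "make_structure_pair:a")
    b <- structure3d(atom_b, source = "make_structure_pair:b")
    dchi <- abs(chi1_pair[1] - chi1_pair[2]) %% 360
    gt <- list(kind = "structure-pair", n_res = n_res, rotation = rotation,
               translation = translation, noise = noise,
               chi1_pair = chi1_pair,
               chi1_delta = if (dchi > 180) 360 - dchi else dchi,
               ser_resno = ser_at, seed = seed)
    out <- list(a = a, b = b, ground_truth = gt)
    if (!is.null(path)) {
      write_structure(a, paste0(path, "_a.pdb"))
      write_structure(b, paste0(path, "_b.pdb"))
      jsonlite::write_json(gt, paste0(path, ".truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    out
  })
}

#' Synthetic hollow shell, optionally pierced by a channel
#'
#' Carbon atoms on a Fibonacci sphere of radius `shell_radius` enclose a
#' void; the probe-accessible void radius is analytically
#' `shell_radius - r_vdW - probe`. With `channel_width` set, a tube of atoms
#' (bore diameter `channel_width` between atom surfaces) connects the void to
#' the exterior, turning the closed cavity into a surface-connected channel
#' for probes small enough to pass. Tube atoms carry residue `GAT` (numbers
#' 901/902) so channel-lining queries have marked gate residues; shell atoms
#' are residue `SHL`.
#'
#' @param shell_radius sphere radius (atom centers), Angstrom
#' @param channel_width bore diameter of the exit tube between atom
#'   surfaces, Angstrom; `NULL` for a closed shell
#' @param atom_spacing approximate atom-center spacing on the shell, Angstrom
#' @param seed RNG seed (kept for interface uniformity; the geometry is
#'   deterministic)
#' @param path if given, write a PDB (plus `.truth.json` sidecar) there
#' @return a [structure3d()] with attribute `ground_truth`
#' @export
make_hollow_structure <- function(shell_radius = 8, channel_width = NULL,
                                  atom_spacing = 1.1, seed = 1L,
                                  path = NULL) {
  r_vdw <- .BONDI[["C"]]
  n <- ceiling(4 * pi * shell_radius^2 / atom_spacing^2)
  i <- seq_len(n) - 0.5
  ga <- pi * (3 - sqrt(5))                      # golden angle
  z <- 1 - 2 * i / n
  rr <- sqrt(pmax(1 - z^2, 0))
  pts <- shell_radius * cbind(rr * cos(ga * i), rr * sin(ga * i), z)
  res <- data.frame(resid = "SHL", resno = 1L)
  atom <- data.frame(elety = "C", resid = "SHL", resno = 1L,
                     x = pts[, 1], y = pts[, 2], z = pts[, 3],
                     elesy = "C", type = "HETATM")
  tube_r <- NULL
  if (!is.null(channel_width)) {
    tube_r <- channel_width / 2 + r_vdw       # atom-center radius of the bore
    ax_d <- sqrt(atom$x^2 + atom$y^2)
    keep <- !(ax_d < tube_r & atom$z > 0)
    atom <- atom[keep, , drop = FALSE]
    z0 <- sqrt(max(shell_radius^2 - tube_r^2, 0)) - 0.6
    zs <- seq(z0, shell_radius + 4, by = atom_spacing * 0.8)
    nring <- max(ceiling(2 * pi * tube_r / (atom_spacing * 0.8)), 6)
    th <- seq(0, 2 * pi, length.out = nring + 1)[-1]
    ring <- do.call(rbind, lapply(seq_along(zs), function(k) {
      data.frame(elety = "C", resid = "GAT",
                 resno = 901L + (k %% 2L),
                 x = tube_r * cos(th), y = tube_r * sin(th), z = zs[k],
                 elesy = "C", type = "HETATM")
    }))
    atom <- rbind(atom, ring)
  }
  atom$chain <- "A"; atom$alt <- ""; atom$insert <- ""
  atom$o <- 1.00; atom$b <- 20.00
  atom$eleno <- seq_len(nrow(atom))
  # identity uniqueness needs distinct atom names within a residue
  atom$elety <- sprintf("C%d", stats::ave(seq_len(nrow(atom)),
                                          paste(atom$resid, atom$resno),
                                          FUN = seq_along))
  st <- structure3d(atom, source = "make_hollow_structure")
  attr(st, "ground_truth") <- list(
    kind = "hollow-structure", shell_radius = shell_radius,
    channel_width = channel_width, r_vdw = r_vdw,
    tube_center_radius = tube_r,
    void_radius_at_probe = paste0("shell_radius - ", r_vdw, " - probe"),
    seed = seed)
  if (!is.null(path)) {
    write_structure(st, path)
    .write_ground_truth(st, path)
  }
  st
}
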