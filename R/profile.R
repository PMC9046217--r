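#' Construct a reaction profile
#'
#' An ordered set of frames along a reaction path: per-frame energies
#' (re-zeroed to the first frame), an optional path coordinate, optional
#' per-frame Cartesian geometries, and the named atoms of the transferring
#' triad. This is the container consumed by [detect_stationary_points()],
#' [transfer_distance()] and [fit_eckart()].
#'
#' @param energy per-frame energies, kcal/mol
#' @param s path coordinate, strictly increasing; default frame index 0,1,...
#' @param coords `natom x 3 x nframe` array of positions (Angstrom), or NULL
#' @param elements per-atom element symbols (length natom), or NULL
#' @param atom_map named integer vector with entries `donor`, `h`, `acceptor`
#'   (1-based atom indices), or NULL
#' @return an object of class `reaction_profile`
#' @export
reaction_profile <- function(energy, s = seq_along(energy) - 1,
                             coords = NULL, elements = NULL,
                             atom_map = NULL) {
  if (!is.numeric(energy) || length(energy) < 2L || any(!is.finite(energy)))
    stop("'energy' must be finite numeric with >= 2 frames")
  if (length(s) != length(energy) || any(diff(s) <= 0))
    stop("'s' must be strictly increasing and match the frame count")
  if (!is.null(coords)) {
    if (length(dim(coords)) != 3L || dim(coords)[2] != 3L ||
        dim(coords)[3] != length(energy))
      stop("'coords' must be a natom x 3 x nframe array")
    if (is.null(elements) || length(elements) != dim(coords)[1])
      stop("'elements' must name every atom of 'coords'")
    if (any(!is.finite(coords))) stop("non-finite coordinates")
  }
  if (!is.null(atom_map)) {
    need <- c("donor", "h", "acceptor")
    if (!all(need %in% names(atom_map)))
      stop("'atom_map' needs named entries donor, h, acceptor")
    atom_map <- vapply(atom_map[need], as.integer, 0L)
  }
  structure(list(energy = energy - energy[1], s = as.numeric(s),
                 coords = coords, elements = elements, atom_map = atom_map,
                 roles = NULL),
            class = "reaction_profile")
}

#' @export
print.reaction_profile <- function(x, ...) {
  cat(sprintf("Reaction profile: %d frames, energy span %.3f kcal/mol\n",
              length(x$energy), diff(range(x$energy))))
  if (!is.null(x$coords))
    cat(sprintf("  %d atoms per frame (%s)\n", dim(x$coords)[1],
                paste(utils::head(x$elements, 8), collapse = " ")))
  if (!is.null(x$roles))
    cat(sprintf("  roles: reactant %d, TS %d, product %d\n",
                x$roles["reactant"], x$roles["ts"], x$roles["product"]))
  invisible(x)
}

#' Locate reactant, transition state and product on a profile
#'
#' The transition state is the interior global energy maximum; reactant and
#' product are the minima of the two branches on either side of it. Forward
#' and reverse barriers are the TS energy minus each minimum. Ties on the
#' maximum are broken toward the lower index and flagged.
#'
#' @param profile a [reaction_profile()] or a bare numeric energy vector
#' @return a list with `reactant`, `ts`, `product` (frame indices),
#'   `forward_barrier`, `reverse_barrier` (kcal/mol) and `tie` (logical)
#' @export
detect_stationary_points <- function(profile) {
  e <- if (inherits(profile, "reaction_profile")) profile$energy else profile
  n <- length(e)
  if (n < 5L) stop("need >= 5 frames")
  ts <- which.max(e)   # first index on ties (lower index)
  tie <- sum(e == e[ts]) > 1L
  if (ts == 1L || ts == n)
    stop("no interior barrier: the energy maximum is at a terminus")
  reactant <- which.min(e[1:(ts - 1L)])
  product <- ts + which.min(e[(ts + 1L):n])
  list(reactant = reactant, ts = ts, product = product,
       forward_barrier = e[ts] - e[reactant],
       reverse_barrier = e[ts] - e[product],
       tie = tie)
}

#' Net displacement of the migrating hydrogen across the TS window
#'
#' Euclidean displacement of the transferring hydrogen between the first and
#' last frame of an odd window centered on the transition state -- the
#' operational "transfer distance" of a hydrogen-abstraction path sampled as
#' discrete frames. Donor-H and acceptor-H distances at every window frame
#' are reported alongside so alternative definitions can be audited.
#'
#' @param profile a [reaction_profile()] with coords and atom_map
#' @param window odd window size in frames, default 5
#' @return a list with `distance` (Angstrom), `window` (frame indices used),
#'   and `dh_distances` (window x 2 matrix of donor-H / acceptor-H distances)
#' @export
transfer_distance <- function(profile, window = 5L) {
  stopifnot(inherits(profile, "reaction_profile"))
  if (is.null(profile$coords) || is.null(profile$atom_map))
    stop("profile carries no geometry or no donor/h/acceptor map")
  if (window %% 2L != 1L) stop("'window' must be odd")
  ts <- detect_stationary_points(profile)$ts
  half <- (window - 1L) %/% 2L
  n <- dim(profile$coords)[3]
  if (ts - half < 1L || ts + half > n) {
    half <- min(ts - 1L, n - ts)
    warning("window extends beyond the profile; shrunk symmetrically to ",
            2L * half + 1L, " frames")
  }
  idx <- (ts - half):(ts + half)
  h <- profile$atom_map["h"]
  d <- profile$atom_map["donor"]
  a <- profile$atom_map["acceptor"]
  disp <- sqrt(sum((profile$coords[h, , idx[length(idx)]] -
                    profile$coords[h, , idx[1]])^2))
  dh <- t(vapply(idx, function(i) c(
    donor_h = sqrt(sum((profile$coords[h, , i] - profile$coords[d, , i])^2)),
    acceptor_h = sqrt(sum((profile$coords[h, , i] - profile$coords[a, , i])^2))),
    c(donor_h = 0, acceptor_h = 0)))
  rownames(dh) <- idx
  list(distance = disp, window = idx, dh_distances = dh)
}

# Asymmetric Eckart energy curve. With y = exp((s - s_ref)/L):
#   V(s) = A*y/(1+y) + B*y/(1+y)^2,  A = Vf - Vr,  B = (sqrt(Vf)+sqrt(Vr))^2
# V(-Inf) = 0, V(+Inf) = Vf - Vr, max(V) = Vf. 's0' shifts the curve so the
# maximum sits at s = s0.
.eckart_curve <- function(s, V_forward, V_reverse, L, s0 = 0) {
  A <- V_forward - V_reverse
  B <- (sqrt(V_forward) + sqrt(V_reverse))^2
  sref <- s0 - if (abs(A) < 1e-12) 0 else L * log((A + B) / (B - A))
  y <- exp((s - sref) / L)
  A * y / (1 + y) + B * y / (1 + y)^2
}

#' Fit an asymmetric Eckart curve to a tabulated profile
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the asymmetric Eckart
#' form to `(s, energy)` samples, reporting forward/reverse barriers, the
#' characteristic width `L`, the barrier-top position `s0`, the residual sum
#' of squares, and the imaginary wavenumber implied by the curvature at the
#' fitted maximum, `nu = 1/(2*pi*c) * sqrt(|V''(s0)|/mu)`.
#'
#' @param points a two-column matrix/data.frame `(s, energy)` or a
#'   [reaction_profile()]
#' @param mass reduced mass for the implied wavenumber, amu
#' @return an object of class `eckart_fit`
#' @export
fit_eckart <- function(points, mass = 1.00783) {
  if (inherits(points, "reaction_profile"))
    points <- cbind(points$s, points$energy)
  points <- as.matrix(points)
  if (ncol(points) < 2L || nrow(points) < 7L)
    stop("need >= 7 (s, energy) points spanning both asymptotes and the maximum")
  s <- points[, 1]; e <- points[, 2] - points[1, 2]
  if (diff(range(e)) < 1e-8) stop("no barrier detected: the profile is flat")
  imax <- which.max(e)
  if (imax == 1L || imax == nrow(points))
    stop("no interior maximum: profile does not span the barrier")
  Vf0 <- max(e[imax] - min(e[1:imax]), 0.5)
  Vr0 <- max(e[imax] - min(e[imax:length(e)]), 0.5)
  st <- list(Vf = Vf0, Vr = Vr0, L = diff(range(s)) / 12, s0 = s[imax])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      e ~ .eckart_curve(s, Vf, Vr, L, s0),
      start = st,
      lower = c(Vf = 1e-3, Vr = 1e-3, L = 1e-4, s0 = min(s)),
      upper = c(Vf = Inf, Vr = Inf, L = diff(range(s)), s0 = max(s)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(err) stop(
      "Eckart fit did not converge (start: Vf = ", signif(st$Vf, 4),
      ", Vr = ", signif(st$Vr, 4), ", L = ", signif(st$L, 4),
      ", s0 = ", signif(st$s0, 4), "): ", conditionMessage(err)))
  cf <- stats::coef(fit)
  h <- max(cf[["L"]] * 1e-3, 1e-6)
  vpp <- (.eckart_curve(cf[["s0"]] + h, cf[["Vf"]], cf[["Vr"]], cf[["L"]], cf[["s0"]]) -
          2 * .eckart_curve(cf[["s0"]], cf[["Vf"]], cf[["Vr"]], cf[["L"]], cf[["s0"]]) +
          .eckart_curve(cf[["s0"]] - h, cf[["Vf"]], cf[["Vr"]], cf[["L"]], cf[["s0"]])) / h^2
  structure(list(V_forward = cf[["Vf"]], V_reverse = cf[["Vr"]],
                 L = cf[["L"]], s0 = cf[["s0"]],
                 rss = sum(stats::resid(fit)^2),
                 implied_nu = .NUFAC * sqrt(abs(vpp) / mass),
                 mass = mass, fit = fit, s = s, energy = e),
            class = "eckart_fit")
}

#' @export
print.eckart_fit <- function(x, ...) {
  cat(sprintf("Eckart fit: Vf = %.3f, Vr = %.3f kcal/mol; L = %.4f A; s0 = %.4f\n",
              x$V_forward, x$V_reverse, x$L, x$s0))
  cat(sprintf("  rss = %.4g; implied nu = %.1f cm^-1 (mu = %.4f u)\n",
              x$rss, x$implied_nu, x$mass))
  invisible(x)
}

#' @export
coef.eckart_fit <- function(object, ...) {
  c(V_forward = object$V_forward, V_reverse = object$V_reverse,
    L = object$L, s0 = object$s0)
}

#' @export
predict.eckart_fit <- function(object, newdata = NULL, ...) {
  s <- if (is.null(newdata)) object$s
       else if (is.list(newdata)) newdata$s else newdata
  .eckart_curve(s, object$V_forward, object$V_reverse, object$L, object$s0)
}

#' @export
residuals.eckart_fit <- function(object, ...) {
  object$energy - predict(object)
}

#' Construct a scan curve
#'
#' Ordered `(x, energy)` samples of a bond-distance or dihedral scan, with
#' optional per-fragment spin populations (columns summing to the total
#' unpaired spin at each point).
#'
#' @param x scanned coordinate, strictly monotone (Angstrom or degrees)
#' @param energy energies, kcal/mol
#' @param spins optional matrix/data.frame of per-fragment spin populations
#' @param kind `"distance"` or `"dihedral"`
#' @return an object of class `scan_curve`
#' @export
scan_curve <- function(x, energy, spins = NULL,
                       kind = c("distance", "dihedral")) {
  kind <- match.arg(kind)
  if (length(x) != length(energy)) stop("'x' and 'energy' lengths differ")
  d <- diff(x)
  if (any(d == 0) || (any(d > 0) && any(d < 0)))
    stop("'x' must be strictly monotone")
  if (!is.null(spins)) {
    spins <- as.matrix(spins)
    if (nrow(spins) != length(x)) stop("'spins' rows must match points")
    if (any(spins < -1e-9)) stop("negative spin population")
  }
  structure(list(x = as.numeric(x), energy = as.numeric(energy),
                 spins = spins, kind = kind),
            class = "scan_curve")
}

#' @export
print.scan_curve <- function(x, ...) {
  cat(sprintf("Scan curve (%s): %d points, x in [%.3f, %.3f]\n",
              x$kind, length(x$x), min(x$x), max(x$x)))
  if (!is.null(x$spins))
    cat("  spin fragments:", paste(colnames(x$spins), collapse = ", "), "\n")
  invisible(x)
}

# 3-point quadratic refinement of a discrete extremum at index i
.quad_refine <- function(x, e, i) {
  if (i == 1L || i == length(x)) return(x[i])
  x1 <- x[i - 1L]; x2 <- x[i]; x3 <- x[i + 1L]
  y1 <- e[i - 1L]; y2 <- e[i]; y3 <- e[i + 1L]
  den <- (x1 - x2) * (x1 - x3) * (x2 - x3)
  a <- (x3 * (y2 - y1) + x2 * (y1 - y3) + x1 * (y3 - y2)) / den
  b <- (x3^2 * (y1 - y2) + x2^2 * (y3 - y1) + x1^2 * (y2 - y3)) / den
  if (a <= 0) return(x2)
  xv <- -b / (2 * a)
  if (xv < x1 || xv > x3) x2 else xv
}

#' Assess bond-scission completion on a distance scan
#'
#' Locates the scan's energy minimum (refined by local quadratic
#' interpolation), reports whether the energy is monotone decreasing over the
#' scanned range, and classifies the scission as complete when the scan
#' endpoint exceeds the completion distance with the unpaired spin located
#' (at least `spin_threshold` of the total) on the leaving fragment. With no
#' spin columns the status is `"undetermined"` but all numeric fields are
#' still returned.
#'
#' @param curve a [scan_curve()] of kind `"distance"`
#' @param completion_distance separation counted as broken, Angstrom;
#'   default 3.0
#' @param spin_threshold fraction of total spin on the leaving fragment that
#'   counts as "exclusively"; default 0.95
#' @param leaving column of `curve$spins` holding the leaving fragment;
#'   default the first column
#' @return an object of class `scission_assessment` with fields `x_min`,
#'   `endpoint_distance`, `leaving_spin_fraction`, `status`,
#'   `monotone_decreasing`, `flags`
#' @export
analyze_scan <- function(curve, completion_distance = 3.0,
                         spin_threshold = 0.95, leaving = 1L) {
  stopifnot(inherits(curve, "scan_curve"))
  n <- length(curve$x)
  if (n < 5L) stop("need >= 5 scan points")
  e <- curve$energy - curve$energy[1]
  flags <- character()
  flat <- diff(range(e)) < 1e-8
  if (flat) {
    x_min <- min(curve$x)
    flags <- c(flags, "no curvature")
  } else {
    imin <- which.min(e)
    if (sum(e == e[imin]) > 1L) flags <- c(flags, "tie broken toward lower coordinate")
    x_min <- .quad_refine(curve$x, e, imin)
  }
  monotone <- all(diff(e) <= 1e-9)
  endpoint <- curve$x[n]
  if (!is.null(curve$spins)) {
    tot <- sum(curve$spins[n, ])
    frac <- if (tot > 0) sum(curve$spins[n, leaving]) / tot else NA_real_
    status <- if (isTRUE(endpoint > completion_distance && frac >= spin_threshold))
      "complete" else "incomplete"
  } else {
    frac <- NA_real_
    status <- "undetermined"
  }
  structure(list(x_min = x_min, endpoint_distance = endpoint,
                 leaving_spin_fraction = frac, status = status,
                 monotone_decreasing = monotone, flags = flags,
                 completion_distance = completion_distance,
                 spin_threshold = spin_threshold),
            class = "scission_assessment")
}

#' @export
print.scission_assessment <- function(x, ...) {
  cat(sprintf("Scission assessment: %s\n", x$status))
  cat(sprintf("  energy minimum at x = %.3f; endpoint %.3f (threshold %.2f)\n",
              x$x_min, x$endpoint_distance, x$completion_distance))
  if (!is.na(x$leaving_spin_fraction))
    cat(sprintf("  leaving-fragment spin fraction %.3f (threshold %.2f)\n",
                x$leaving_spin_fraction, x$spin_threshold))
  if (x$monotone_decreasing) cat("  energy is monotone decreasing over the scan\n")
  for (f in x$flags) cat("  flag: ", f, "\n", sep = "")
  invisible(x)
}

# signed angular difference folded to (-180, 180]
.angdiff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Find local minima of a scan curve
#'
#' Interior minima with at least the requested prominence (the smaller of the
#' climbs required to escape the minimum on either side before reaching a
#' lower point). Dihedral scans are treated as periodic: the curve wraps at
#' +/-180 degrees, so a well straddling the wrap is found once. Minima
#' positions are refined by 3-point quadratic interpolation.
#'
#' @param curve a [scan_curve()]
#' @param prominence minimum prominence, kcal/mol; default 0.5
#' @return a data.frame with columns `x`, `energy`, `global`
#' @export
find_local_minima <- function(curve, prominence = 0.5) {
  stopifnot(inherits(curve, "scan_curve"))
  n <- length(curve$x)
  if (n < 5L) stop("need >= 5 scan points")
  e <- curve$energy
  periodic <- curve$kind == "dihedral"
  at <- function(i) e[((i - 1L) %% n) + 1L]
  is_min <- function(i) {
    if (periodic) at(i) < at(i - 1L) && at(i) < at(i + 1L)
    else i > 1L && i < n && e[i] < e[i - 1L] && e[i] < e[i + 1L]
  }
  prom <- function(i) {
    climb <- function(step) {
      best <- 0; j <- i
      for (k in seq_len(n)) {
        j <- j + step
        if (!periodic && (j < 1L || j > n)) break
        v <- at(j) - at(i)
        if (at(j) < at(i)) break
        best <- max(best, v)
      }
      best
    }
    min(climb(1L), climb(-1L))
  }
  cand <- Filter(is_min, seq_len(n))
  cand <- Filter(function(i) prom(i) >= prominence, cand)
  if (!length(cand))
    return(data.frame(x = numeric(), energy = numeric(), global = logical()))
  xr <- vapply(cand, function(i) {
    if (periodic) {
      im <- ((i - 2L) %% n) + 1L; ip <- (i %% n) + 1L
      xs <- c(curve$x[i] + .angdiff(curve$x[im], curve$x[i]),
              curve$x[i],
              curve$x[i] + .angdiff(curve$x[ip], curve$x[i]))
      v <- .quad_refine(xs, c(e[im], e[i], e[ip]), 2L)
      d <- ((v + 180) %% 360) - 180                      # fold to (-180, 180]
      if (d == -180) 180 else d
    } else .quad_refine(curve$x, e, i)
  }, 0)
  out <- data.frame(x = xr, energy = e[cand], global = FALSE)
  out$global[which.min(out$energy)] <- TRUE
  out[order(out$x), , drop = FALSE]
}
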