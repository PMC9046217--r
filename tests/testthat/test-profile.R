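test_that("stationary points: interior maximum, terminal minima, barriers", {
  r <- detect_stationary_points(c(0, 5, 10, 5, 0))
  expect_equal(r$ts, 3L)
  expect_equal(r$reactant, 1L)
  expect_equal(r$product, 5L)
  expect_equal(r$forward_barrier, 10)
  expect_equal(r$reverse_barrier, 10)
  # generator parameters are the oracle
  p <- make_irc(V_forward = 20, V_reverse = 14, L = 0.15, n_frames = 41L,
                seed = 11)
  r <- detect_stationary_points(p)
  expect_equal(r$forward_barrier, 20, tolerance = 0.1 / 20)
  expect_equal(r$reverse_barrier, 14, tolerance = 0.1 / 14)
  expect_error(detect_stationary_points(c(0, 1, 2, 3, 4, 5)),
               "no interior barrier")
  expect_error(detect_stationary_points(c(0, 1)), ">= 5 frames")
})

test_that("barriers are invariant under energy offset and frame reversal", {
  set.seed(5)
  for (k in 1:10) {
    p <- make_irc(V_forward = runif(1, 10, 25), V_reverse = runif(1, 8, 20),
                  L = 0.2, n_frames = 31L, noise = 0.02, seed = k)
    r <- detect_stationary_points(p)
    roff <- detect_stationary_points(p$energy + 7.3)
    expect_equal(roff$forward_barrier, r$forward_barrier)
    expect_equal(roff$reverse_barrier, r$reverse_barrier)
    rrev <- detect_stationary_points(rev(p$energy))
    expect_equal(rrev$forward_barrier, r$reverse_barrier)
    expect_equal(rrev$reverse_barrier, r$forward_barrier)
  }
})

test_that("transfer distance measures the migrating hydrogen displacement", {
  # identical frames: zero
  p0 <- make_irc(h_displacement = 0, seed = 2)
  expect_equal(transfer_distance(p0)$distance, 0)
  # hydrogen moved linearly 0.1 A per frame across the 5-frame window
  p1 <- make_irc(h_displacement = 0.4, seed = 2)
  expect_equal(transfer_distance(p1)$distance, 0.4, tolerance = 1e-9)
  # the short-transfer regime: 0.45 A prescribed, recovered within 0.01
  p2 <- make_irc(h_displacement = 0.45, seed = 3)
  td <- transfer_distance(p2)
  expect_equal(td$distance, 0.45, tolerance = 0.01 / 0.45)
  expect_lt(td$distance, 0.5)
  expect_equal(nrow(td$dh_distances), 5L)
  # donor-H grows, acceptor-H shrinks as the H migrates
  expect_true(all(diff(td$dh_distances[, "donor_h"]) >= 0))
  expect_true(all(diff(td$dh_distances[, "acceptor_h"]) <= 0))
})

test_that("transfer distance is invariant under rigid motion of all frames", {
  p <- make_irc(h_displacement = 0.45, seed = 4)
  d0 <- transfer_distance(p)$distance
  set.seed(21)
  for (k in 1:5) {
    rg <- random_rigid()
    q <- p
    for (i in seq_along(q$energy))
      q$coords[, , i] <- sweep(q$coords[, , i] %*% t(rg$R), 2, rg$t, "+")
    expect_equal(transfer_distance(q)$distance, d0, tolerance = 1e-10)
  }
})

test_that("transfer window shrinks with a warning near the profile edge", {
  p <- make_irc(n_frames = 21L, seed = 6)
  # force the TS near the edge by truncating frames past the barrier
  q <- reaction_profile(p$energy[8:12], s = p$s[8:12],
                        coords = p$coords[, , 8:12, drop = FALSE],
                        elements = p$elements, atom_map = p$atom_map)
  expect_error(transfer_distance(p, window = 4L), "odd")
  expect_warning(transfer_distance(q, window = 5L), "shrunk")
})

test_that("Eckart fit recovers generator parameters", {
  # symmetry forced
  ps <- make_irc(V_forward = 20, V_reverse = 20, L = 0.4, n_frames = 41L,
                 seed = 8)
  fs <- fit_eckart(ps)
  expect_equal(fs$V_forward, fs$V_reverse, tolerance = 0.1 / 20)
  expect_equal(fs$V_forward, 20, tolerance = 0.01)
  # asymmetric with noise, fixed seed
  pa <- make_irc(V_forward = 20, V_reverse = 14, L = 0.5, n_frames = 41L,
                 noise = 0.05, seed = 9)
  fa <- fit_eckart(pa)
  expect_equal(fa$V_forward, 20, tolerance = 0.05)
  expect_equal(fa$V_reverse, 14, tolerance = 0.05)
  expect_equal(fa$L, 0.5, tolerance = 0.05)
  # implied wavenumber round trip: choose L for nu = 2500 analytically.
  # Symmetric barrier curvature |V''| = Vf/(2 L^2) => L = NUFAC/nu * sqrt(Vf/(2 mu))
  mu <- 1.00783
  L_star <- 108.5914 / 2500 * sqrt(20 / (2 * mu))
  pr <- make_irc(V_forward = 20, V_reverse = 20, L = L_star, n_frames = 41L,
                 seed = 10)
  fr <- fit_eckart(pr, mass = mu)
  expect_equal(fr$implied_nu, 2500, tolerance = 0.02)
  # model-object interface
  expect_named(coef(fa), c("V_forward", "V_reverse", "L", "s0"))
  expect_equal(predict(fa, newdata = pa$s) + residuals(fa), fa$energy)
  expect_error(fit_eckart(cbind(1:10, rep(0, 10))), "flat")
})

test_that("Eckart fit parameter recovery holds over 50 seeded profiles", {
  rel_err <- function(noise) {
    vapply(1:50, function(sd) {
      Vf <- 10 + (sd %% 5) * 3
      Vr <- Vf * (0.7 + (sd %% 3) * 0.15)
      p <- make_irc(V_forward = Vf, V_reverse = Vr, L = 0.3, n_frames = 31L,
                    noise = noise, seed = sd)
      f <- fit_eckart(p)
      max(abs(f$V_forward - Vf) / Vf, abs(f$V_reverse - Vr) / Vr)
    }, 0)
  }
  expect_lt(median(rel_err(0)), 0.02)
  expect_lt(median(rel_err(0.05)), 0.06)
})

test_that("scan assessment mirrors the incomplete and complete scissions", {
  # X-ray-frame analogue: minimum near 2.7 A, residual spin on the nitrogen
  inc <- analyze_scan(make_scan(minimum_x = 2.70, endpoint_spin = 0.55,
                                seed = 1))
  expect_equal(inc$x_min, 2.70, tolerance = 0.02 / 2.70)
  expect_identical(inc$status, "incomplete")
  # MD-frame analogue: monotone downhill to 3.4 A, spin fully departed
  cmp <- analyze_scan(make_scan(shape = "monotone", endpoint_spin = 1.0,
                                x_range = c(2.2, 3.4), seed = 1))
  expect_identical(cmp$status, "complete")
  expect_true(cmp$monotone_decreasing)
  expect_equal(cmp$endpoint_distance, 3.4)
  # flat curve flagged
  flat <- analyze_scan(scan_curve(seq(2, 3, 0.1), rep(0, 11),
                                  kind = "distance"))
  expect_equal(flat$x_min, 2)
  expect_match(flat$flags, "no curvature")
  # spins absent: undetermined but numerics intact
  und <- analyze_scan(make_scan(minimum_x = 2.7, endpoint_spin = NULL,
                                seed = 1))
  expect_identical(und$status, "undetermined")
  expect_equal(und$x_min, 2.70, tolerance = 0.02 / 2.70)
})

test_that("completion status is monotone in endpoint spin and distance", {
  base <- make_scan(shape = "monotone", endpoint_spin = 0.95,
                    x_range = c(2.2, 3.1), seed = 2)
  r0 <- analyze_scan(base)
  expect_identical(r0$status, "complete")
  # raising the endpoint spin can never flip complete -> incomplete
  for (sp in c(0.96, 0.99, 1.0)) {
    r <- analyze_scan(make_scan(shape = "monotone", endpoint_spin = sp,
                                x_range = c(2.2, 3.1), seed = 2))
    expect_identical(r$status, "complete")
  }
  # nor can extending the scanned range
  for (xmax in c(3.2, 3.4, 3.8)) {
    r <- analyze_scan(make_scan(shape = "monotone", endpoint_spin = 0.95,
                                x_range = c(2.2, xmax), seed = 2))
    expect_identical(r$status, "complete")
  }
})

test_that("local minima: single well, double well, periodic wrap", {
  # single-well parabola
  x <- seq(-2, 2, 0.25)
  m <- find_local_minima(scan_curve(x, (x - 0.3)^2, kind = "distance"),
                         prominence = 0.5)
  expect_equal(nrow(m), 1L)
  expect_equal(m$x, 0.3, tolerance = 1e-6)
  # dihedral double well emulating the productive/non-productive pair
  d <- make_dihedral_scan(wells = c(-48, 55), depths = c(6, 3.5), seed = 3)
  md <- find_local_minima(d)
  expect_equal(nrow(md), 2L)
  expect_equal(sort(md$x), c(-48, 55), tolerance = 1 / 48)
  expect_true(md$global[md$x < 0])
  expect_false(md$global[md$x > 0])
  # well straddling the +/-180 wrap is found exactly once
  w <- make_dihedral_scan(wells = 179, depths = 5, seed = 4)
  mw <- find_local_minima(w)
  expect_equal(nrow(mw), 1L)
  expect_equal(abs(mw$x), 179, tolerance = 2 / 179)
})
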