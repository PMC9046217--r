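test_that("dihedral: planar anchors, independent oracle, symmetries", {
  expect_equal(dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  expect_equal(dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(-1, 0, 0)), 180)
  set.seed(31)
  for (k in 1:20) {
    p <- lapply(1:4, function(i) rnorm(3, 0, 3))
    a <- dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
    expect_equal(a, dihedral_oracle(p[[1]], p[[2]], p[[3]], p[[4]]),
                 tolerance = 1e-11)
    # traversal-direction invariance (IUPAC torsions are reversal-symmetric);
    # negation comes from mirror reflection instead
    b <- dihedral(p[[4]], p[[3]], p[[2]], p[[1]])
    expect_equal(b, a, tolerance = 1e-9)
    refl <- lapply(p, function(v) v * c(1, 1, -1))
    expect_equal(dihedral(refl[[1]], refl[[2]], refl[[3]], refl[[4]]), -a,
                 tolerance = 1e-9)
    # rigid-motion invariance
    rg <- random_rigid()
    q <- lapply(p, function(v) as.numeric(rg$R %*% v) + rg$t)
    expect_equal(dihedral(q[[1]], q[[2]], q[[3]], q[[4]]), a,
                 tolerance = 1e-9)
  }
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "coincident")
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("Newman classifier reproduces both product regiochemistries", {
  # tryptophan-lyase product, phi = 174.5: carboxylate C-C aligned
  nosl <- newman_assess(174.5)
  b <- nosl$bonds
  expect_equal(b$omega[b$bond == "Calpha-C"], 24.5)
  expect_identical(b$zone[b$bond == "Calpha-C"], "periplanar")
  expect_equal(b$omega[b$bond == "Calpha-Cbeta"], 84.5)
  expect_identical(b$zone[b$bond == "Calpha-Cbeta"], "clinal")
  # tyrosine-lyase product, phi = 39.6: Cbeta bond allowed but not optimal
  thih <- newman_assess(39.6)
  b <- thih$bonds
  expect_equal(b$omega[b$bond == "Calpha-Cbeta"], 50.4)
  expect_identical(b$zone[b$bond == "Calpha-Cbeta"], "intermediate")
  expect_equal(b$omega[b$bond == "Calpha-C"], 69.6)
  expect_identical(b$zone[b$bond == "Calpha-C"], "clinal")
  # perpendicularity forced
  perp <- newman_assess(90)
  expect_equal(perp$bonds$omega[perp$bonds$bond == "Calpha-Cbeta"], 0)
  expect_identical(perp$bonds$zone[perp$bonds$bond == "Calpha-Cbeta"],
                   "periplanar")
})

test_that("Newman zones respect orbital-lobe and mirror symmetry", {
  set.seed(13)
  for (phi in runif(15, -180, 180)) {
    a <- newman_assess(phi)
    # two-lobe symmetry: phi + 180 projects onto the same orbital axis
    b <- newman_assess(phi + 180)
    expect_equal(a$bonds$omega, b$bonds$omega, tolerance = 1e-9)
    expect_identical(a$bonds$zone, b$bonds$zone)
    # mirror symmetry: sign flip with offset flip
    m <- newman_assess(-phi, substituent_offset = -120)
    expect_equal(a$bonds$omega, m$bonds$omega, tolerance = 1e-9)
  }
})

test_that("contact census finds and types a square-pyramidal anion site", {
  st <- make_site(n_basal = 4L, basal_distance = 2.8, apical = TRUE,
                  jitter = 0, seed = 1)
  cc <- contact_census(st, "A:500:O1")
  expect_equal(nrow(cc$contacts), 5L)
  expect_identical(cc$geometry, "square-pyramidal")
  expect_true(all(cc$contacts$distance <= 3.5))
  # same-residue ring carbons were not counted
  expect_false(any(cc$contacts$resno == 500))
  # four donors only (no apical) still qualifies
  cc4 <- contact_census(make_site(apical = FALSE, seed = 1), "A:500:O1")
  expect_equal(nrow(cc4$contacts), 4L)
  expect_identical(cc4$geometry, "square-pyramidal")
  # no neighbors in range
  lone <- structure3d(data.frame(elety = c("O1", "N"),
                                 resid = c("PHO", "GLY"),
                                 resno = c(1L, 2L), x = c(0, 30), y = 0,
                                 z = 0, elesy = c("O", "N"),
                                 type = "HETATM"))
  cc0 <- contact_census(lone, "A:1:O1")
  expect_equal(nrow(cc0$contacts), 0L)
  expect_identical(cc0$geometry, "underdetermined")
  # too few donors cannot define the geometry
  cc2 <- contact_census(make_site(n_basal = 2L, apical = FALSE, seed = 1),
                        "A:500:O1")
  expect_identical(cc2$geometry, "underdetermined")
  expect_error(contact_census(st, "A:999:O1"), "matches no atom")
})

test_that("square-pyramidal typing survives donor jitter and atom order", {
  # the [70, 110] degree angular windows tolerate ~0.2 A of donor jitter
  # essentially always; at 0.3 A (angular noise ~8.7 degrees s.d. against a
  # +/-20 degree window) the expected pass rate drops to ~0.8
  hits <- function(jit) mean(vapply(1:20, function(sd) {
    cc <- contact_census(make_site(jitter = jit, seed = sd), "A:500:O1")
    cc$geometry == "square-pyramidal"
  }, TRUE))
  expect_gte(hits(0.2), 0.9)
  expect_gte(hits(0.3), 0.7)
  # result independent of atom ordering in the table
  st <- make_site(jitter = 0.1, seed = 3)
  set.seed(99)
  perm <- sample(nrow(st$atom))
  shuffled <- structure3d(st$atom[perm, ])
  a <- contact_census(st, "A:500:O1")
  b <- contact_census(shuffled, "A:500:O1")
  expect_identical(a$geometry, b$geometry)
  expect_equal(sort(a$contacts$distance), sort(b$contacts$distance))
})

test_that("superposition: exact on rigid copies, sigma*sqrt(3) on noise", {
  pair <- make_structure_pair(noise = 0, seed = 5)
  s <- superpose(pair$a, pair$b)
  expect_lt(s$rmsd, 1e-9)
  expect_equal(s$n_used, s$n_total)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  # matrix interface, random rigid motion
  set.seed(17)
  X <- matrix(rnorm(300), ncol = 3)
  rg <- random_rigid()
  Y <- sweep(X %*% t(rg$R), 2, rg$t, "+")
  expect_lt(superpose(X, Y)$rmsd, 1e-9)
  # isotropic noise: rmsd approaches sigma*sqrt(3)
  sig <- 0.2
  pairn <- make_structure_pair(n_res = 500L, noise = sig, seed = 6)
  sn <- superpose(pairn$a, pairn$b)
  expect_equal(sn$rmsd, sig * sqrt(3), tolerance = 0.05)
  # independent cross-check against bio3d's fitter on the same pairs
  ka <- pairn$a$atom$elety == "CA"
  kb <- pairn$b$atom$elety == "CA"
  xyz_a <- as.numeric(t(as.matrix(pairn$a$atom[ka, c("x", "y", "z")])))
  xyz_b <- as.numeric(t(as.matrix(pairn$b$atom[kb, c("x", "y", "z")])))
  fit <- suppressWarnings(bio3d::fit.xyz(xyz_a, xyz_b))
  rmsd_bio3d <- sqrt(mean(colSums(matrix((fit - xyz_a)^2, nrow = 3))))
  expect_equal(sn$rmsd, rmsd_bio3d, tolerance = 1e-6)
  expect_error(superpose(X[1:2, ], Y[1:2, ]), ">= 3")
})

test_that("superposition rmsd is symmetric and pre-rotation invariant", {
  pair <- make_structure_pair(noise = 0.15, seed = 7)
  ab <- superpose(pair$a, pair$b)$rmsd
  ba <- superpose(pair$b, pair$a)$rmsd
  expect_equal(ab, ba, tolerance = 1e-9)
  set.seed(23)
  rg <- random_rigid()
  rot <- pair$b
  rot$atom[, c("x", "y", "z")] <-
    sweep(as.matrix(rot$atom[, c("x", "y", "z")]) %*% t(rg$R), 2, rg$t, "+")
  expect_equal(superpose(pair$a, rot)$rmsd, ab, tolerance = 1e-9)
})

test_that("trimming drops outliers, never more than 30 percent", {
  pair <- make_structure_pair(n_res = 100L, noise = 0.05, seed = 8)
  # corrupt a handful of CA positions in copy B
  bad <- pair$b
  ca_rows <- which(bad$atom$elety == "CA")[c(10, 40, 70)]
  bad$atom$x[ca_rows] <- bad$atom$x[ca_rows] + 8
  full <- superpose(pair$a, bad, trim = FALSE)
  trim <- superpose(pair$a, bad, trim = TRUE)
  expect_lt(trim$rmsd, full$rmsd)
  expect_equal(trim$n_total - trim$n_used, 3L)
  expect_gte(trim$n_used, ceiling(0.7 * trim$n_total))
  expect_gte(trim$rounds, 1L)
})

test_that("chi1 delta reproduces a constructed side-chain rotation", {
  pair <- make_structure_pair(chi1_pair = c(-60, 50), noise = 0, seed = 9)
  ser <- pair$ground_truth$ser_resno
  expect_equal(as.numeric(chi1_delta(pair$a, pair$a, "A", ser)), 0)
  d <- chi1_delta(pair$a, pair$b, "A", ser)
  expect_equal(as.numeric(d), 110, tolerance = 1e-6)
  chi <- attr(d, "chi1")
  expect_equal(as.numeric(chi["A"]), -60, tolerance = 1e-6)
  expect_equal(as.numeric(chi["B"]), 50, tolerance = 1e-6)
  # folding: (-170, 170) differ by 20, not 340
  wrap <- make_structure_pair(chi1_pair = c(-170, 170), noise = 0, seed = 9)
  expect_equal(as.numeric(chi1_delta(wrap$a, wrap$b, "A", ser)), 20,
               tolerance = 1e-6)
  # missing gamma atom is reported by name
  noga <- pair$a
  noga$atom <- noga$atom[!(noga$atom$resno == ser & noga$atom$elety == "OG"), ]
  expect_error(chi1_delta(noga, pair$b, "A", ser), "missing atom OG")
})
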