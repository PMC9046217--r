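# Independent numerical oracles used by the test suite. These deliberately
# avoid the package's analytic code paths: transmission probabilities come
# from direct Numerov integration of the 1-D Schrodinger equation, thermal
# averages from plain trapezoidal sums, and dihedrals from an explicit
# projection construction.

O_RGAS <- 1.987204e-3
O_HCKB <- 1.438777
O_KINFAC <- 20.74758    # psi'' = O_KINFAC * m[amu] * (V-E)[kcal/mol] * psi
O_NUFAC <- 108.5914     # nu[cm^-1] = O_NUFAC * sqrt(|V''|/mu)

# Numerov transmission through an asymmetric Eckart potential defined by
# (V_forward, V_reverse, nu_imag, mass). The potential's width parameter is
# recovered from the curvature condition at the barrier top; the scattering
# solution is integrated from the transmitted side backwards and decomposed
# into incident + reflected waves on the reactant side. Vectorized over E.
numerov_transmission <- function(E, Vf, Vr, nu, mass = 1.00783) {
  A <- Vf - Vr
  B <- (sqrt(Vf) + sqrt(Vr))^2
  Vfun <- function(x, aa) { y <- exp(aa * x); A * y / (1 + y) + B * y / (1 + y)^2 }
  xmax <- function(aa) if (abs(A) < 1e-12) 0 else log((A + B) / (B - A)) / aa
  vpp <- function(aa) {
    h <- 1e-4; x0 <- xmax(aa)
    (Vfun(x0 + h, aa) - 2 * Vfun(x0, aa) + Vfun(x0 - h, aa)) / h^2
  }
  aa <- uniroot(function(a) O_NUFAC * sqrt(abs(vpp(a)) / mass) - nu,
                c(0.05, 120))$root
  k2c <- O_KINFAC * mass
  res <- numeric(length(E))
  ok <- E > 0 & (E - A) > 0
  Ev <- E[ok]
  if (length(Ev)) {
    k1 <- sqrt(k2c * Ev)
    k2 <- sqrt(k2c * (Ev - A))
    X <- 30 / aa
    h <- min(2 * pi / max(c(k1, k2)) / 40, 0.05 / aa)
    xs <- seq(-X, X, by = h)
    n <- length(xs)
    Vx <- Vfun(xs, aa)
    fq <- function(j) 1 + h^2 / 12 * (-(k2c * (Vx[j] - Ev)))
    psi_pp <- exp(1i * xs[n] * k2)       # psi[j+1]
    psi_c <- exp(1i * xs[n - 1] * k2)    # psi[j]
    fj1 <- fq(n); fj <- fq(n - 1)
    for (j in (n - 1):2) {
      fjm1 <- fq(j - 1)
      psi_m <- ((12 - 10 * fj) * psi_c - fj1 * psi_pp) / fjm1
      psi_pp <- psi_c; psi_c <- psi_m
      fj1 <- fj; fj <- fjm1
    }
    e1m <- exp(-1i * k1 * xs[1]); e2m <- exp(-1i * k1 * xs[2])
    det <- exp(1i * k1 * xs[1]) * e2m - e1m * exp(1i * k1 * xs[2])
    Ain <- (psi_c * e2m - psi_pp * e1m) / det
    res[ok] <- (k2 / k1) / Mod(Ain)^2
  }
  res
}

# Boltzmann average of the Numerov transmission by plain trapezoid on the
# substituted variable t = sqrt(E/kBT).
kappa_numerov_oracle <- function(Vf, Vr, nu, Temp, mass = 1.00783,
                                 npts = 801L) {
  aT <- Vf / (O_RGAS * Temp)
  t <- seq(1e-6, sqrt(aT + 40), length.out = npts)
  E <- t^2 * O_RGAS * Temp
  TT <- numerov_transmission(E, Vf, Vr, nu, mass)
  y <- ifelse(TT > 0, 2 * t * exp(aT - t^2 + log(TT)), 0)
  sum((y[-1] + y[-npts]) / 2) * (t[2] - t[1])
}

# Boltzmann average of the Kemble parabolic transmission by trapezoid;
# independent of the package's series and quadrature.
kappa_kemble_oracle <- function(V, nu, Temp, npts = 200001L) {
  u <- O_HCKB * nu / Temp
  al <- V / (O_RGAS * Temp)
  eps <- seq(0, al + 40, length.out = npts)
  y <- exp(al - eps - log1p(exp(2 * pi * (al - eps) / u)))
  sum((y[-1] + y[-npts]) / 2) * (eps[2] - eps[1])
}

# Dihedral by explicit frame construction: project the outer bonds onto the
# plane perpendicular to the central bond and take the signed angle there.
dihedral_oracle <- function(p1, p2, p3, p4) {
  u <- (p3 - p2); u <- u / sqrt(sum(u^2))
  w1 <- (p1 - p2) - sum((p1 - p2) * u) * u
  w2 <- (p4 - p3) - sum((p4 - p3) * u) * u
  e1 <- w1 / sqrt(sum(w1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  ang <- atan2(sum(w2 * e2), sum(w2 * e1)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# random rigid motion for invariance checks
random_rigid <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
               3, 3, byrow = TRUE)
  list(R = ct * diag(3) + st * ux + (1 - ct) * tcrossprod(ax),
       t = rnorm(3, 0, 10))
}
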