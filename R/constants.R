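# Physical constants, fixed to 7 significant digits so results are
# reproducible bit-for-bit at double precision across platforms.
.RGAS   <- 1.987204e-3   # gas constant, kcal mol^-1 K^-1
.HC_KB  <- 1.438777      # hc/kB (second radiation constant), cm K
.KCAL_CM <- 349.755      # 1 kcal mol^-1 expressed in cm^-1
# 2m/hbar^2 prefactor: psi'' = .KINFAC * m[amu] * (V - E)[kcal/mol] * psi, x in A
.KINFAC <- 20.74758
# wavenumber from curvature: nu[cm^-1] = .NUFAC * sqrt(|V''|[kcal/mol/A^2] / mu[amu])
.NUFAC  <- 108.5914
.HARTREE_KCAL <- 627.5095
.KJ_KCAL <- 1/4.184

# log(cosh(x)) without overflow
.logcosh <- function(x) {
  ax <- abs(x)
  ax - log(2) + log1p(exp(-2 * ax))
}

# log(exp(a) + exp(b)), vectorized
.logadd <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

#' Composite Simpson quadrature with interval doubling
#'
#' Integrates a vectorized integrand on a finite interval, doubling the
#' panel count (and reusing previous evaluations) until the Richardson
#' error estimate meets the relative tolerance. Used for the Boltzmann
#' averages, where the integrands are smooth but span many orders of
#' magnitude.
#'
#' @param f vectorized function of one numeric vector
#' @param a,b finite integration limits
#' @param rel_tol relative tolerance on the Simpson estimate
#' @param n0 initial (even) panel count
#' @param max_n panel cap; exceeding it without convergence is an error
#' @return the integral estimate (scalar)
#' @keywords internal
.simpson_adapt <- function(f, a, b, rel_tol = 1e-8, n0 = 64L, max_n = 2^21) {
  stopifnot(is.finite(a), is.finite(b), b > a)
  n <- as.integer(n0)
  x <- seq(a, b, length.out = n + 1L)
  y <- f(x)
  h <- (b - a) / n
  S <- h / 3 * (y[1] + y[n + 1] + 4 * sum(y[seq(2, n, 2)]) + 2 * sum(y[seq(3, n - 1, 2)]))
  repeat {
    ym <- f(seq(a + h / 2, b - h / 2, by = h))
    yy <- numeric(2L * n + 1L)
    yy[seq(1L, 2L * n + 1L, 2L)] <- y
    yy[seq(2L, 2L * n, 2L)] <- ym
    n <- 2L * n
    h <- h / 2
    y <- yy
    S2 <- h / 3 * (y[1] + y[n + 1] + 4 * sum(y[seq(2, n, 2)]) + 2 * sum(y[seq(3, n - 1, 2)]))
    if (abs(S2 - S) <= rel_tol * abs(S2)) return(S2 + (S2 - S) / 15)
    if (n >= max_n) stop("quadrature did not converge to rel_tol = ", rel_tol)
    S <- S2
  }
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
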