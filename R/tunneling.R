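#' Specify a one-dimensional barrier for tunneling corrections
#'
#' Bundles the quantities that define the hydrogen-atom-transfer barrier:
#' forward and reverse barrier heights, the magnitude of the transition-state
#' imaginary-mode wavenumber, the temperature, and the transferring-particle
#' mass. These are the inputs of the Eckart and Bell transmission treatments.
#'
#' The reverse barrier defaults to the forward one (symmetric barrier): the
#' product-side asymptote of a hydrogen-abstraction step is rarely tabulated,
#' and the symmetric form is the single-parameter choice that is conservative
#' for consistency checks on the implied imaginary frequency.
#'
#' @param V_forward forward barrier height, kcal/mol (> 0)
#' @param V_reverse reverse barrier height, kcal/mol; default `V_forward`
#' @param nu_imag magnitude of the imaginary-mode wavenumber, cm^-1 (> 0)
#' @param temp temperature, K (> 0)
#' @param mass transferring-particle mass, unified atomic mass units;
#'   default 1.00783 (1H)
#' @return an object of class `barrier_spec`
#' @examples
#' barrier_spec(20, nu_imag = 2800, temp = 333.15)
#' @export
barrier_spec <- function(V_forward, V_reverse = V_forward, nu_imag,
                         temp, mass = 1.00783) {
  for (nm in c("V_forward", "V_reverse", "nu_imag", "temp", "mass")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single positive finite number")
  }
  structure(list(V_forward = V_forward, V_reverse = V_reverse,
                 nu_imag = nu_imag, temp = temp, mass = mass),
            class = "barrier_spec")
}

#' @export
print.barrier_spec <- function(x, ...) {
  cat(sprintf(
    "Barrier spec: Vf = %.3f, Vr = %.3f kcal/mol; nu = %.1f cm^-1; T = %.2f K; m = %.5f u\n",
    x$V_forward, x$V_reverse, x$nu_imag, x$temp, x$mass))
  cat(sprintf("  reduced frequency u = hc*nu/(kB*T) = %.4f\n",
              .HC_KB * x$nu_imag / x$temp))
  invisible(x)
}

# dimensionless Eckart parameters of the Johnston-Heicklen closed form
.eckart_params <- function(spec) {
  a1 <- 2 * pi * spec$V_forward * .KCAL_CM / spec$nu_imag
  a2 <- 2 * pi * spec$V_reverse * .KCAL_CM / spec$nu_imag
  list(u = .HC_KB * spec$nu_imag / spec$temp, alpha1 = a1, alpha2 = a2,
       darg = a1 * a2 - pi^2 / 4)   # (2*pi*d/2)^2; negative => oscillatory d-branch
}

# log T(E), vectorized over E (kcal/mol, measured from the reactant asymptote).
# Returns -Inf where no channel is open (E <= 0 or below the product asymptote).
.log_eckart_T <- function(E, spec) {
  p <- .eckart_params(spec)
  xi <- E / spec$V_forward
  barg <- (xi - 1) * p$alpha1 + p$alpha2
  den <- 1 / sqrt(p$alpha1) + 1 / sqrt(p$alpha2)
  tpa <- 2 * sqrt(pmax(p$alpha1 * xi, 0)) / den
  tpb <- 2 * sqrt(pmax(barg, 0)) / den
  if (p$darg >= 0) {
    tpd <- 2 * sqrt(p$darg)
    v <- log(-expm1(.logadd(.logcosh(tpa - tpb), .logcosh(tpd)) -
                    .logadd(.logcosh(tpa + tpb), .logcosh(tpd))))
  } else {
    cd <- cos(2 * sqrt(-p$darg))
    v <- log1p(-(cosh(tpa - tpb) + cd) / (cosh(tpa + tpb) + cd))
  }
  out <- rep(-Inf, length(E))
  ok <- E > 0 & barg >= 0
  out[ok] <- v[ok]
  out
}

#' Eckart barrier transmission probability
#'
#' Evaluates the exact transmission probability T(E) through an (a)symmetric
#' Eckart barrier, in the dimensionless Johnston-Heicklen closed form
#' parameterized by `alpha1 = 2*pi*V_f/(hc*nu)`, `alpha2 = 2*pi*V_r/(hc*nu)`
#' and `xi = E/V_f`. Hyperbolic cosines are evaluated in log space, so the
#' deep-tunneling regime never overflows to NaN. Below the higher of the two
#' asymptotes no scattering channel is open and T = 0.
#'
#' @param E energy above the reactant asymptote, kcal/mol (vectorized, >= 0)
#' @param spec a [barrier_spec()]
#' @return transmission probabilities in `[0, 1]`
#' @examples
#' sp <- barrier_spec(20, nu_imag = 2800, temp = 333.15)
#' eckart_transmission(c(0, 10, 20, 40), sp)
#' @export
eckart_transmission <- function(E, spec) {
  stopifnot(inherits(spec, "barrier_spec"))
  if (!is.numeric(E) || any(!is.finite(E)))
    stop("'E' must be finite numeric (kcal/mol)")
  if (any(E < 0))
    stop("'E' must be non-negative: energies are measured from the reactant asymptote")
  exp(.log_eckart_T(E, spec))
}

.kappa_result <- function(kappa, method, spec_Vf, temp, u, warnings = character()) {
  structure(list(kappa = kappa, method = method,
                 effective_barrier = spec_Vf - .RGAS * temp * log(kappa),
                 u = u, warnings = warnings),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("kappa(%s) = %.6g  (u = %.3f)\n", x$method, x$kappa, x$u))
  cat(sprintf("  effective barrier = %.3f kcal/mol\n", x$effective_barrier))
  for (w in x$warnings) cat("  note: ", w, "\n", sep = "")
  invisible(x)
}

#' Thermal Eckart tunneling transmission coefficient
#'
#' Computes `kappa(T) = exp(Vf/kBT) / kBT * integral_0^Inf T(E) exp(-E/kBT) dE`,
#' the Boltzmann average of the Eckart transmission probability relative to
#' classical barrier crossing. The integral is evaluated to relative
#' tolerance 1e-8 in the reduced variable `eps = E/kBT` after substituting
#' `eps = t^2` (which removes the sqrt(E) edge of T at the origin); the
#' cutoff `Vf/kBT + cutoff` leaves the result unchanged once `cutoff >= 40`
#' (doubling it is a documented no-op at the quadrature tolerance).
#'
#' @param spec a [barrier_spec()]
#' @param cutoff upper limit of the reduced-energy integral beyond the
#'   barrier top, in units of kBT; default 40
#' @return a `kappa_result` with fields `kappa`, `method`,
#'   `effective_barrier` (kcal/mol), `u`
#' @examples
#' kappa_eckart(barrier_spec(20, nu_imag = 2800, temp = 333.15))
#' @export
kappa_eckart <- function(spec, cutoff = 40) {
  stopifnot(inherits(spec, "barrier_spec"))
  u <- .HC_KB * spec$nu_imag / spec$temp
  if (u > 60)
    stop("deep-tunneling regime outside validated domain (u = ",
         sprintf("%.1f", u), " > 60)")
  if (u < 0.02) {
    # the transmission is a near-step of width u/(2*pi) in the reduced
    # energy; here the thermal average equals the small-u expansion
    # 1 + u^2/24 to double precision (next term is O(u^4))
    return(.kappa_result(1 + u^2 / 24, "eckart", spec$V_forward,
                         spec$temp, u))
  }
  aT <- spec$V_forward / (.RGAS * spec$temp)
  f <- function(t) {
    e <- t * t
    v <- aT - e + .log_eckart_T(e * .RGAS * spec$temp, spec)
    ifelse(is.finite(v), 2 * t * exp(v), 0)
  }
  kap <- tryCatch(
    # split at the barrier top, where the integrand's rise is sharpest
    .simpson_adapt(f, 0, sqrt(aT), rel_tol = 1e-8) +
      .simpson_adapt(f, sqrt(aT), sqrt(aT + cutoff), rel_tol = 1e-8),
    error = function(e) stop(
      "quadrature non-convergence for barrier spec (Vf = ", spec$V_forward,
      ", Vr = ", spec$V_reverse, ", nu = ", spec$nu_imag,
      ", T = ", spec$temp, "): ", conditionMessage(e)))
  .kappa_result(kap, "eckart", spec$V_forward, spec$temp, u)
}

# Boltzmann average of the Kemble parabolic transmission
# 1/(1 + exp(2*pi*(V-E)/(hc*nu))), barrier truncated at its base (E >= 0).
.kappa_kemble_integral <- function(V_forward, nu_imag, temp) {
  u <- .HC_KB * nu_imag / temp
  al <- V_forward / (.RGAS * temp)
  f <- function(eps) exp(al - eps - log1p(exp(2 * pi * (al - eps) / u)))
  .simpson_adapt(f, 0, al + 40, rel_tol = 1e-10)
}

#' Bell truncated-parabola tunneling correction
#'
#' Analytic Bell series for the thermal tunneling correction of a parabolic
#' barrier truncated at its base:
#' `kappa = (u/2)/sin(u/2) + sum_n (-1)^n * u/(2*n*pi - u) * exp(alpha*(1 - 2*n*pi/u))`
#' with `u = hc*nu/(kB*T)` and `alpha = V/(kB*T)`; the series is summed until
#' the term magnitude drops below 1e-12. Within 0.1 of a pole `u = 2*n*pi`
#' the series is ill-conditioned and the equivalent numerical Boltzmann
#' integral of the Kemble transmission is substituted (flagged in the result).
#'
#' @param V_forward barrier height, kcal/mol
#' @param nu_imag imaginary-mode wavenumber magnitude, cm^-1
#' @param temp temperature, K
#' @return a `kappa_result` (method `"bell"`)
#' @examples
#' kappa_bell(20, 2800, 333.15)
#' @export
kappa_bell <- function(V_forward, nu_imag, temp) {
  if (any(c(V_forward, nu_imag, temp) <= 0) ||
      any(!is.finite(c(V_forward, nu_imag, temp))))
    stop("all inputs must be positive and finite")
  u <- .HC_KB * nu_imag / temp
  al <- V_forward / (.RGAS * temp)
  npole <- round(u / (2 * pi))
  warn <- character()
  if (npole >= 1 && abs(u - 2 * npole * pi) < 0.1) {
    kap <- .kappa_kemble_integral(V_forward, nu_imag, temp)
    warn <- sprintf(
      "u = %.4f within 0.1 of the Bell pole 2*%d*pi; numerical integral substituted",
      u, npole)
  } else {
    kap <- (u / 2) / sin(u / 2)
    for (n in seq_len(2000L)) {
      tn <- (-1)^n * u / (2 * n * pi - u) * exp(al * (1 - 2 * n * pi / u))
      kap <- kap + tn
      if (abs(tn) < 1e-12) break
    }
  }
  .kappa_result(kap, "bell", V_forward, temp, u, warn)
}

#' Wigner tunneling correction
#'
#' Leading-order correction `kappa = 1 + u^2/24`, `u = hc*nu/(kB*T)`.
#' Exact closed form; baseline comparator for the Eckart and Bell results.
#'
#' @inheritParams kappa_bell
#' @param V_forward barrier height, kcal/mol, used only to report the
#'   effective barrier; default `NA` reports `NA` there
#' @return a `kappa_result` (method `"wigner"`)
#' @export
kappa_wigner <- function(nu_imag, temp, V_forward = NA_real_) {
  if (any(c(nu_imag, temp) <= 0) || any(!is.finite(c(nu_imag, temp))))
    stop("all inputs must be positive and finite")
  u <- .HC_KB * nu_imag / temp
  .kappa_result(1 + u^2 / 24, "wigner", V_forward, temp, u)
}

#' Tunneling-corrected effective barrier
#'
#' `V_eff = V_forward - R*T*ln(kappa)`: the barrier a purely classical rate
#' expression would need in order to reproduce the tunneling-corrected rate.
#'
#' @param spec a [barrier_spec()]
#' @param kappa transmission coefficient (> 0), or a `kappa_result`
#' @return effective barrier, kcal/mol
#' @export
effective_barrier <- function(spec, kappa) {
  stopifnot(inherits(spec, "barrier_spec"))
  if (inherits(kappa, "kappa_result")) kappa <- kappa$kappa
  if (!is.numeric(kappa) || any(!is.finite(kappa)) || any(kappa <= 0))
    stop("'kappa' must be positive and finite")
  spec$V_forward - .RGAS * spec$temp * log(kappa)
}

.kappa_by_model <- function(model, V_forward, V_reverse, nu, temp, mass) {
  switch(model,
    "eckart-symmetric" = kappa_eckart(
      barrier_spec(V_forward, V_forward, nu, temp, mass)),
    "eckart" = kappa_eckart(
      barrier_spec(V_forward, V_reverse, nu, temp, mass)),
    "bell" = kappa_bell(V_forward, nu, temp),
    "wigner" = kappa_wigner(nu, temp, V_forward),
    stop("unknown model '", model, "'"))
}

#' Invert the tunneling correction for the imaginary wavenumber
#'
#' Finds the imaginary-mode wavenumber whose tunneling correction reduces
#' `V_forward` to a stated effective barrier, by bracketing search on
#' `[bracket[1], bracket[2]]` cm^-1 to 1 cm^-1. This is the consistency check
#' between a printed pair (barrier, tunneling-corrected barrier) and the
#' transition state's imaginary frequency: a large implied wavenumber means
#' the stated reduction requires a narrow barrier.
#'
#' @param V_forward uncorrected barrier, kcal/mol
#' @param V_effective tunneling-corrected barrier, kcal/mol
#'   (`0 < V_effective <= V_forward`)
#' @param temp temperature, K
#' @param model `"eckart-symmetric"` (default), `"eckart"` (supply
#'   `V_reverse`), or `"bell"`
#' @param V_reverse reverse barrier for the asymmetric Eckart model
#' @param mass transferring-particle mass, amu
#' @param bracket search interval in cm^-1
#' @return the wavenumber in cm^-1; if no tunneling is needed
#'   (`V_effective` is reachable at the lower bracket edge) the lower edge is
#'   returned with attribute `note = "no tunneling required"`
#' @examples
#' invert_frequency(20.0, 9.6, 333.15)   # ThiH-like inversion
#' @export
invert_frequency <- function(V_forward, V_effective, temp,
                             model = c("eckart-symmetric", "eckart", "bell"),
                             V_reverse = NULL, mass = 1.00783,
                             bracket = c(50, 6000)) {
  model <- match.arg(model)
  if (!is.numeric(V_effective) || V_effective <= 0)
    stop("'V_effective' must be positive")
  if (V_effective > V_forward)
    stop("'V_effective' exceeds 'V_forward': kappa >= 1 cannot raise a barrier")
  if (model == "eckart" && is.null(V_reverse))
    stop("the asymmetric 'eckart' model needs 'V_reverse'")
  if (is.null(V_reverse)) V_reverse <- V_forward
  f <- function(nu) {
    kr <- .kappa_by_model(model, V_forward, V_reverse, nu, temp, mass)
    kr$effective_barrier - V_effective
  }
  flo <- f(bracket[1])
  if (flo <= 0) {
    out <- bracket[1]
    attr(out, "note") <- "no tunneling required"
    return(out)
  }
  fhi <- f(bracket[2])
  if (fhi > 0)
    stop(sprintf(
      "no root in [%g, %g] cm^-1: effective barrier is %.3f above target at the lower edge and %.3f at the upper edge",
      bracket[1], bracket[2], flo, fhi))
  stats::uniroot(f, interval = bracket, f.lower = flo, f.upper = fhi,
                 tol = 0.5)$root
}

#' Kinetic isotope effect of the tunneling correction
#'
#' Ratio `kappa(nu_H) / kappa(nu_D)` for substituting the transferring
#' particle by a heavier isotope at the same barrier and temperature. The
#' heavy-isotope wavenumber follows the 1-D oscillator scaling
#' `nu_D = nu_H * sqrt(m_light/m_heavy)`; reduced-mass coupling to heavy-atom
#' motion is not modeled. Large values are the classic signature of
#' hydrogen tunneling.
#'
#' @param spec a [barrier_spec()] for the light (default 1H) particle
#' @param heavy_mass heavier isotope mass, amu; default 2.0141 (2H)
#' @param model `"eckart"`, `"bell"`, or `"wigner"`
#' @return the dimensionless ratio (>= 1)
#' @export
kie <- function(spec, heavy_mass = 2.0141,
                model = c("eckart", "bell", "wigner")) {
  stopifnot(inherits(spec, "barrier_spec"))
  model <- match.arg(model)
  if (heavy_mass <= spec$mass)
    stop("'heavy_mass' must exceed the light mass ", spec$mass)
  nu_D <- spec$nu_imag * sqrt(spec$mass / heavy_mass)
  kH <- .kappa_by_model(if (model == "eckart") "eckart" else model,
                        spec$V_forward, spec$V_reverse, spec$nu_imag,
                        spec$temp, spec$mass)
  kD <- .kappa_by_model(if (model == "eckart") "eckart" else model,
                        spec$V_forward, spec$V_reverse, nu_D,
                        spec$temp, heavy_mass)
  kH$kappa / kD$kappa
}
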