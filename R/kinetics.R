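#' Tissue kinetic parameters
#'
#' The standard tracer-kinetic parameter pair: the volume transfer
#' coefficient Ktrans (per minute) and the extravascular extracellular
#' volume fraction ve (dimensionless). Their ratio kep = Ktrans / ve is the
#' efflux rate constant.
#'
#' @param ktrans Transfer coefficient, 1/min (>= 0).
#' @param ve Extravascular extracellular volume fraction, in (0, 1].
#' @return An object of class `tissue_kinetics`.
#' @examples
#' muscle <- tissue_kinetics(ktrans = 0.045, ve = 0.08)
#' @export
tissue_kinetics <- function(ktrans, ve) {
  stopifnot(is.numeric(ktrans), length(ktrans) == 1L,
            is.numeric(ve), length(ve) == 1L)
  if (ktrans < 0) stop("ktrans must be non-negative", call. = FALSE)
  if (ve <= 0 || ve > 1) stop("ve must lie in (0, 1]", call. = FALSE)
  structure(list(ktrans = ktrans, ve = ve), class = "tissue_kinetics")
}

#' @export
print.tissue_kinetics <- function(x, ...) {
  cat(sprintf("Ktrans = %.4g /min, ve = %.4g (kep = %.4g /min)\n",
              x$ktrans, x$ve, x$ktrans / x$ve))
  invisible(x)
}

# kep with a guard against ve = 0 (constructor forbids it, but arithmetic
# built from raw lists must not divide silently).
kep_of <- function(kinetics) {
  if (kinetics$ve <= 0) stop("ve must be positive", call. = FALSE)
  kinetics$ktrans / kinetics$ve
}

#' Arterial input function specification
#'
#' Parametric plasma concentration models for the synthetic-data generator
#' and the AIF-based validation fitter. The reference-region analysis itself
#' never uses an AIF; these forms exist so that the generator can produce
#' tissue curves and so that AIF-independence of the estimates can be
#' demonstrated.
#'
#' Two models are available:
#' \describe{
#'   \item{`biexponential`}{Weinmann-type plasma clearance
#'     \eqn{C_p(t') = D (a_1 e^{-m_1 t'} + a_2 e^{-m_2 t'})} for
#'     \eqn{t' = t - t_{arrival} \ge 0}, zero before arrival. Defaults
#'     \eqn{a_1 = 3.99, a_2 = 4.78} kg/L, \eqn{m_1 = 0.144, m_2 = 0.0111}
#'     per minute.}
#'   \item{`parker`}{Population mixed-Gaussian-plus-sigmoid form (two
#'     Gaussians plus an exponential modulated by a sigmoid), scaled
#'     linearly from its nominal 0.1 mmol/kg dose.}
#' }
#' An optional exponential dispersion kernel (time constant `dispersion_s`)
#' smooths the bolus, emulating injection-to-tissue transit.
#'
#' @param model `"biexponential"` or `"parker"`.
#' @param dose Injected dose, mmol/kg (> 0). The default 0.2 mmol/kg is a
#'   double dose.
#' @param arrival_time_s Bolus arrival time, s (>= 0).
#' @param a1,a2 Biexponential amplitudes, kg/L.
#' @param m1,m2 Biexponential decay rates, 1/min (> 0).
#' @param dispersion_s Exponential dispersion time constant, s (0 = none).
#' @return An object of class `aif_spec`.
#' @export
aif_spec <- function(model = c("biexponential", "parker"), dose = 0.2,
                     arrival_time_s = 0, a1 = 3.99, a2 = 4.78,
                     m1 = 0.144, m2 = 0.0111, dispersion_s = 0) {
  model <- match.arg(model)
  if (dose < 0) stop("dose must be non-negative", call. = FALSE)
  if (arrival_time_s < 0) stop("arrival_time_s must be >= 0", call. = FALSE)
  if (m1 <= 0 || m2 <= 0) stop("decay rates must be positive", call. = FALSE)
  if (dispersion_s < 0) stop("dispersion_s must be >= 0", call. = FALSE)
  structure(
    list(model = model, dose = dose, arrival_time_s = arrival_time_s,
         a1 = a1, a2 = a2, m1 = m1, m2 = m2, dispersion_s = dispersion_s),
    class = "aif_spec"
  )
}

#' Evaluate an arterial input function on a time grid
#'
#' @param spec An [aif_spec()].
#' @param times_min Sampling instants in minutes (strictly increasing).
#' @return A [dynamic_series()] of plasma concentration in mM with
#'   `time_unit = "min"`. Concentration is zero before the arrival time.
#' @examples
#' tt <- seq(0, 8, by = 13.32 / 60)
#' cp <- make_aif(aif_spec(arrival_time_s = 39.96), tt)
#' max(cp$values)  # bolus peak
#' @export
make_aif <- function(spec, times_min) {
  stopifnot(inherits(spec, "aif_spec"))
  t_rel <- times_min - spec$arrival_time_s / 60
  cp <- numeric(length(times_min))
  pos <- t_rel >= 0
  if (spec$model == "biexponential") {
    cp[pos] <- spec$dose * (spec$a1 * exp(-spec$m1 * t_rel[pos]) +
                            spec$a2 * exp(-spec$m2 * t_rel[pos]))
  } else {
    cp[pos] <- parker_aif(t_rel[pos]) * (spec$dose / 0.1)
  }
  if (spec$dispersion_s > 0) cp <- disperse(cp, times_min, spec$dispersion_s / 60)
  dynamic_series(times_min, cp, unit = "mM", time_unit = "min")
}

# Parker population AIF at nominal dose 0.1 mmol/kg; t in minutes from
# arrival. Two Gaussians plus sigmoid-gated exponential washout.
parker_aif <- function(t) {
  A <- c(0.809, 0.330); T0 <- c(0.17046, 0.365); s2 <- c(0.0563, 0.132)
  alpha <- 1.050; beta <- 0.1685; s <- 38.078; tau <- 0.483
  g <- A[1] / (s2[1] * sqrt(2 * pi)) * exp(-(t - T0[1])^2 / (2 * s2[1]^2)) +
       A[2] / (s2[2] * sqrt(2 * pi)) * exp(-(t - T0[2])^2 / (2 * s2[2]^2))
  g + alpha * exp(-beta * t) / (1 + exp(-s * (t - tau)))
}

# Exponential dispersion: convolve cp with (1/tau) exp(-t/tau) by
# trapezoidal quadrature on the given grid (tau in minutes).
disperse <- function(cp, times_min, tau_min) {
  conv <- convolver(times_min)
  conv(cp, 1 / tau_min) / tau_min
}

# Causal exponential-kernel convolution integrals on a fixed grid:
# returns f |-> { int_0^{T_j} f(t) exp(-rate (T_j - t)) dt }_j by
# trapezoidal quadrature. The input samples are linearly interpolated onto
# a grid refined by `refine` subdivisions per interval before integrating;
# refine = 1 integrates on the sampling nodes themselves. Refinement tames
# the O((rate dt)^2) kernel-curvature error at coarse frame spacings.
# Precomputes lag, weight and interpolation matrices once per grid.
convolver <- function(times, refine = 4L) {
  n <- length(times)
  refine <- as.integer(refine)
  if (n < 2L) return(function(f, rate) numeric(n))
  # refined grid: every interval split into `refine` equal parts
  tf <- unlist(lapply(seq_len(n - 1L), function(k) {
    times[k] + (times[k + 1L] - times[k]) * (seq_len(refine) - 1L) / refine
  }))
  tf <- c(tf, times[n])
  nf <- length(tf)
  node_idx <- (seq_len(n) - 1L) * refine + 1L   # positions of the nodes
  # linear interpolation matrix: ffine = interp %*% f
  interp <- matrix(0, nf, n)
  k <- pmin(findInterval(tf, times), n - 1L)
  a <- (tf - times[k]) / (times[k + 1L] - times[k])
  interp[cbind(seq_len(nf), k)] <- 1 - a
  interp[cbind(seq_len(nf), k + 1L)] <- interp[cbind(seq_len(nf), k + 1L)] + a
  # trapezoid weights of the fine grid truncated at each output node
  w <- matrix(0, n, nf)
  dtf <- diff(tf)
  for (j in 2:n) {
    m <- node_idx[j]
    wj <- numeric(m)
    wj[1] <- dtf[1] / 2
    wj[m] <- dtf[m - 1] / 2
    if (m > 2) wj[2:(m - 1)] <- (dtf[1:(m - 2)] + dtf[2:(m - 1)]) / 2
    w[j, seq_len(m)] <- wj
  }
  lag <- outer(times, tf, "-")   # [j, i] = T_j - tfine_i
  lag[lag < 0] <- 0              # acausal part carries zero weight
  function(f, rate) {
    if (length(f) != n) stop("grid mismatch in convolution", call. = FALSE)
    as.vector((exp(-rate * lag) * w) %*% (interp %*% f))
  }
}
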