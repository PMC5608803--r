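#' Steady-state spoiled gradient-echo (FLASH) signal
#'
#' Forward signal model of an ideally spoiled gradient echo:
#' \deqn{S = M_0 \sin\theta \, (1 - E_1) / (1 - E_1 \cos\theta), \quad
#'       E_1 = e^{-TR/T_1}.}
#' `m0_eff` is the effective equilibrium signal scale; it absorbs proton
#' density, coil sensitivity and echo-time decay, none of which the
#' relaxation analysis needs to separate.
#'
#' @param m0_eff Effective equilibrium signal scale (arbitrary units).
#' @param t1_ms Longitudinal relaxation time, ms (> 0); vectorised.
#' @param tr_ms Repetition time, ms (> 0).
#' @param fa_deg Flip angle, degrees, in (0, 90].
#' @return Signal value(s), same length as `t1_ms`; strictly positive for
#'   finite `t1_ms`.
#' @examples
#' flash_signal(1000, t1_ms = 1000, tr_ms = 8.09, fa_deg = 30)
#' @export
flash_signal <- function(m0_eff, t1_ms, tr_ms, fa_deg) {
  if (any(t1_ms <= 0)) stop("t1_ms must be positive", call. = FALSE)
  if (tr_ms <= 0) stop("tr_ms must be positive", call. = FALSE)
  if (fa_deg <= 0 || fa_deg > 90)
    stop("fa_deg must lie in (0, 90]", call. = FALSE)
  th <- fa_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  m0_eff * sin(th) * (1 - e1) / (1 - e1 * cos(th))
}

#' Dynamic T1 estimation from a proton-density reference scan
#'
#' Inverts the FLASH steady-state equation frame by frame using a single
#' low-flip-angle, long-TR reference acquisition in place of a
#' variable-flip-angle series:
#' \deqn{T_1(t) = -TR_{DCE} \Big/ \ln\!\frac{S_{REF}\sin\theta_{DCE} -
#'   S_{DCE}(t)\sin\theta_{REF}}{S_{REF}\sin\theta_{DCE} -
#'   S_{DCE}(t)\sin\theta_{REF}\cos\theta_{DCE}}.}
#' The inversion assumes the reference signal is proportional to the
#' equilibrium magnetisation times \eqn{\sin\theta_{REF}}; with a finite
#' reference TR this holds only approximately and produces a deterministic,
#' monotone bias (see the package vignette). Frames where the logarithm's
#' argument falls outside (0, 1) have no finite positive T1 and are marked
#' invalid rather than returned as numbers; if every frame is invalid the
#' series is returned fully flagged, without an error.
#'
#' @param s_ref Scalar reference-scan signal (> 0).
#' @param s_dce A [dynamic_series()] of dynamic signals (values >= 0).
#' @param protocol An [acquisition_protocol()].
#' @return A [dynamic_series()] of T1 in ms on the same time grid.
#' @export
estimate_t1 <- function(s_ref, s_dce, protocol) {
  stopifnot(inherits(s_dce, "dynamic_series"),
            inherits(protocol, "acquisition_protocol"))
  if (!is.numeric(s_ref) || length(s_ref) != 1L || s_ref <= 0)
    stop("s_ref must be a positive scalar", call. = FALSE)
  if (any(s_dce$values[s_dce$valid] < 0))
    stop("dynamic signals must be non-negative", call. = FALSE)
  th_ref <- protocol$fa_ref_deg * pi / 180
  th_dce <- protocol$fa_dce_deg * pi / 180
  num <- s_ref * sin(th_dce) - s_dce$values * sin(th_ref)
  den <- s_ref * sin(th_dce) - s_dce$values * sin(th_ref) * cos(th_dce)
  arg <- num / den
  ok <- s_dce$valid & is.finite(arg) & arg > 0 & arg < 1
  t1 <- rep(NA_real_, length(arg))
  t1[ok] <- -protocol$tr_dce_ms / log(arg[ok])
  dynamic_series(s_dce$times, t1, valid = ok, unit = "ms",
                 time_unit = s_dce$time_unit)
}

#' Relaxation rate R1 = 1/T1
#'
#' Valuewise reciprocal with ms-to-s conversion; validity flags propagate.
#'
#' @param t1_series A [dynamic_series()] of T1 in ms.
#' @return A [dynamic_series()] of R1 in 1/s.
#' @examples
#' r1_from_t1(dynamic_series(0, 1000, unit = "ms"))$values  # 1 /s
#' @export
r1_from_t1 <- function(t1_series) {
  stopifnot(inherits(t1_series, "dynamic_series"))
  ok <- t1_series$valid & is.finite(t1_series$values) & t1_series$values > 0
  r1 <- rep(NA_real_, length(t1_series$values))
  r1[ok] <- 1000 / t1_series$values[ok]
  dynamic_series(t1_series$times, r1, valid = ok, unit = "1/s",
                 time_unit = t1_series$time_unit)
}

#' Pre-contrast relaxation rate from baseline frames
#'
#' The native (pre-contrast) relaxation rate R10 is the arithmetic mean of
#' the valid R1 samples over the first `n_baseline` frames. Averaging is
#' done in rate space, where the reference-region model operates.
#'
#' @param r1_series A [dynamic_series()] of R1 in 1/s.
#' @param n_baseline Number of pre-contrast frames to average.
#' @return A list of class `relaxation_state` with elements `r10` (1/s;
#'   `NA` on failure), `n_used` (valid baseline frames averaged) and `ok`.
#'   No valid baseline sample yields a flagged failure, not an error.
#' @export
estimate_r10 <- function(r1_series, n_baseline) {
  stopifnot(inherits(r1_series, "dynamic_series"))
  n_baseline <- as.integer(n_baseline)
  if (n_baseline < 1L || n_baseline > length(r1_series$times))
    stop("n_baseline out of range", call. = FALSE)
  idx <- seq_len(n_baseline)
  ok <- r1_series$valid[idx]
  vals <- r1_series$values[idx][ok]
  structure(
    list(r10 = if (length(vals)) mean(vals) else NA_real_,
         n_used = length(vals), ok = length(vals) > 0L),
    class = "relaxation_state"
  )
}

#' @export
print.relaxation_state <- function(x, ...) {
  if (x$ok)
    cat(sprintf("R10 = %.4g 1/s (mean of %d baseline frames)\n",
                x$r10, x$n_used))
  else
    cat("R10 estimation failed: no valid baseline sample\n")
  invisible(x)
}

# Ratio of the Rayleigh-distributed background standard deviation to the
# per-channel Gaussian sigma, sqrt((4 - pi)/2), rounded as conventionally
# applied in magnitude-image SNR reporting.
RAYLEIGH_SD_FACTOR <- 0.655

#' Rayleigh-corrected signal-to-noise ratio
#'
#' Magnitude-image background noise follows a Rayleigh distribution whose
#' standard deviation underestimates the per-channel Gaussian sigma by a
#' factor of about 0.655. The SNR of a tissue region is therefore
#' \deqn{SNR = \mu_{signal} / \sigma_{corr}, \quad
#'       \sigma_{corr} = \sigma_{Rayleigh} / 0.655.}
#'
#' @param mu_signal Mean signal of the tissue region.
#' @param sigma_rayleigh Standard deviation measured in a background
#'   (signal-free) region (> 0).
#' @return The SNR value.
#' @examples
#' snr(65.5, 6.55)  # sigma_corr = 10, SNR = 6.55
#' @export
snr <- function(mu_signal, sigma_rayleigh) {
  if (!is.numeric(sigma_rayleigh) || any(sigma_rayleigh <= 0))
    stop("sigma_rayleigh must be positive", call. = FALSE)
  mu_signal / (sigma_rayleigh / RAYLEIGH_SD_FACTOR)
}
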