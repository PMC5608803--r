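#' Control parameters for the kinetic least-squares fits
#'
#' @param init Starting values `c(ktrans, ve)`; default (0.1 /min, 0.2).
#' @param lower,upper Box bounds on `c(ktrans, ve)`; defaults span the
#'   physiological range, Ktrans in \[1e-5, 5\] /min, ve in \[1e-3, 1\].
#' @param ftol Relative convergence tolerance on the sum of squares.
#' @param maxiter Iteration cap.
#' @return A list of class `rrm_control`.
#' @export
rrm_control <- function(init = c(0.1, 0.2), lower = c(1e-5, 1e-3),
                        upper = c(5, 1), ftol = 1e-8, maxiter = 500L) {
  stopifnot(length(init) == 2L, length(lower) == 2L, length(upper) == 2L,
            all(lower < upper), all(init >= lower), all(init <= upper),
            ftol > 0, maxiter >= 1L)
  structure(list(init = as.numeric(init), lower = as.numeric(lower),
                 upper = as.numeric(upper), ftol = ftol,
                 maxiter = as.integer(maxiter)),
            class = "rrm_control")
}

#' Reference-region forward model
#'
#' Maps the relaxation-rate course of the reference region onto the tissue
#' of interest without an arterial input function:
#' \deqn{R_{1,TOI}(T) = R\,[R_{1,RR}(T) - R_{10,RR}]
#'   + R\,[K^{trans,RR}/v_{e,RR} - K^{trans,TOI}/v_{e,TOI}]
#'   \int_0^T [R_{1,RR}(t) - R_{10,RR}]\,
#'   e^{-(K^{trans,TOI}/v_{e,TOI})(T-t)} dt + R_{10,TOI},}
#' with \eqn{R = K^{trans,TOI}/K^{trans,RR}}. The integral is evaluated by
#' trapezoidal quadrature on the sampling grid with time in minutes;
#' relaxation rates stay in 1/s (the model is linear in the rates, so the
#' mixed units cancel everywhere except inside the exponential, where the
#' conversion is explicit).
#'
#' @param r1_rr A [dynamic_series()] of reference-region R1, 1/s.
#' @param r10_rr,r10_toi Pre-contrast relaxation rates, 1/s.
#' @param kinetics_toi,kinetics_rr [tissue_kinetics()] of the tissue of
#'   interest and the reference region.
#' @return A [dynamic_series()] of tissue-of-interest R1, 1/s.
#' @export
rrm_forward <- function(r1_rr, r10_rr, r10_toi, kinetics_toi, kinetics_rr) {
  stopifnot(inherits(r1_rr, "dynamic_series"),
            inherits(kinetics_toi, "tissue_kinetics"),
            inherits(kinetics_rr, "tissue_kinetics"))
  kep_toi <- kep_of(kinetics_toi)
  kep_rr <- kep_of(kinetics_rr)
  if (kinetics_rr$ktrans <= 0)
    stop("reference-region ktrans must be positive", call. = FALSE)
  ratio <- kinetics_toi$ktrans / kinetics_rr$ktrans
  conv <- convolver(times_min(r1_rr))
  delta <- r1_rr$values - r10_rr
  vals <- ratio * delta +
    ratio * (kep_rr - kep_toi) * conv(delta, kep_toi) + r10_toi
  dynamic_series(r1_rr$times, vals, valid = r1_rr$valid, unit = "1/s",
                 time_unit = r1_rr$time_unit)
}

#' Fit the reference-region model to a tissue relaxation-rate curve
#'
#' The central estimator of the package: identifies the tissue of
#' interest's transfer coefficient Ktrans and extravascular extracellular
#' volume fraction ve by bounded Levenberg-Marquardt least squares on the
#' reference-region forward model ([rrm_forward()]), holding the reference
#' region's kinetics fixed at literature values (default skeletal muscle,
#' Ktrans = 0.045 /min, ve = 0.08). The fit has exactly two free
#' parameters; the amplitude ratio `R = Ktrans_TOI / Ktrans_RR` is derived,
#' never free.
#'
#' Samples flagged invalid in either curve are excluded from the residual.
#' Fewer than 10 valid common samples yields a flagged, non-converged
#' result rather than an error. If the tissue curve's enhancement peak is
#' below 3 times its baseline noise level (standard deviation of the
#' pre-peak baseline samples), the result carries a `"low_enhancement"`
#' flag: the estimate is returned but should not be trusted.
#'
#' @param r1_toi A [dynamic_series()] of tissue-of-interest R1, 1/s.
#' @param r1_rr A [dynamic_series()] of reference-region R1 on the same
#'   time grid, 1/s.
#' @param r10_toi,r10_rr Pre-contrast relaxation rates, 1/s (scalars or
#'   `relaxation_state` objects from [estimate_r10()]).
#' @param kinetics_rr Fixed reference-region kinetics.
#' @param control A [rrm_control()] list.
#' @param n_baseline Baseline frames used for the enhancement-to-noise
#'   check; default 3.
#' @return An object of class `rrm_fit`; see Details. Methods:
#'   [print()], [summary()], [coef()], [predict()], [fitted()],
#'   [residuals()], [plot()].
#' @details The returned object is a list with components
#'   `kinetics` (the fitted [tissue_kinetics()]), `ratio_R`
#'   (`kinetics$ktrans / kinetics_rr$ktrans`), `residual` (root-mean-square
#'   misfit in 1/s), `converged`, `n_iter`, `flags` (character vector;
#'   possible values `"low_enhancement"`, `"too_few_samples"`),
#'   `fitted_series`, the input data and the call.
#' @examples
#' tt <- seq(0, 13.32 * 39, by = 13.32)
#' cp <- make_aif(aif_spec(arrival_time_s = 39.96), tt / 60)
#' muscle <- tissue_kinetics(0.045, 0.08)
#' r1_rr <- concentration_to_r1(tofts_concentration(cp, muscle), r10 = 0.82)
#' r1_rr$times <- tt; r1_rr$time_unit <- "s"
#' fit <- fit_rrm(r1_rr, r1_rr, r10_toi = 0.82, r10_rr = 0.82)
#' coef(fit)  # recovers the muscle parameters
#' @export
fit_rrm <- function(r1_toi, r1_rr, r10_toi, r10_rr,
                    kinetics_rr = tissue_kinetics(0.045, 0.08),
                    control = rrm_control(), n_baseline = 3L) {
  stopifnot(inherits(r1_toi, "dynamic_series"),
            inherits(r1_rr, "dynamic_series"),
            inherits(kinetics_rr, "tissue_kinetics"),
            inherits(control, "rrm_control"))
  if (inherits(r10_toi, "relaxation_state")) r10_toi <- r10_toi$r10
  if (inherits(r10_rr, "relaxation_state")) r10_rr <- r10_rr$r10
  if (!is.finite(r10_toi) || !is.finite(r10_rr))
    stop("pre-contrast relaxation rates must be finite", call. = FALSE)
  if (length(r1_toi) != length(r1_rr) ||
      any(abs(r1_toi$times - r1_rr$times) > 1e-9 * max(r1_toi$times, 1)))
    stop("r1_toi and r1_rr must share one sampling grid", call. = FALSE)

  cl <- match.call()
  ok <- r1_toi$valid & r1_rr$valid
  flags <- character(0)
  if (sum(ok) < 10L) {
    res <- list(kinetics = NULL, ratio_R = NA_real_, residual = NA_real_,
                converged = FALSE, n_iter = 0L,
                flags = "too_few_samples", fitted_series = NULL,
                data = list(r1_toi = r1_toi, r1_rr = r1_rr,
                            r10_toi = r10_toi, r10_rr = r10_rr),
                kinetics_rr = kinetics_rr, control = control, call = cl)
    return(structure(res, class = "rrm_fit"))
  }

  # enhancement-to-noise screen on the tissue curve
  base_idx <- seq_len(min(n_baseline, length(r1_toi)))
  base_vals <- r1_toi$values[base_idx][r1_toi$valid[base_idx]]
  noise_sd <- if (length(base_vals) >= 2L) stats::sd(base_vals) else 0
  peak_enh <- max(r1_toi$values[ok]) - r10_toi
  if (noise_sd > 0 && peak_enh < 3 * noise_sd)
    flags <- c(flags, "low_enhancement")

  kep_rr <- kep_of(kinetics_rr)
  conv <- convolver(times_min(r1_rr))
  delta <- r1_rr$values - r10_rr
  delta[!r1_rr$valid] <- 0  # masked samples contribute nothing new; the
                            # residual is evaluated on valid samples only
  obs <- r1_toi$values
  resid_fn <- function(par) {
    ratio <- par[1] / kinetics_rr$ktrans
    kep_toi <- par[1] / par[2]
    pred <- ratio * delta + ratio * (kep_rr - kep_toi) *
      conv(delta, kep_toi) + r10_toi
    (pred - obs)[ok]
  }
  fit <- minpack.lm::nls.lm(
    par = control$init, lower = control$lower, upper = control$upper,
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      ftol = control$ftol, maxiter = control$maxiter))

  kin <- tissue_kinetics(fit$par[1], fit$par[2])
  fitted_series <- rrm_forward(r1_rr, r10_rr, r10_toi, kin, kinetics_rr)
  res <- list(
    kinetics = kin,
    ratio_R = kin$ktrans / kinetics_rr$ktrans,
    residual = sqrt(mean(fit$fvec^2)),
    converged = fit$info %in% 1:4,
    n_iter = fit$niter,
    flags = flags,
    fitted_series = fitted_series,
    data = list(r1_toi = r1_toi, r1_rr = r1_rr,
                r10_toi = r10_toi, r10_rr = r10_rr),
    kinetics_rr = kinetics_rr, control = control, call = cl
  )
  structure(res, class = "rrm_fit")
}

#' @export
print.rrm_fit <- function(x, ...) {
  cat("Reference-region model fit\n")
  if (is.null(x$kinetics)) {
    cat("  failed:", paste(x$flags, collapse = ", "), "\n")
    return(invisible(x))
  }
  cat(sprintf("  Ktrans = %.4g /min   ve = %.4g   (R = %.4g)\n",
              x$kinetics$ktrans, x$kinetics$ve, x$ratio_R))
  cat(sprintf("  RMS residual = %.3g /s, converged = %s (%d iterations)\n",
              x$residual, x$converged, x$n_iter))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.rrm_fit <- function(object, ...) {
  if (is.null(object$kinetics)) return(c(ktrans = NA_real_, ve = NA_real_))
  c(ktrans = object$kinetics$ktrans, ve = object$kinetics$ve)
}

#' @export
fitted.rrm_fit <- function(object, ...) object$fitted_series

#' @export
residuals.rrm_fit <- function(object, ...) {
  if (is.null(object$fitted_series)) return(numeric(0))
  ok <- object$data$r1_toi$valid & object$fitted_series$valid
  r <- object$data$r1_toi$values - object$fitted_series$values
  r[!ok] <- NA_real_
  r
}

#' Predict a tissue relaxation-rate curve from a fitted reference-region model
#'
#' Evaluates the forward model at the fitted kinetics, by default on the
#' training reference curve, or on a new reference-region curve.
#'
#' @param object An `rrm_fit`.
#' @param r1_rr Optional new reference-region [dynamic_series()].
#' @param r10_rr,r10_toi Optional pre-contrast rates for the new curve.
#' @param ... Unused.
#' @return A [dynamic_series()] of predicted R1, 1/s.
#' @export
predict.rrm_fit <- function(object, r1_rr = NULL, r10_rr = NULL,
                            r10_toi = NULL, ...) {
  if (is.null(object$kinetics)) stop("fit failed; nothing to predict",
                                     call. = FALSE)
  if (is.null(r1_rr)) return(object$fitted_series)
  rrm_forward(r1_rr,
              r10_rr = if (is.null(r10_rr)) object$data$r10_rr else r10_rr,
              r10_toi = if (is.null(r10_toi)) object$data$r10_toi else r10_toi,
              kinetics_toi = object$kinetics,
              kinetics_rr = object$kinetics_rr)
}

#' @export
summary.rrm_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.rrm_fit")
}

#' @export
print.summary.rrm_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  if (!is.null(f$kinetics)) {
    cat(sprintf("  reference region: Ktrans = %.4g /min, ve = %.4g (fixed)\n",
                f$kinetics_rr$ktrans, f$kinetics_rr$ve))
    cat(sprintf("  R10 (TOI / RR) = %.4g / %.4g 1/s\n",
                f$data$r10_toi, f$data$r10_rr))
    cat(sprintf("  samples used = %d of %d\n",
                sum(f$data$r1_toi$valid & f$data$r1_rr$valid),
                length(f$data$r1_toi)))
  }
  invisible(x)
}

#' Plot a reference-region model fit
#'
#' Observed tissue-of-interest R1 against time, with the fitted forward
#' model overlaid and the reference-region curve for context.
#'
#' @param x An `rrm_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rrm_fit <- function(x, ...) {
  if (is.null(x$fitted_series)) stop("fit failed; nothing to plot",
                                     call. = FALSE)
  toi <- x$data$r1_toi
  rr <- x$data$r1_rr
  graphics::plot(toi$times, toi$values, pch = 16, cex = 0.7,
                 xlab = sprintf("time [%s]", toi$time_unit),
                 ylab = "R1 [1/s]", ...)
  graphics::lines(x$fitted_series$times, x$fitted_series$values,
                  col = "firebrick", lwd = 2)
  graphics::lines(rr$times, rr$values, col = "grey50", lty = 2)
  graphics::legend("bottomright",
                   legend = c("tissue of interest", "RRM fit",
                              "reference region"),
                   pch = c(16, NA, NA), lty = c(NA, 1, 2),
                   col = c("black", "firebrick", "grey50"), bty = "n")
  invisible(x)
}
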