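#' Tofts tissue concentration from a plasma input
#'
#' Standard (two-parameter) Tofts model:
#' \deqn{C_t(T) = K^{trans} \int_0^T C_p(t)\,
#'   e^{-(K^{trans}/v_e)(T - t)}\, dt,}
#' evaluated by trapezoidal quadrature on the sampling grid with time in
#' minutes.
#'
#' @param cp A [dynamic_series()] of plasma concentration, mM.
#' @param kinetics A [tissue_kinetics()].
#' @return A [dynamic_series()] of tissue concentration, mM, on `cp`'s grid.
#' @examples
#' tt <- seq(0, 5, by = 0.25)
#' cp <- dynamic_series(tt, rep(1, length(tt)), unit = "mM", time_unit = "min")
#' ct <- tofts_concentration(cp, tissue_kinetics(0.1, 0.1))
#' @export
tofts_concentration <- function(cp, kinetics) {
  stopifnot(inherits(cp, "dynamic_series"), inherits(kinetics, "tissue_kinetics"))
  kep <- kep_of(kinetics)
  tm <- times_min(cp)
  conv <- convolver(tm)
  ct <- kinetics$ktrans * conv(cp$values, kep)
  dynamic_series(cp$times, ct, valid = cp$valid, unit = "mM",
                 time_unit = cp$time_unit)
}

#' Convert concentration to relaxation rate (and back)
#'
#' Linear fast-exchange relaxivity model: `R1(t) = R10 + r1 * Ct(t)`. The
#' default relaxivity of 4.7 /s/mM corresponds to gadobutrol at 3 T.
#'
#' @param ct A [dynamic_series()] of concentration, mM.
#' @param r10 Pre-contrast relaxation rate, 1/s.
#' @param relaxivity Contrast-agent relaxivity, 1/s/mM (> 0).
#' @return A [dynamic_series()] of R1, 1/s.
#' @export
concentration_to_r1 <- function(ct, r10, relaxivity = 4.7) {
  stopifnot(inherits(ct, "dynamic_series"))
  if (relaxivity <= 0) stop("relaxivity must be positive", call. = FALSE)
  dynamic_series(ct$times, r10 + relaxivity * ct$values, valid = ct$valid,
                 unit = "1/s", time_unit = ct$time_unit)
}

#' @rdname concentration_to_r1
#' @param r1 A [dynamic_series()] of R1, 1/s.
#' @export
r1_to_concentration <- function(r1, r10, relaxivity = 4.7) {
  stopifnot(inherits(r1, "dynamic_series"))
  if (relaxivity <= 0) stop("relaxivity must be positive", call. = FALSE)
  dynamic_series(r1$times, (r1$values - r10) / relaxivity, valid = r1$valid,
                 unit = "mM", time_unit = r1$time_unit)
}

#' Fit the Tofts model given a known arterial input
#'
#' Bounded Levenberg-Marquardt least-squares fit of
#' [tofts_concentration()] to a measured tissue concentration curve. Within
#' this package it serves as the standard-model comparator used to validate
#' the AIF-free reference-region fit; it shares the bounds, initialisation
#' and convergence policy of [fit_rrm()].
#'
#' @param ct_toi A [dynamic_series()] of tissue concentration, mM.
#' @param cp A [dynamic_series()] of plasma concentration on the same grid.
#' @param control A [rrm_control()] list.
#' @return A list of class `tofts_fit` with elements `kinetics`
#'   ([tissue_kinetics()]), `residual` (root-mean-square misfit, mM),
#'   `converged`, `n_iter`, `flags`.
#' @export
fit_tofts_with_aif <- function(ct_toi, cp, control = rrm_control()) {
  stopifnot(inherits(ct_toi, "dynamic_series"), inherits(cp, "dynamic_series"))
  if (length(ct_toi) != length(cp) ||
      any(abs(ct_toi$times - cp$times) > 1e-9 * max(ct_toi$times, 1)))
    stop("ct_toi and cp must share one sampling grid", call. = FALSE)
  ok <- ct_toi$valid & cp$valid
  if (sum(ok) < 10L)
    return(structure(list(kinetics = NULL, residual = NA_real_,
                          converged = FALSE, n_iter = 0L,
                          flags = "too_few_samples"),
                     class = "tofts_fit"))
  tm <- times_min(cp)
  conv <- convolver(tm)
  obs <- ct_toi$values
  resid_fn <- function(par) {
    pred <- par[1] * conv(cp$values, par[1] / par[2])
    (pred - obs)[ok]
  }
  fit <- minpack.lm::nls.lm(
    par = control$init, lower = control$lower, upper = control$upper,
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      ftol = control$ftol, maxiter = control$maxiter))
  structure(
    list(kinetics = tissue_kinetics(fit$par[1], fit$par[2]),
         residual = sqrt(mean(fit$fvec^2)),
         converged = fit$info %in% 1:4,
         n_iter = fit$niter,
         flags = character(0)),
    class = "tofts_fit"
  )
}

#' @export
print.tofts_fit <- function(x, ...) {
  cat("Tofts fit (known AIF)\n")
  if (is.null(x$kinetics)) {
    cat("  failed:", paste(x$flags, collapse = ", "), "\n")
  } else {
    cat(sprintf("  Ktrans = %.4g /min, ve = %.4g\n",
                x$kinetics$ktrans, x$kinetics$ve))
    cat(sprintf("  RMS residual = %.3g mM, converged = %s (%d iterations)\n",
                x$residual, x$converged, x$n_iter))
  }
  invisible(x)
}

#' @export
coef.tofts_fit <- function(object, ...) {
  if (is.null(object$kinetics)) return(c(ktrans = NA_real_, ve = NA_real_))
  c(ktrans = object$kinetics$ktrans, ve = object$kinetics$ve)
}
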