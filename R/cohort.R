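#' Specification of a longitudinal synthetic cohort
#'
#' Describes a repeated-measures animal study: `n_animals` animals imaged
#' on a fixed set of post-lesion days, with a day-wise trajectory of
#' tissue-of-interest kinetics and log-normal between-animal variation.
#' The default trajectory is a generator invention shaped like the healing
#' course the analysis is meant to detect: the transfer coefficient is low
#' immediately post-lesion, rises from day 3, plateaus over days 7-28,
#' peaks at day 42 and falls back by day 82, while ve is flat with high
#' between-animal scatter. Manual bolus administration is emulated by a
#' uniform per-measurement arrival jitter of up to one frame plus a fixed
#' dispersion.
#'
#' @param n_animals Number of animals (>= 2), default 5.
#' @param days Strictly increasing measurement days, default
#'   `c(1, 3, 7, 14, 28, 42, 82)`.
#' @param ktrans_mean Per-day mean Ktrans of the tissue of interest, 1/min;
#'   length must match `days`.
#' @param ktrans_cv Between-animal coefficient of variation of Ktrans.
#' @param ve_mean Per-day mean ve; length must match `days`.
#' @param ve_cv Between-animal coefficient of variation of ve.
#' @param kinetics_rr Reference-region kinetics (fixed across the cohort).
#' @param r10_rr,r10_toi Pre-contrast relaxation rates, 1/s.
#' @param protocol An [acquisition_protocol()].
#' @param target_snr Per-voxel muscle baseline SNR of the simulated scans.
#' @param n_rr_voxels Voxels averaged into each reference-region curve.
#' @param arrival_jitter_frames Uniform arrival jitter amplitude, frames.
#' @param dispersion_s Bolus dispersion time constant, s.
#' @param seed Integer seed; all randomness in the cohort flows from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_animals = 5L,
                        days = c(1, 3, 7, 14, 28, 42, 82),
                        ktrans_mean = c(0.02, 0.035, 0.08, 0.08,
                                        0.09, 0.18, 0.09),
                        ktrans_cv = 0.15,
                        ve_mean = rep(0.25, length(days)),
                        ve_cv = 0.35,
                        kinetics_rr = tissue_kinetics(0.045, 0.08),
                        r10_rr = 0.82, r10_toi = 1.0,
                        protocol = acquisition_protocol(),
                        target_snr = 80, n_rr_voxels = 64L,
                        arrival_jitter_frames = 1,
                        dispersion_s = 4, seed = 1L) {
  n_animals <- as.integer(n_animals)
  if (n_animals < 2L) stop("n_animals must be >= 2", call. = FALSE)
  if (any(diff(days) <= 0)) stop("days must be strictly increasing",
                                 call. = FALSE)
  if (length(ktrans_mean) != length(days) || length(ve_mean) != length(days))
    stop("ktrans_mean and ve_mean must match the length of days",
         call. = FALSE)
  if (ktrans_cv < 0 || ve_cv < 0) stop("CVs must be >= 0", call. = FALSE)
  structure(
    list(n_animals = n_animals, days = days, ktrans_mean = ktrans_mean,
         ktrans_cv = ktrans_cv, ve_mean = ve_mean, ve_cv = ve_cv,
         kinetics_rr = kinetics_rr, r10_rr = r10_rr, r10_toi = r10_toi,
         protocol = protocol, target_snr = target_snr,
         n_rr_voxels = as.integer(n_rr_voxels),
         arrival_jitter_frames = arrival_jitter_frames,
         dispersion_s = dispersion_s, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# log-normal draw with arithmetic mean mu and coefficient of variation cv
rlnorm_cv <- function(n, mu, cv) {
  if (cv == 0) return(rep(mu, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a longitudinal cohort
#'
#' Draws per-animal, per-day tissue kinetics from the trajectory in the
#' spec and generates the corresponding ROI measurement curves with
#' [simulate_roi_curves()]. Deterministic given `spec$seed`; identical
#' animals are produced when both CVs are zero.
#'
#' @param spec A [cohort_spec()].
#' @param curves If `FALSE`, only the ground-truth table is generated
#'   (useful for statistics-level studies).
#' @return A list of class `cohort_dataset` with `truth` (data frame:
#'   `animal`, `day`, `ktrans`, `ve`, `arrival_s`) and `datasets` (list of
#'   [simulate_roi_curves()] outputs, aligned with the rows of `truth`;
#'   `NULL` when `curves = FALSE`), plus the spec.
#' @export
simulate_cohort <- function(spec, curves = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  nd <- length(spec$days)
  na <- spec$n_animals
  base_arrival <- spec$protocol$n_baseline * spec$protocol$dt_s
  with_seed(spec$seed, {
    rows <- vector("list", na * nd)
    datasets <- if (curves) vector("list", na * nd) else NULL
    k <- 0L
    for (d in seq_len(nd)) {
      kt <- rlnorm_cv(na, spec$ktrans_mean[d], spec$ktrans_cv)
      ve <- pmin(rlnorm_cv(na, spec$ve_mean[d], spec$ve_cv), 1)
      for (a in seq_len(na)) {
        k <- k + 1L
        jit <- stats::runif(1, 0, spec$arrival_jitter_frames) *
          spec$protocol$dt_s
        arrival <- base_arrival + jit
        rows[[k]] <- data.frame(animal = a, day = spec$days[d],
                                ktrans = kt[a], ve = ve[a],
                                arrival_s = arrival)
        if (curves) {
          datasets[[k]] <- simulate_roi_curves(
            protocol = spec$protocol,
            kinetics_rr = spec$kinetics_rr,
            kinetics_toi = tissue_kinetics(kt[a], ve[a]),
            r10_rr = spec$r10_rr, r10_toi = spec$r10_toi,
            aif = aif_spec(arrival_time_s = arrival,
                           dispersion_s = spec$dispersion_s),
            target_snr = spec$target_snr,
            n_rr_voxels = spec$n_rr_voxels,
            n_background = 0L,
            seed = NULL)
        }
      }
    }
    structure(list(truth = do.call(rbind, rows), datasets = datasets,
                   spec = spec),
              class = "cohort_dataset")
  })
}
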