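# Run code with the RNG seeded, restoring the caller's RNG state afterwards.
# seed = NULL means "use the RNG as-is" so composite generators can drive
# everything from one top-level seed.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Add Rician noise to magnitude data
#'
#' Magnitude MRI noise model: each value v becomes `|v + n1 + i n2|` with
#' independent `n1, n2 ~ Normal(0, sigma)`. Where the underlying signal is
#' zero the result is Rayleigh-distributed with scale `sigma`, which is what
#' the Rayleigh-corrected [snr()] estimate assumes of image background.
#'
#' @param values Numeric vector/array of noise-free magnitudes (>= 0).
#' @param sigma Per-channel Gaussian standard deviation (>= 0); 0 returns
#'   the input unchanged.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return Noised values with the same shape as the input.
#' @examples
#' add_rician_noise(rep(0, 5), sigma = 1, seed = 1)
#' @export
add_rician_noise <- function(values, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (sigma == 0) return(values)
  with_seed(seed, {
    n <- length(values)
    re <- values + stats::rnorm(n, 0, sigma)
    im <- stats::rnorm(n, 0, sigma)
    out <- sqrt(re^2 + im^2)
    if (!is.null(dim(values))) dim(out) <- dim(values)
    out
  })
}

#' Simulate reference and dynamic signal curves for one ROI pair
#'
#' Generates the full measurement chain for a reference region (skeletal
#' muscle by default) and a tissue of interest: arterial input
#' ([make_aif()]), Tofts tissue concentration ([tofts_concentration()]),
#' relaxivity conversion to R1 ([concentration_to_r1()]), and FLASH signal
#' synthesis ([flash_signal()]), with optional Rician noise. Defaults
#' reproduce the study conditions the package is validated under: 40 frames
#' every 13.32 s with 3 pre-contrast baseline frames, muscle kinetics
#' Ktrans = 0.045 /min and ve = 0.08 at R10 = 0.82 /s, bolus arrival at the
#' end of the baseline window.
#'
#' The reference (proton-density) scan is synthesised in one of two modes:
#' `"ideal"` treats it as fully relaxed (`m0_eff * sin(fa_ref)`), under
#' which the T1 inversion of [estimate_t1()] is exact; `"protocol"` uses
#' the finite-TR FLASH signal at the tissue's pre-contrast T1, exposing the
#' method's deterministic reference bias.
#'
#' The returned reference-region curve can be an average over
#' `n_rr_voxels` independently noised voxels, mirroring an ROI-mean muscle
#' curve; the tissue of interest is a single voxel. Noise is set either
#' directly (`noise_sigma`, per-channel signal units) or via `target_snr`,
#' defined on the muscle baseline signal of a single voxel.
#'
#' @param protocol An [acquisition_protocol()].
#' @param kinetics_rr,kinetics_toi [tissue_kinetics()] of the two tissues.
#' @param r10_rr,r10_toi Pre-contrast relaxation rates, 1/s.
#' @param aif An [aif_spec()]; default biexponential, double dose, arrival
#'   at `n_baseline * dt`. Arrival inside the baseline window is an error.
#' @param noise_sigma Per-channel Gaussian sigma in signal units.
#' @param target_snr If non-`NULL`, overrides `noise_sigma` so that the
#'   single-voxel muscle baseline SNR equals this value.
#' @param m0_eff Effective equilibrium signal scale.
#' @param relaxivity Contrast relaxivity, 1/s/mM.
#' @param reference_mode `"ideal"` or `"protocol"` (see Details).
#' @param n_rr_voxels Voxels averaged into the reference-region curve.
#' @param n_background Background (signal-free) noise samples returned for
#'   SNR estimation.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return A list with elements `s_ref_rr`, `s_ref_toi` (reference-scan
#'   values), `s_rr`, `s_toi` (dynamic [dynamic_series()], signal units,
#'   times in s), `background` (noised zero-signal samples), `sigma`
#'   (per-channel sigma used) and `truth` (noise-free `cp`, `r1_rr`,
#'   `r1_toi`, the kinetics, R10s and the generating specs).
#' @export
simulate_roi_curves <- function(protocol = acquisition_protocol(),
                                kinetics_rr = tissue_kinetics(0.045, 0.08),
                                kinetics_toi = tissue_kinetics(0.2, 0.3),
                                r10_rr = 0.82, r10_toi = 1.0,
                                aif = NULL,
                                noise_sigma = 0, target_snr = NULL,
                                m0_eff = 1000, relaxivity = 4.7,
                                reference_mode = c("ideal", "protocol"),
                                n_rr_voxels = 1L, n_background = 1000L,
                                seed = NULL) {
  reference_mode <- match.arg(reference_mode)
  stopifnot(inherits(protocol, "acquisition_protocol"))
  if (is.null(aif))
    aif <- aif_spec(arrival_time_s = protocol$n_baseline * protocol$dt_s)
  stopifnot(inherits(aif, "aif_spec"))
  baseline_end_s <- (protocol$n_baseline - 1L) * protocol$dt_s
  if (aif$arrival_time_s <= baseline_end_s)
    stop("bolus arrival must come after the last baseline frame",
         call. = FALSE)

  t_s <- frame_times(protocol, "s")
  cp <- make_aif(aif, t_s / 60)
  r1_of <- function(kin, r10)
    concentration_to_r1(tofts_concentration(cp, kin), r10, relaxivity)
  r1_rr <- r1_of(kinetics_rr, r10_rr)
  r1_toi <- r1_of(kinetics_toi, r10_toi)

  sig_of <- function(r1) flash_signal(m0_eff, 1000 / r1$values,
                                      protocol$tr_dce_ms, protocol$fa_dce_deg)
  s_rr_clean <- sig_of(r1_rr)
  s_toi_clean <- sig_of(r1_toi)
  ref_of <- function(r10) {
    if (reference_mode == "ideal") m0_eff * sin(protocol$fa_ref_deg * pi / 180)
    else flash_signal(m0_eff, 1000 / r10, protocol$tr_ref_ms,
                      protocol$fa_ref_deg)
  }
  ref_rr_clean <- ref_of(r10_rr)
  ref_toi_clean <- ref_of(r10_toi)

  sigma <- noise_sigma
  if (!is.null(target_snr)) {
    if (target_snr <= 0) stop("target_snr must be positive", call. = FALSE)
    muscle_baseline <- flash_signal(m0_eff, 1000 / r10_rr,
                                    protocol$tr_dce_ms, protocol$fa_dce_deg)
    sigma <- muscle_baseline / target_snr
  }

  with_seed(seed, {
    avg_noised <- function(v, n_avg) {
      if (sigma == 0) return(v)
      acc <- 0
      for (i in seq_len(n_avg)) acc <- acc + add_rician_noise(v, sigma)
      acc / n_avg
    }
    s_rr <- avg_noised(s_rr_clean, n_rr_voxels)
    ref_rr <- avg_noised(ref_rr_clean, n_rr_voxels)
    s_toi <- add_rician_noise(s_toi_clean, sigma)
    ref_toi <- add_rician_noise(ref_toi_clean, sigma)
    background <- add_rician_noise(numeric(n_background), sigma)

    # seconds grid on the relaxation truths, for direct use with fit_rrm
    as_seconds <- function(x) dynamic_series(t_s, x$values, valid = x$valid,
                                             unit = x$unit, time_unit = "s")
    list(
      s_ref_rr = ref_rr, s_ref_toi = ref_toi,
      s_rr = dynamic_series(t_s, s_rr, unit = "a.u."),
      s_toi = dynamic_series(t_s, s_toi, unit = "a.u."),
      background = background, sigma = sigma,
      truth = list(cp = cp, r1_rr = as_seconds(r1_rr),
                   r1_toi = as_seconds(r1_toi),
                   kinetics_rr = kinetics_rr, kinetics_toi = kinetics_toi,
                   r10_rr = r10_rr, r10_toi = r10_toi,
                   m0_eff = m0_eff, relaxivity = relaxivity,
                   aif = aif, protocol = protocol,
                   reference_mode = reference_mode)
    )
  })
}

#' Specification of a synthetic phantom volume
#'
#' Describes a rectangular-ROI digital phantom: grid shape, placement of
#' the reference-region and tissue-of-interest labels, acquisition
#' protocol, AIF, per-tissue kinetics and baseline relaxation, and the
#' noise level. Label conventions: 0 = background, 1 = reference region,
#' 2 = tissue of interest.
#'
#' @param grid Integer vector (nx, ny, nz), at least 8 x 8 x 1.
#' @param rr_box,toi_box Inclusive 1-based index ranges per axis, each a
#'   list with elements `x`, `y`, `z` of length-2 vectors. Boxes must not
#'   overlap.
#' @param protocol,aif,kinetics_rr,kinetics_toi,r10_rr,r10_toi,m0_eff,relaxivity,reference_mode,noise_sigma,target_snr
#'   As in [simulate_roi_curves()].
#' @param seed Integer seed driving all randomness of the phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(32L, 32L, 4L),
                         rr_box = list(x = c(5, 12), y = c(5, 28), z = c(1, 4)),
                         toi_box = list(x = c(21, 28), y = c(5, 28), z = c(1, 4)),
                         protocol = acquisition_protocol(),
                         aif = NULL,
                         kinetics_rr = tissue_kinetics(0.045, 0.08),
                         kinetics_toi = tissue_kinetics(0.2, 0.3),
                         r10_rr = 0.82, r10_toi = 1.0,
                         m0_eff = 1000, relaxivity = 4.7,
                         reference_mode = "ideal",
                         noise_sigma = 0, target_snr = NULL,
                         seed = 1L) {
  grid <- as.integer(grid)
  if (length(grid) != 3L || grid[1] < 8L || grid[2] < 8L || grid[3] < 1L)
    stop("grid must be (nx, ny, nz) with nx, ny >= 8 and nz >= 1",
         call. = FALSE)
  check_box <- function(b, nm) {
    if (!all(c("x", "y", "z") %in% names(b)))
      stop(nm, " must have x, y, z ranges", call. = FALSE)
    for (ax in 1:3) {
      r <- b[[c("x", "y", "z")[ax]]]
      if (length(r) != 2L || r[1] < 1 || r[2] > grid[ax] || r[1] > r[2])
        stop(nm, " range out of grid on axis ", ax, call. = FALSE)
    }
  }
  check_box(rr_box, "rr_box"); check_box(toi_box, "toi_box")
  overlap <- function(a, b) max(a[1], b[1]) <= min(a[2], b[2])
  if (overlap(rr_box$x, toi_box$x) && overlap(rr_box$y, toi_box$y) &&
      overlap(rr_box$z, toi_box$z))
    stop("rr_box and toi_box overlap", call. = FALSE)
  structure(
    list(grid = grid, rr_box = rr_box, toi_box = toi_box,
         protocol = protocol, aif = aif,
         kinetics_rr = kinetics_rr, kinetics_toi = kinetics_toi,
         r10_rr = r10_rr, r10_toi = r10_toi, m0_eff = m0_eff,
         relaxivity = relaxivity, reference_mode = reference_mode,
         noise_sigma = noise_sigma, target_snr = target_snr,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Simulate a phantom dataset
#'
#' Applies [simulate_roi_curves()] voxelwise by label: every voxel of a
#' label carries the label's noise-free curve plus independent Rician
#' noise; background voxels are pure noise. Deterministic given the spec's
#' seed.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom_dataset`: `reference` (3D array),
#'   `dynamic` (4D array, x-y-z-t), `mask` (integer 3D array), `truth`
#'   (list with parameter maps `ktrans_map`, `ve_map` and the noise-free
#'   curves), `protocol` and `spec`.
#' @export
simulate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  base <- simulate_roi_curves(
    protocol = spec$protocol, kinetics_rr = spec$kinetics_rr,
    kinetics_toi = spec$kinetics_toi, r10_rr = spec$r10_rr,
    r10_toi = spec$r10_toi, aif = spec$aif, noise_sigma = 0,
    m0_eff = spec$m0_eff, relaxivity = spec$relaxivity,
    reference_mode = spec$reference_mode, seed = NULL)
  # noise level resolved exactly as in simulate_roi_curves
  sigma <- spec$noise_sigma
  if (!is.null(spec$target_snr)) {
    muscle_baseline <- flash_signal(spec$m0_eff, 1000 / spec$r10_rr,
                                    spec$protocol$tr_dce_ms,
                                    spec$protocol$fa_dce_deg)
    sigma <- muscle_baseline / spec$target_snr
  }

  g <- spec$grid
  nt <- spec$protocol$n_frames
  mask <- array(0L, g)
  in_box <- function(b) {
    idx <- as.matrix(expand.grid(x = b$x[1]:b$x[2], y = b$y[1]:b$y[2],
                                 z = b$z[1]:b$z[2]))
    idx
  }
  mask[in_box(spec$rr_box)] <- 1L
  mask[in_box(spec$toi_box)] <- 2L

  # noise-free dynamic signal per label (recompute cleans from truth)
  sig_of <- function(r1) flash_signal(spec$m0_eff, 1000 / r1$values,
                                      spec$protocol$tr_dce_ms,
                                      spec$protocol$fa_dce_deg)
  s_rr <- sig_of(base$truth$r1_rr)
  s_toi <- sig_of(base$truth$r1_toi)

  reference <- array(0, g)
  reference[mask == 1L] <- base$s_ref_rr
  reference[mask == 2L] <- base$s_ref_toi
  dynamic <- array(0, c(g, nt))
  flat <- matrix(dynamic, nrow = prod(g), ncol = nt)
  flat[mask == 1L, ] <- matrix(s_rr, nrow = sum(mask == 1L), ncol = nt,
                               byrow = TRUE)
  flat[mask == 2L, ] <- matrix(s_toi, nrow = sum(mask == 2L), ncol = nt,
                               byrow = TRUE)
  with_seed(spec$seed, {
    reference <- add_rician_noise(reference, sigma)
    flat <- add_rician_noise(flat, sigma)
  })
  dynamic <- array(flat, c(g, nt))

  ktrans_map <- array(NA_real_, g)
  ktrans_map[mask == 1L] <- spec$kinetics_rr$ktrans
  ktrans_map[mask == 2L] <- spec$kinetics_toi$ktrans
  ve_map <- array(NA_real_, g)
  ve_map[mask == 1L] <- spec$kinetics_rr$ve
  ve_map[mask == 2L] <- spec$kinetics_toi$ve

  structure(
    list(reference = reference, dynamic = dynamic, mask = mask,
         truth = c(base$truth, list(ktrans_map = ktrans_map,
                                    ve_map = ve_map, sigma = sigma)),
         protocol = spec$protocol, spec = spec),
    class = "phantom_dataset"
  )
}

#' Write a phantom dataset to disk
#'
#' Emits `reference.nii.gz`, `dynamic.nii.gz`, `mask.nii.gz`, `truth.csv`
#' (per-label ground-truth kinetics) and `provenance.json` (the generating
#' spec including the seed).
#'
#' @param phantom A `phantom_dataset` from [simulate_phantom()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("reference.nii.gz", "dynamic.nii.gz",
                            "mask.nii.gz", "truth.csv", "provenance.json"))
  RNifti::writeNifti(phantom$reference, paths[1])
  RNifti::writeNifti(phantom$dynamic, paths[2])
  RNifti::writeNifti(phantom$mask, paths[3], datatype = "int16")
  truth <- data.frame(
    roi_label = c(1L, 2L),
    roi = c("reference_region", "tissue_of_interest"),
    ktrans_min = c(phantom$spec$kinetics_rr$ktrans,
                   phantom$spec$kinetics_toi$ktrans),
    ve = c(phantom$spec$kinetics_rr$ve, phantom$spec$kinetics_toi$ve),
    r10_s = c(phantom$spec$r10_rr, phantom$spec$r10_toi)
  )
  utils::write.csv(truth, paths[4], row.names = FALSE)
  spec <- phantom$spec
  spec$protocol <- unclass(spec$protocol)
  spec$kinetics_rr <- unclass(spec$kinetics_rr)
  spec$kinetics_toi <- unclass(spec$kinetics_toi)
  if (!is.null(spec$aif)) spec$aif <- unclass(spec$aif)
  jsonlite::write_json(list(spec = unclass(spec), package = "dcerrm",
                            version = as.character(utils::packageVersion("dcerrm"))),
                       paths[5], auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(paths)
}
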