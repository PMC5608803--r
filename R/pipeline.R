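#' Signal-to-relaxation conversion for one curve
#'
#' Convenience chain for a single voxel or ROI: dynamic T1 estimation
#' against the reference scan ([estimate_t1()]) followed by conversion to
#' relaxation rate ([r1_from_t1()]).
#'
#' @param s_ref Scalar reference-scan signal.
#' @param s_dce A [dynamic_series()] of dynamic signals.
#' @param protocol An [acquisition_protocol()].
#' @return A [dynamic_series()] of R1 in 1/s.
#' @export
signal_to_r1 <- function(s_ref, s_dce, protocol) {
  r1_from_t1(estimate_t1(s_ref, s_dce, protocol))
}

# Fit one simulated ROI dataset (output of simulate_roi_curves) through the
# full measurement chain: T1 inversion, R10 baseline, RRM fit.
fit_roi_dataset <- function(ds, kinetics_rr = tissue_kinetics(0.045, 0.08),
                            control = rrm_control()) {
  protocol <- ds$truth$protocol
  r1_rr <- signal_to_r1(ds$s_ref_rr, ds$s_rr, protocol)
  r1_toi <- signal_to_r1(ds$s_ref_toi, ds$s_toi, protocol)
  r10_rr <- estimate_r10(r1_rr, protocol$n_baseline)
  r10_toi <- estimate_r10(r1_toi, protocol$n_baseline)
  fit_rrm(r1_toi, r1_rr, r10_toi = r10_toi, r10_rr = r10_rr,
          kinetics_rr = kinetics_rr, control = control,
          n_baseline = protocol$n_baseline)
}

#' Fit every measurement of a simulated cohort
#'
#' Runs the full analysis chain (T1 inversion, baseline R10, reference
#' region fit) on each animal-day dataset of a [simulate_cohort()] output.
#'
#' @param cohort A `cohort_dataset` with curve-level datasets.
#' @param kinetics_rr Fixed reference-region kinetics.
#' @param control A [rrm_control()].
#' @return A data frame with one row per animal-day: `animal`, `day`,
#'   `ktrans`, `ve`, `ratio_R`, `residual`, `converged`, `flags`
#'   (semicolon-joined), plus the ground-truth `ktrans_true`, `ve_true`.
#' @export
fit_cohort <- function(cohort, kinetics_rr = tissue_kinetics(0.045, 0.08),
                       control = rrm_control()) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (is.null(cohort$datasets))
    stop("cohort was generated without curves", call. = FALSE)
  rows <- lapply(seq_along(cohort$datasets), function(i) {
    fit <- fit_roi_dataset(cohort$datasets[[i]], kinetics_rr, control)
    tr <- cohort$truth[i, ]
    data.frame(
      animal = tr$animal, day = tr$day,
      ktrans = if (is.null(fit$kinetics)) NA_real_ else fit$kinetics$ktrans,
      ve = if (is.null(fit$kinetics)) NA_real_ else fit$kinetics$ve,
      ratio_R = fit$ratio_R, residual = fit$residual,
      converged = fit$converged,
      flags = paste(fit$flags, collapse = ";"),
      ktrans_true = tr$ktrans, ve_true = tr$ve
    )
  })
  do.call(rbind, rows)
}

#' Run the reference-region analysis on image volumes
#'
#' Orchestrates the full pipeline on a reference volume, a 4D dynamic
#' volume and an ROI label mask (label 1 = reference region, label 2 =
#' tissue of interest): per-curve T1 estimation against the reference
#' scan, baseline R10, and reference-region fits of the tissue of
#' interest. The reference-region curve is always the ROI mean (computed
#' from ROI-averaged signals), which suppresses its noise; in
#' `"voxelwise"` mode each tissue voxel is fitted against that mean curve
#' and the ROI is summarised by median and interquartile range over
#' converged, unflagged voxels, while `"roi_mean"` mode fits the single
#' ROI-averaged tissue curve.
#'
#' Voxels whose T1 series is invalid in more than `max_invalid_frac` of
#' frames are excluded from fitting and counted as flagged.
#'
#' @param reference 3D array or path to a NIfTI file.
#' @param dynamic 4D array (x, y, z, t) or path to a NIfTI file.
#' @param mask Integer 3D array or path; same grid as `reference`.
#' @param protocol An [acquisition_protocol()].
#' @param kinetics_rr Fixed reference-region kinetics.
#' @param mode `"voxelwise"` (default) or `"roi_mean"`.
#' @param control A [rrm_control()].
#' @param rr_label,toi_label Mask labels of the two regions.
#' @param max_invalid_frac Maximum tolerated fraction of invalid frames
#'   per voxel.
#' @param summary_stat `"median"` (default) or `"mean"` for the ROI
#'   summary location estimate.
#' @return A list of class `rrm_pipeline_fit`: `summary` (one-row data
#'   frame: `roi_label`, `n_voxels`, `n_fit`, `ktrans_*`, `ve_*` location
#'   and quartiles, `frac_flagged`, `mode`), `voxels` (per-voxel results,
#'   voxel indices 0-based; `NULL` in `roi_mean` mode), `maps` (named list
#'   of 3D parameter arrays; `NULL` in `roi_mean` mode), `roi_fit` (the
#'   single `rrm_fit` in `roi_mean` mode), `r1_rr` and `r10_rr`.
#' @export
run_fit <- function(reference, dynamic, mask, protocol,
                    kinetics_rr = tissue_kinetics(0.045, 0.08),
                    mode = c("voxelwise", "roi_mean"),
                    control = rrm_control(),
                    rr_label = 1L, toi_label = 2L,
                    max_invalid_frac = 0.25,
                    summary_stat = c("median", "mean")) {
  mode <- match.arg(mode)
  summary_stat <- match.arg(summary_stat)
  reference <- load_volume(reference)
  dynamic <- load_volume(dynamic)
  mask <- load_volume(mask)
  g <- dim(reference)
  if (length(g) != 3L || length(dim(dynamic)) != 4L ||
      !all(dim(dynamic)[1:3] == g) ||
      length(dim(mask)) != 3L || !all(dim(mask) == g))
    stop("reference, dynamic and mask grids do not match", call. = FALSE)
  nt <- dim(dynamic)[4]
  if (nt != protocol$n_frames)
    stop("dynamic volume has ", nt, " frames but protocol declares ",
         protocol$n_frames, call. = FALSE)
  if (!any(mask == rr_label)) stop("reference-region label ", rr_label,
                                   " absent from mask", call. = FALSE)
  if (!any(mask == toi_label)) stop("tissue-of-interest label ", toi_label,
                                    " absent from mask", call. = FALSE)

  t_s <- frame_times(protocol, "s")
  dyn_flat <- matrix(dynamic, nrow = prod(g), ncol = nt)
  rr_idx <- which(mask == rr_label)
  toi_idx <- which(mask == toi_label)

  # ROI-mean reference-region curve
  s_ref_rr <- mean(reference[rr_idx])
  s_rr <- dynamic_series(t_s, colMeans(dyn_flat[rr_idx, , drop = FALSE]))
  r1_rr <- signal_to_r1(s_ref_rr, s_rr, protocol)
  r10_rr <- estimate_r10(r1_rr, protocol$n_baseline)
  if (!r10_rr$ok)
    stop("reference-region baseline R1 could not be estimated", call. = FALSE)

  empty_summary <- function(n_vox, n_fit, frac_flagged) {
    data.frame(roi_label = toi_label, n_voxels = n_vox, n_fit = n_fit,
               ktrans_med = NA_real_, ktrans_q25 = NA_real_,
               ktrans_q75 = NA_real_, ve_med = NA_real_,
               ve_q25 = NA_real_, ve_q75 = NA_real_,
               frac_flagged = frac_flagged, mode = mode)
  }
  loc <- if (summary_stat == "median") stats::median else mean

  if (mode == "roi_mean") {
    s_ref_toi <- mean(reference[toi_idx])
    s_toi <- dynamic_series(t_s, colMeans(dyn_flat[toi_idx, , drop = FALSE]))
    r1_toi <- signal_to_r1(s_ref_toi, s_toi, protocol)
    r10_toi <- estimate_r10(r1_toi, protocol$n_baseline)
    fit <- fit_rrm(r1_toi, r1_rr, r10_toi = r10_toi, r10_rr = r10_rr,
                   kinetics_rr = kinetics_rr, control = control,
                   n_baseline = protocol$n_baseline)
    smry <- empty_summary(length(toi_idx), as.integer(fit$converged),
                          as.numeric(length(fit$flags) > 0))
    if (!is.null(fit$kinetics)) {
      smry$ktrans_med <- smry$ktrans_q25 <- smry$ktrans_q75 <-
        fit$kinetics$ktrans
      smry$ve_med <- smry$ve_q25 <- smry$ve_q75 <- fit$kinetics$ve
    }
    return(structure(list(summary = smry, voxels = NULL, maps = NULL,
                          roi_fit = fit, r1_rr = r1_rr, r10_rr = r10_rr,
                          mode = mode),
                     class = "rrm_pipeline_fit"))
  }

  n_toi <- length(toi_idx)
  res <- data.frame(
    voxel = toi_idx - 1L,  # 0-based flat index
    ktrans = NA_real_, ve = NA_real_, ratio_R = NA_real_,
    residual = NA_real_, converged = FALSE, flags = "",
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n_toi)) {
    v <- toi_idx[i]
    s_toi <- dynamic_series(t_s, dyn_flat[v, ])
    t1 <- estimate_t1(reference[v], s_toi, protocol)
    if (mean(!t1$valid) > max_invalid_frac) {
      res$flags[i] <- "invalid_frames"
      next
    }
    r1_toi <- r1_from_t1(t1)
    r10_toi <- estimate_r10(r1_toi, protocol$n_baseline)
    if (!r10_toi$ok) {
      res$flags[i] <- "no_baseline"
      next
    }
    fit <- fit_rrm(r1_toi, r1_rr, r10_toi = r10_toi, r10_rr = r10_rr,
                   kinetics_rr = kinetics_rr, control = control,
                   n_baseline = protocol$n_baseline)
    if (!is.null(fit$kinetics)) {
      res$ktrans[i] <- fit$kinetics$ktrans
      res$ve[i] <- fit$kinetics$ve
      res$ratio_R[i] <- fit$ratio_R
      res$residual[i] <- fit$residual
      res$converged[i] <- fit$converged
    }
    res$flags[i] <- paste(fit$flags, collapse = ";")
  }

  good <- res$converged & res$flags == ""
  maps <- list(ktrans = array(NA_real_, g), ve = array(NA_real_, g),
               ratio_R = array(NA_real_, g), residual = array(NA_real_, g))
  maps$ktrans[toi_idx] <- res$ktrans
  maps$ve[toi_idx] <- res$ve
  maps$ratio_R[toi_idx] <- res$ratio_R
  maps$residual[toi_idx] <- res$residual

  if (!any(good)) {
    smry <- empty_summary(n_toi, 0L, mean(res$flags != ""))
  } else {
    q <- function(x, p) unname(stats::quantile(x[good], p, na.rm = TRUE))
    smry <- data.frame(
      roi_label = toi_label, n_voxels = n_toi, n_fit = sum(good),
      ktrans_med = loc(res$ktrans[good]),
      ktrans_q25 = q(res$ktrans, 0.25), ktrans_q75 = q(res$ktrans, 0.75),
      ve_med = loc(res$ve[good]),
      ve_q25 = q(res$ve, 0.25), ve_q75 = q(res$ve, 0.75),
      frac_flagged = mean(res$flags != ""), mode = mode
    )
  }
  structure(list(summary = smry, voxels = res, maps = maps, roi_fit = NULL,
                 r1_rr = r1_rr, r10_rr = r10_rr, mode = mode),
            class = "rrm_pipeline_fit")
}

#' @export
print.rrm_pipeline_fit <- function(x, ...) {
  cat(sprintf("Reference-region pipeline fit (%s mode)\n", x$mode))
  s <- x$summary
  cat(sprintf("  tissue label %d: %d voxels, %d fitted (%.0f%% flagged)\n",
              s$roi_label, s$n_voxels, s$n_fit, 100 * s$frac_flagged))
  if (is.finite(s$ktrans_med))
    cat(sprintf("  Ktrans %.4g [%.4g, %.4g] /min   ve %.4g [%.4g, %.4g]\n",
                s$ktrans_med, s$ktrans_q25, s$ktrans_q75,
                s$ve_med, s$ve_q25, s$ve_q75))
  invisible(x)
}

# Accept in-memory arrays or NIfTI paths.
load_volume <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("file not found: ", x, call. = FALSE)
    arr <- RNifti::readNifti(x)
    return(array(as.numeric(arr), dim = dim(arr)))
  }
  if (!is.array(x)) stop("expected an array or a file path", call. = FALSE)
  x
}

#' Write pipeline fit outputs
#'
#' Emits `roi_summary.csv`, `voxels.csv` (voxelwise mode), NIfTI parameter
#' maps and a `provenance.json` with the fit configuration, seed and
#' package version. CSV files are UTF-8, header row, '.' decimal.
#'
#' @param fit An `rrm_pipeline_fit`.
#' @param dir Output directory.
#' @param config Optional list recorded in the provenance file.
#' @param seed Optional seed recorded in the provenance file.
#' @return Invisibly, the paths written.
#' @export
write_fit_results <- function(fit, dir, config = NULL, seed = NULL) {
  stopifnot(inherits(fit, "rrm_pipeline_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "roi_summary.csv")
  utils::write.csv(fit$summary, p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(fit$voxels)) {
    p <- file.path(dir, "voxels.csv")
    utils::write.csv(fit$voxels, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(fit$maps)) {
    for (nm in names(fit$maps)) {
      p <- file.path(dir, paste0(nm, ".nii.gz"))
      RNifti::writeNifti(fit$maps[[nm]], p)
      paths <- c(paths, p)
    }
  }
  prov <- list(package = "dcerrm",
               version = as.character(utils::packageVersion("dcerrm")),
               mode = fit$mode, seed = seed, config = config,
               config_hash = config_hash(config))
  p <- file.path(dir, "provenance.json")
  jsonlite::write_json(prov, p, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}

# md5 of the JSON serialisation of a config list (NULL-safe).
config_hash <- function(config) {
  if (is.null(config)) return(NULL)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tf))
}
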