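test_that("make_aif honours causality, dose scaling and its closed form", {
  tm <- seq(0, 8, by = 13.32 / 60)
  arr <- 39.96
  cp <- make_aif(aif_spec(arrival_time_s = arr), tm)
  expect_true(all(cp$values[tm < arr / 60] == 0))
  # frozen from direct evaluation of D (a1 e^{-m1 t'} + a2 e^{-m2 t'})
  expect_equal(max(cp$values), 1.754, tolerance = 1e-10)       # bolus peak
  cp5 <- make_aif(aif_spec(arrival_time_s = 0), c(0, 5, 8))
  expect_equal(cp5$values[2], 1.29281579, tolerance = 1e-7)    # 5 min tail
  expect_equal(cp5$values[3], 1.12693860, tolerance = 1e-7)    # 8 min tail
  # zero dose -> zero input
  expect_equal(make_aif(aif_spec(dose = 0), tm)$values, rep(0, length(tm)))
  # parker mode is positive after arrival and causal before
  cpp <- make_aif(aif_spec("parker", arrival_time_s = arr), tm)
  expect_true(all(cpp$values[tm < arr / 60] == 0))
  expect_true(all(cpp$values[tm > arr / 60 + 0.2] > 0))
  expect_error(aif_spec(m1 = -1), "positive")
})

test_that("Rician noise has the right moments and degenerates to identity", {
  x <- c(0, 1, 50, 100)
  expect_identical(add_rician_noise(x, 0), x)
  # background becomes Rayleigh with sd 0.655 * sigma_corr, closing the
  # loop with the snr() definition
  set.seed(99)
  bg <- add_rician_noise(numeric(2e5), sigma = 5)
  expect_equal(sd(bg) / 0.655, 5, tolerance = 0.02)
  # high-SNR Rician bias is sigma^2 / (2 v): 100.005 for v = 100, sigma 1
  v <- add_rician_noise(rep(100, 1e6), sigma = 1, seed = 7)
  expect_equal(mean(v), 100.005, tolerance = 5e-5)
  # same seed -> same draw; shape is preserved
  a <- add_rician_noise(matrix(1:6, 2), 1, seed = 3)
  b <- add_rician_noise(matrix(1:6, 2), 1, seed = 3)
  expect_identical(a, b)
  expect_identical(dim(a), c(2L, 3L))
})

test_that("simulated tissue curves obey the Tofts concentration bound", {
  p <- default_protocol()
  tm <- frame_times(p, "min")
  for (model in c("biexponential", "parker")) {
    cp <- make_aif(aif_spec(model, arrival_time_s = p$n_baseline * p$dt_s),
                   tm)
    for (kt in c(0.05, 0.3)) {
      for (ve in c(0.1, 0.4)) {
        ct <- tofts_concentration(cp, tissue_kinetics(kt, ve))
        expect_lte(max(ct$values), ve * max(cp$values) * (1 + 1e-9))
      }
    }
  }
})

test_that("simulate_roi_curves is consistent in the noise-free limit", {
  ds <- simulate_roi_curves(kinetics_toi = muscle_kinetics(),
                            r10_toi = 0.82, noise_sigma = 0)
  # identical kinetics and baseline -> identical curves sample-for-sample
  expect_equal(ds$s_toi$values, ds$s_rr$values)
  expect_equal(ds$s_ref_rr, ds$s_ref_toi)
  # baseline frames are pre-arrival
  p <- default_protocol()
  nb <- p$n_baseline
  expect_equal(ds$s_toi$values[seq_len(nb)],
               rep(ds$s_toi$values[1], nb))
  # end-to-end recovery through the full measurement chain
  ds2 <- simulate_roi_curves(kinetics_toi = tissue_kinetics(0.2, 0.3),
                             noise_sigma = 0)
  fit <- fit_rrm(signal_to_r1(ds2$s_ref_toi, ds2$s_toi, p),
                 signal_to_r1(ds2$s_ref_rr, ds2$s_rr, p),
                 r10_toi = 1.0, r10_rr = 0.82)
  expect_equal(unname(coef(fit)), c(0.2, 0.3), tolerance = 0.02)
  # arrival inside the baseline window is a config error
  expect_error(simulate_roi_curves(aif = aif_spec(arrival_time_s = 5)),
               "baseline")
})

test_that("target_snr calibrates the simulated noise level", {
  ds <- simulate_roi_curves(target_snr = 80, seed = 21,
                            n_background = 5000)
  measured <- snr(mean(ds$s_rr$values[1:3]), sd(ds$background))
  expect_equal(measured, 80, tolerance = 0.05)
  # noise model closure: background sd recovers the generating sigma
  expect_equal(sd(ds$background) / 0.655, ds$sigma, tolerance = 0.02)
})

test_that("phantoms are deterministic and round-trip through NIfTI", {
  spec <- phantom_spec(grid = c(16L, 16L, 2L),
                       rr_box = list(x = c(3, 6), y = c(3, 14), z = c(1, 2)),
                       toi_box = list(x = c(11, 14), y = c(3, 14),
                                      z = c(1, 2)),
                       target_snr = 80, seed = 42L)
  ph1 <- simulate_phantom(spec)
  ph2 <- simulate_phantom(spec)
  expect_identical(ph1$dynamic, ph2$dynamic)
  expect_identical(ph1$reference, ph2$reference)
  expect_identical(sort(unique(as.vector(ph1$mask))), c(0L, 1L, 2L))
  # background voxels are pure noise: Rayleigh mean sigma sqrt(pi/2)
  bg <- ph1$dynamic[, , , 1][ph1$mask == 0L]
  expect_equal(mean(bg), ph1$truth$sigma * sqrt(pi / 2), tolerance = 0.05)

  dir <- withr::local_tempdir()
  paths <- write_phantom(ph1, dir)
  expect_true(all(file.exists(paths)))
  mask_back <- RNifti::readNifti(file.path(dir, "mask.nii.gz"))
  expect_equal(array(as.integer(mask_back), dim = dim(ph1$mask)), ph1$mask)
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  expect_equal(prov$spec$seed, 42L)
  # overlapping ROIs are rejected at spec construction
  expect_error(
    phantom_spec(rr_box = list(x = c(5, 12), y = c(5, 28), z = c(1, 4)),
                 toi_box = list(x = c(10, 15), y = c(5, 28), z = c(1, 4))),
    "overlap")
})

test_that("cohort generation is seed-reproducible with controlled variation", {
  sp <- cohort_spec(seed = 8L)
  co1 <- simulate_cohort(sp)
  co2 <- simulate_cohort(sp)
  expect_identical(co1$truth, co2$truth)
  expect_identical(co1$datasets[[7]]$s_toi$values,
                   co2$datasets[[7]]$s_toi$values)
  expect_equal(nrow(co1$truth), 5 * 7)
  # zero CV -> all animals share the day's kinetics exactly
  sp0 <- cohort_spec(ktrans_cv = 0, ve_cv = 0, seed = 9L)
  co0 <- simulate_cohort(sp0, curves = FALSE)
  per_day <- tapply(co0$truth$ktrans, co0$truth$day,
                    function(x) length(unique(x)))
  expect_true(all(per_day == 1L))
  expect_equal(sort(unique(co0$truth$day)), c(1, 3, 7, 14, 28, 42, 82))
})
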