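test_that("Tofts concentration reproduces closed forms and the fine-grid oracle", {
  tt <- seq(0, 10, by = 0.25)  # minutes
  cp1 <- dynamic_series(tt, rep(1, length(tt)), unit = "mM",
                        time_unit = "min")
  # no transfer -> no uptake
  ct0 <- tofts_concentration(cp1, tissue_kinetics(0, 0.1))
  expect_equal(ct0$values, rep(0, length(tt)))
  # step input closed form: Ct(T) = ve (1 - exp(-kep T)) * ... with
  # ktrans = kep * ve = 0.1/min, ve = 0.1: Ct(T) = 0.1 (1 - e^-T)
  ct <- tofts_concentration(cp1, tissue_kinetics(0.1, 0.1))
  expect_equal(ct$values, 0.1 * (1 - exp(-tt)), tolerance = 1e-3)
  expect_equal(ct$values[length(tt)], 0.1, tolerance = 1e-3)
  expect_error(tofts_concentration(cp1, list(ktrans = 0.1, ve = 0)))

  # fine-grid convolution oracle under the study sampling
  p <- default_protocol()
  tm <- frame_times(p, "min")
  cp <- make_aif(aif_spec(arrival_time_s = p$n_baseline * p$dt_s), tm)
  ct_pkg <- tofts_concentration(cp, tissue_kinetics(0.2, 0.3))
  ct_ref <- tofts_fine_grid_oracle(cp$values, tm, 0.2, 0.3)
  expect_lt(max(abs(ct_pkg$values - ct_ref)) / max(ct_ref), 0.002)
})

test_that("relaxivity conversion is linear and invertible", {
  tt <- c(0, 1, 2)
  ct <- dynamic_series(tt, c(0, 0.1, 0.05), unit = "mM", time_unit = "min")
  r1 <- concentration_to_r1(ct, r10 = 0.82, relaxivity = 4.7)
  expect_equal(r1$values[1], 0.82)
  expect_equal(r1$values[2], 1.29)
  back <- r1_to_concentration(r1, r10 = 0.82, relaxivity = 4.7)
  expect_equal(back$values, ct$values)
  expect_error(concentration_to_r1(ct, 0.82, relaxivity = 0), "positive")
})

test_that("rrm_forward collapses correctly in its degenerate limits", {
  pair <- rr_toi_pair(muscle_kinetics(), r10_toi = 0.82)
  # TOI identical to RR -> identity
  out <- rrm_forward(pair$rr, 0.82, 0.82, muscle_kinetics(),
                     muscle_kinetics())
  expect_equal(out$values, pair$rr$values, tolerance = 1e-12)
  # no transfer -> flat at the TOI baseline
  out0 <- rrm_forward(pair$rr, 0.82, 1.0, tissue_kinetics(0, 0.3),
                      muscle_kinetics())
  expect_equal(out0$values, rep(1.0, length(out0)))
})

test_that("rrm_forward reproduces a directly simulated tissue curve", {
  toi <- tissue_kinetics(0.2, 0.3)
  pair <- rr_toi_pair(toi, r10_toi = 1.0)
  pred <- rrm_forward(pair$rr, pair$r10_rr, pair$r10_toi, toi,
                      muscle_kinetics())
  peak_enh <- max(pair$toi$values) - pair$r10_toi
  expect_lt(max(abs(pred$values - pair$toi$values)) / peak_enh, 0.005)
})

test_that("fit_rrm recovers the fixed muscle parameters in the self-reference limit", {
  rr <- noise_free_r1(muscle_kinetics(), 0.82)
  fit <- fit_rrm(rr, rr, r10_toi = 0.82, r10_rr = 0.82)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(0.045, 0.08), tolerance = 1e-6)
  expect_equal(fit$ratio_R, 1, tolerance = 1e-6)
})

test_that("fit_rrm handles non-enhancing and degenerate inputs", {
  p <- default_protocol()
  tt <- frame_times(p)
  flat <- dynamic_series(tt, rep(1.0, length(tt)), unit = "1/s")
  rr <- noise_free_r1(muscle_kinetics(), 0.82)
  fit <- fit_rrm(flat, rr, r10_toi = 1.0, r10_rr = 0.82)
  expect_lt(coef(fit)[["ktrans"]], 1e-3)  # at/near the lower bound
  # too few valid samples -> flagged failure, not an error
  short_valid <- dynamic_series(tt, rr$values,
                                valid = c(rep(TRUE, 5),
                                          rep(FALSE, length(tt) - 5)))
  fit2 <- fit_rrm(short_valid, short_valid, 0.82, 0.82)
  expect_false(fit2$converged)
  expect_true("too_few_samples" %in% fit2$flags)
  # sub-noise enhancement is flagged but still fitted
  set.seed(5)
  noisy_flat <- dynamic_series(tt, 1.0 + rnorm(length(tt), 0, 0.02),
                               unit = "1/s")
  fit3 <- fit_rrm(noisy_flat, rr, r10_toi = 1.0, r10_rr = 0.82)
  expect_true("low_enhancement" %in% fit3$flags)
})

test_that("every returned fit satisfies the ratio_R consistency invariant", {
  for (kt in c(0.05, 0.2)) {
    pair <- rr_toi_pair(tissue_kinetics(kt, 0.25))
    fit <- fit_rrm(pair$toi, pair$rr, pair$r10_toi, pair$r10_rr)
    expect_identical(fit$ratio_R, fit$kinetics$ktrans / 0.045)
  }
})

test_that("fitted ktrans is strictly increasing in the true ktrans", {
  kt_true <- c(0.05, 0.1, 0.2, 0.4)
  est <- vapply(kt_true, function(kt) {
    pair <- rr_toi_pair(tissue_kinetics(kt, 0.3))
    coef(fit_rrm(pair$toi, pair$rr, pair$r10_toi, pair$r10_rr))[["ktrans"]]
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("estimates are invariant under s <-> min relabeling of the grid", {
  toi <- tissue_kinetics(0.15, 0.25)
  pair <- rr_toi_pair(toi)
  as_min <- function(x) dynamic_series(x$times / 60, x$values,
                                       valid = x$valid, unit = x$unit,
                                       time_unit = "min")
  f_s <- fit_rrm(pair$toi, pair$rr, pair$r10_toi, pair$r10_rr)
  f_min <- fit_rrm(as_min(pair$toi), as_min(pair$rr), pair$r10_toi,
                   pair$r10_rr)
  expect_equal(coef(f_s), coef(f_min), tolerance = 1e-10)
})

test_that("fit_tofts_with_aif is self-consistent on its own forward model", {
  p <- default_protocol()
  tm <- frame_times(p, "min")
  cp <- make_aif(aif_spec(arrival_time_s = p$n_baseline * p$dt_s), tm)
  # single-point exactness
  ct <- tofts_concentration(cp, tissue_kinetics(0.1, 0.2))
  fit <- fit_tofts_with_aif(ct, cp)
  expect_equal(unname(coef(fit)), c(0.1, 0.2), tolerance = 1e-4)
  # zero-transfer data pins the estimate at the lower bound
  ct0 <- tofts_concentration(cp, tissue_kinetics(0, 0.2))
  expect_lt(coef(fit_tofts_with_aif(ct0, cp))[["ktrans"]], 1e-3)
  # recovery across a 3x3 grid
  for (kt in c(0.05, 0.1, 0.2)) {
    for (ve in c(0.1, 0.2, 0.3)) {
      ctg <- tofts_concentration(cp, tissue_kinetics(kt, ve))
      cf <- coef(fit_tofts_with_aif(ctg, cp))
      expect_equal(unname(cf), c(kt, ve), tolerance = 1e-3)
    }
  }
})

test_that("rrm_fit methods expose the model consistently", {
  toi <- tissue_kinetics(0.2, 0.3)
  pair <- rr_toi_pair(toi)
  fit <- fit_rrm(pair$toi, pair$rr, pair$r10_toi, pair$r10_rr)
  expect_s3_class(fit, "rrm_fit")
  expect_named(coef(fit), c("ktrans", "ve"))
  expect_equal(predict(fit)$values, fitted(fit)$values)
  r <- residuals(fit)
  expect_equal(length(r), length(pair$toi))
  expect_lt(max(abs(r), na.rm = TRUE), 1e-3)
  # predict on a new reference curve equals the forward model
  pred <- predict(fit, r1_rr = pair$rr)
  expect_equal(pred$values, fitted(fit)$values)
  expect_output(print(fit), "Ktrans")
  expect_output(print(summary(fit)), "reference region")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
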