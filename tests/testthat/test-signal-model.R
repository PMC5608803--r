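test_that("flash_signal matches its closed form and limiting cases", {
  # frozen from direct evaluation of m0*sin(fa)*(1-E1)/(1-E1*cos(fa))
  expect_equal(flash_signal(1000, 1000, 8.09, 30), 28.5818458953,
               tolerance = 1e-10)
  # no longitudinal recovery -> no signal in the limit
  expect_lt(flash_signal(1000, 1e12, 8.09, 30), 1e-6)
  # signal scale is linear in m0_eff
  expect_equal(flash_signal(2000, 800, 8.09, 30),
               2 * flash_signal(1000, 800, 8.09, 30))
  expect_error(flash_signal(1000, -5, 8.09, 30), "positive")
  expect_error(flash_signal(1000, 1000, 0, 30), "positive")
  expect_error(flash_signal(1000, 1000, 8.09, 0), "0, 90")
})

test_that("T1 inversion round-trips the forward FLASH model exactly", {
  p <- default_protocol()
  m0 <- 1000
  s_ref <- m0 * sin(p$fa_ref_deg * pi / 180)  # idealized fully relaxed
  t1_true <- c(200, 500, 1000, 2000, 3000)
  s_dce <- dynamic_series(seq_along(t1_true) * p$dt_s,
                          flash_signal(m0, t1_true, p$tr_dce_ms, p$fa_dce_deg))
  est <- estimate_t1(s_ref, s_dce, p)
  expect_true(all(est$valid))
  expect_equal(est$values, t1_true, tolerance = 1e-9)
  expect_identical(est$unit, "ms")
})

test_that("T1 inversion marks out-of-domain samples invalid", {
  p <- default_protocol()
  # zero dynamic signal -> log argument 1 -> infinite T1 -> invalid
  est <- estimate_t1(100, dynamic_series(c(0, 13.32), c(0, 5)), p)
  expect_false(est$valid[1])
  expect_true(is.na(est$values[1]))
  # an absurdly bright frame drives the argument out of (0, 1)
  bright <- dynamic_series(c(0, 13.32), c(5, 1e6))
  est2 <- estimate_t1(100, bright, p)
  expect_false(est2$valid[2])
  # all-invalid series is flagged, not an error
  est3 <- estimate_t1(100, dynamic_series(c(0, 13.32), c(0, 0)), p)
  expect_true(all(!est3$valid))
  expect_error(estimate_t1(-1, bright, p), "positive")
})

test_that("realistic finite-TR reference yields a monotone T1 bias", {
  p <- default_protocol()
  m0 <- 1000
  t1_true <- seq(200, 3000, by = 200)
  # reference simulated as an actual TR = 100 ms FLASH at each tissue's T1
  est <- vapply(t1_true, function(t1) {
    s_ref <- flash_signal(m0, t1, p$tr_ref_ms, p$fa_ref_deg)
    s_dce <- dynamic_series(0, flash_signal(m0, t1, p$tr_dce_ms,
                                            p$fa_dce_deg))
    estimate_t1(s_ref, s_dce, p)$values
  }, numeric(1))
  expect_true(all(is.finite(est)))
  # deterministic bias, but strictly monotone in the true T1
  expect_true(all(diff(est) > 0))
  expect_gt(max(abs(est - t1_true) / t1_true), 1e-6)  # bias is real
})

test_that("R1 conversion and baseline R10 honour units and validity", {
  s <- dynamic_series(c(0, 13.32, 26.64), c(1000, 1219.5, NA), unit = "ms")
  r1 <- r1_from_t1(s)
  expect_equal(r1$values[1], 1.0)
  expect_equal(r1$values[2], 0.82, tolerance = 1e-3)
  expect_false(r1$valid[3])
  expect_identical(r1$unit, "1/s")

  r1b <- dynamic_series(c(0, 13.32, 26.64, 39.96), c(0.8, 0.9, 1.0, 5),
                        valid = c(TRUE, TRUE, TRUE, TRUE), unit = "1/s")
  expect_equal(estimate_r10(r1b, 3)$r10, 0.9)
  # invalid baseline frames are dropped from the mean
  r1c <- dynamic_series(c(0, 13.32, 26.64), c(0.8, 99, 1.0),
                        valid = c(TRUE, FALSE, TRUE), unit = "1/s")
  est <- estimate_r10(r1c, 3)
  expect_equal(est$r10, 0.9)
  expect_equal(est$n_used, 2L)
  # no valid baseline sample -> flagged failure, no exception
  r1d <- dynamic_series(c(0, 13.32), c(1, 1), valid = c(FALSE, FALSE))
  est2 <- estimate_r10(r1d, 2)
  expect_false(est2$ok)
  expect_true(is.na(est2$r10))
})

test_that("snr applies the Rayleigh correction and scales linearly", {
  expect_equal(snr(65.5, 6.55), 6.55)
  expect_equal(snr(0, 3), 0)
  expect_equal(snr(20, 5), 2 * snr(10, 5))
  expect_equal(snr(10, 10), snr(10, 5) / 2)
  expect_error(snr(10, 0), "positive")
})

test_that("Monte-Carlo Rayleigh background recovers the channel sigma", {
  set.seed(314)
  n <- 1e6
  sigma <- 5
  bg <- sqrt(rnorm(n, 0, sigma)^2 + rnorm(n, 0, sigma)^2)
  sigma_corr <- sd(bg) / 0.655
  expect_equal(sigma_corr, sigma, tolerance = 0.01)
})
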