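test_that("predicted signal matches hand-evaluated values", {
  sch <- tiny_scheme()
  s <- predict_signal(100, 0.05, 0.002, sch)
  # at (te_min, b = 0) both exponents vanish
  expect_equal(s[sch$te == te_min(sch) & sch$b == 0], 100)
  # one T2* of extra echo time at b = 0 decays by exactly 1/e
  one_t2 <- tibble::tibble(te = c(0.078, 0.078 + 0.05), b = 0,
                           gx = 0, gy = 0, gz = 0)
  expect_equal(predict_signal(80, 0.05, 0.01, one_t2)[2], 80 * exp(-1))
  # independent hand evaluation: TE 0.114 (te_min 0.078), b 600
  row <- tibble::tibble(te = c(0.078, 0.114), b = c(0, 600),
                        gx = c(0, 1), gy = 0, gz = 0)
  expect_equal(predict_signal(100, 0.05, 0.002, row)[2],
               100 * exp(-0.72) * exp(-1.2), tolerance = 1e-12)
  expect_error(predict_signal(100, -0.1, 0.002, sch))
  expect_error(predict_signal(100, 0.05, -0.002, sch))
})

test_that("signal is strictly decreasing in b and TE", {
  sch <- zebra_scheme("full_cross")
  s <- predict_signal(100, 0.06, 0.003, sch)
  df <- dplyr::mutate(tibble::as_tibble(sch), s = s)
  by_te <- dplyr::arrange(df[df$te == te_min(sch), ], b)
  expect_true(all(diff(unique(by_te[c("b", "s")])$s) < 0))
  by_b <- dplyr::arrange(df[df$b == 0, ], te)
  expect_true(all(diff(by_b$s) < 0))
})

test_that("noiseless round trip recovers the generating parameters", {
  sch <- tiny_scheme()
  set.seed(42)
  for (i in 1:25) {
    theta <- c(s0 = runif(1, 20, 500),
               t2star = exp(runif(1, log(0.008), log(0.4))),
               adc = exp(runif(1, log(5e-5), log(0.3))))
    f <- fit_voxel(predict_signal(theta[1], theta[2], theta[3], sch), sch)
    expect_true(f$converged)
    expect_equal(f$s0, theta[["s0"]], tolerance = 1e-6)
    expect_equal(f$t2star, theta[["t2star"]], tolerance = 1e-6)
    expect_equal(f$adc, theta[["adc"]], tolerance = 1e-6)
  }
})

test_that("degenerate voxels are flagged failed, not fatal", {
  sch <- tiny_scheme()
  sig <- predict_signal(120, 0.06, 0.005, sch)
  sig[3] <- 0
  f <- fit_voxel(sig, sch)
  expect_false(f$converged)
  expect_true(is.na(f$t2star))
  expect_error(fit_voxel(sig[-1], sch), "length")
  # all-equal signals: degenerate design, flagged failed
  f2 <- fit_voxel(rep(50, nrow(sch)), sch)
  expect_false(f2$converged)
})

test_that("noisy fits agree with the exhaustive grid-search oracle", {
  sch <- zebra_scheme("full_cross")
  set.seed(7)
  step_t2 <- diff(log(c(0.005, 0.5))) / 59
  step_adc <- diff(log(c(1e-5, 1.0))) / 59
  for (i in 1:10) {
    sig <- predict_signal(100, 0.05, 0.002, sch)
    e1 <- rnorm(nrow(sch), 0, 2); e2 <- rnorm(nrow(sch), 0, 2)
    y <- sqrt((sig + e1)^2 + e2^2)
    f <- fit_voxel(y, sch)
    g <- grid_search_fit(y, sch, n_t2 = 60, n_adc = 60)
    expect_lt(abs(log(f$t2star) - log(g[["t2"]])), 1.5 * step_t2)
    expect_lt(abs(log(f$adc) - log(g[["adc"]])), 1.5 * step_adc)
  }
})

test_that("median bias of noisy voxel fits stays below 3%", {
  sch <- zebra_scheme("full_cross")
  set.seed(13)
  n <- 150
  t2 <- adc <- numeric(n)
  for (i in seq_len(n)) {
    sig <- predict_signal(100, 0.05, 0.002, sch)
    e1 <- rnorm(nrow(sch), 0, 2); e2 <- rnorm(nrow(sch), 0, 2)
    f <- fit_voxel(sqrt((sig + e1)^2 + e2^2), sch)
    t2[i] <- f$t2star; adc[i] <- f$adc
  }
  expect_lt(abs(median(t2) - 0.05) / 0.05, 0.03)
  expect_lt(abs(median(adc) - 0.002) / 0.002, 0.03)
})

test_that("uniform noiseless ROI fit reproduces the truth exactly", {
  sch <- tiny_scheme()
  sig <- predict_signal(90, 0.07, 0.004, sch)
  arr <- array(rep(sig, each = 6 * 6 * 2), c(6, 6, 2, nrow(sch)))
  # array recycling above fills voxel-major; rebuild measurement-major
  arr <- aperm(array(rep(sig, times = 6 * 6 * 2),
                     c(nrow(sch), 6, 6, 2)), c(2, 3, 4, 1))
  st <- volume_stack(arr, 3, sch)
  m <- array(TRUE, c(6, 6, 2))
  res <- fit_roi(st, roi_mask(m), sch)
  expect_equal(res$summary$mean_t2star_ms, 70, tolerance = 1e-6)
  expect_equal(res$summary$mean_adc, 0.004, tolerance = 1e-6)
  expect_equal(res$summary$n_failed, 0)
  expect_equal(res$summary$volume_mm3, 6 * 6 * 2 * 27)
  # single-voxel mask equals that voxel's fit
  m1 <- array(FALSE, c(6, 6, 2)); m1[2, 3, 1] <- TRUE
  res1 <- fit_roi(st, roi_mask(m1), sch)
  expect_equal(res1$summary$n_voxels, 1)
  expect_equal(res1$summary$mean_t2star_ms,
               fit_voxel(sig, sch)$t2star * 1000)
})
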