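test_that("pure-component voxels recover weight one exactly", {
  sch <- tiny_scheme()
  g <- spectral_grid(15, 15)
  cs <- well_separated_components(g)
  B <- component_signals(cs, sch)
  for (k in 1:3) {
    y <- matrix(120 * B[, k], nrow = 1)
    wm <- fit_weights_reduced(y, components = cs, scheme = sch)
    expected <- numeric(3); expected[k] <- 1
    expect_equal(as.numeric(wm$weights), expected, tolerance = 1e-9)
    expect_equal(wm$s0, 120, tolerance = 1e-9)
  }
})

test_that("even mixtures match the exhaustive quadratic-program oracle", {
  sch <- tiny_scheme()
  g <- spectral_grid(15, 15)
  cs <- well_separated_components(g)
  B <- component_signals(cs, sch)
  y <- as.numeric(100 * (0.5 * B[, 1] + 0.5 * B[, 2]))
  wm <- fit_weights_reduced(matrix(y, 1), components = cs, scheme = sch)
  expect_equal(as.numeric(wm$weights), c(0.5, 0.5, 0), tolerance = 1e-6)
  oracle <- nnls_enumerate(B, y)
  expect_equal(as.numeric(wm$weights * wm$s0), oracle, tolerance = 1e-8)
})

test_that("reduced mode is exact on noiseless phantoms", {
  sch <- tiny_scheme()
  g <- spectral_grid(15, 15)
  cs <- well_separated_components(g)
  ph <- make_phantom(c(10, 10, 4), sch, cs, class_weights = simple_cw(),
                     snr = Inf, seed = 6)
  wm <- fit_weights_reduced(ph$stack, ph$mask, cs, sch)
  ms <- placentadr:::masked_signals(ph$stack, ph$mask)
  sse <- reconstruction_sse(wm, ms$signals, sch)
  expect_lt(sse / sum(ms$signals^2), 1e-10)
  expect_equal(wm$weights, ph$truth$true_weights,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(rowSums(wm$weights), rep(1, nrow(wm$weights)),
               tolerance = 1e-9)
})

test_that("noisy phantoms recover weights with high voxelwise correlation", {
  sch <- tiny_scheme()
  g <- spectral_grid(15, 15)
  cs <- well_separated_components(g)
  cw <- matrix(c(0.8, 0.15, 0.05,
                 0.10, 0.80, 0.10,
                 0.05, 0.15, 0.80,
                 0.40, 0.30, 0.30), 4, 3, byrow = TRUE)
  ph <- make_phantom(c(12, 12, 4), sch, cs, class_weights = cw, snr = 100,
                     seed = 8)
  wm <- fit_weights_reduced(ph$stack, ph$mask, cs, sch)
  for (k in 1:3) {
    expect_gte(cor(wm$weights[, k], ph$truth$true_weights[, k]), 0.95)
  }
})

test_that("all-zero voxels are flagged and excluded from region means", {
  sch <- tiny_scheme()
  g <- spectral_grid(15, 15)
  cs <- well_separated_components(g)
  B <- component_signals(cs, sch)
  sig <- rbind(100 * B[, 1], 0 * B[, 1])
  wm <- fit_weights_reduced(sig, components = cs, scheme = sch)
  expect_equal(wm$flagged, c(FALSE, TRUE))
  mw <- mean_roi_weightings(wm)
  expect_equal(unname(mw), c(1, 0, 0), tolerance = 1e-9)
  # averaging behaviour: half pure 1, half pure 2
  sig2 <- rbind(100 * B[, 1], 100 * B[, 1], 50 * B[, 2], 80 * B[, 2])
  wm2 <- fit_weights_reduced(sig2, components = cs, scheme = sch)
  expect_equal(unname(mean_roi_weightings(wm2)), c(0.5, 0.5, 0),
               tolerance = 1e-8)
  # uniform weights average to themselves
  sigu <- matrix(rep(as.numeric(B %*% rep(1 / 3, 3)) * 90, 3),
                 nrow = 3, byrow = TRUE)
  wmu <- fit_weights_reduced(sigu, components = cs, scheme = sch)
  expect_equal(unname(mean_roi_weightings(wmu)), rep(1 / 3, 3),
               tolerance = 1e-6)
})

test_that("collinear component signals are reported", {
  sch <- tiny_scheme()
  g <- spectral_grid(15, 15)
  spec <- matrix(0, g$J, 2)
  spec[100, ] <- 1  # identical spectra -> collinear signals
  cs <- component_set(spec, g, reorder = FALSE)
  expect_warning(
    fit_weights_reduced(matrix(runif(16, 10, 50), 1), components = cs,
                        scheme = sch),
    "collinear"
  )
})

test_that("weight maps serialise to a 4D NIfTI volume", {
  sch <- tiny_scheme()
  g <- spectral_grid(12, 12)
  cs <- well_separated_components(g)
  ph <- make_phantom(c(8, 8, 4), sch, cs, class_weights = simple_cw(),
                     snr = Inf, seed = 3)
  wm <- fit_weights_reduced(ph$stack, ph$mask, cs, sch)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_weight_maps(wm, c(8, 8, 4), path)
  img <- RNifti::readNifti(path)
  expect_equal(dim(img), c(8, 8, 4, 3))
  arr <- array(as.numeric(img), dim(img))
  v <- ph$truth$voxel_index[1]
  expect_equal(arr[cbind(which(ph$mask$mask, arr.ind = TRUE)[1, , drop = FALSE],
                         1)][1],
               wm$weights[1, 1], tolerance = 1e-12)
})
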