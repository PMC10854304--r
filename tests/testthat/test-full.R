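# Full-mode decomposition tests use a coarse grid and the reduced scheme to
# keep runtimes modest; the algorithm is identical at larger sizes.

test_that("full decomposition recovers well-separated spectra and weights", {
  sch <- tiny_scheme()
  g <- spectral_grid(15, 15)
  cs <- well_separated_components(g)
  cw <- matrix(c(0.85, 0.10, 0.05,
                 0.10, 0.80, 0.10,
                 0.05, 0.10, 0.85,
                 0.40, 0.30, 0.30), 4, 3, byrow = TRUE)
  ph <- make_phantom(c(10, 10, 4), sch, cs, class_weights = cw, snr = Inf,
                     seed = 31)
  dec <- fit_full(ph$stack, ph$mask, sch, K = 3, grid = g, lambda = 0,
                  n_restarts = 2, seed = 17, max_iter = 120)
  expect_s3_class(dec, "decomposition_result")
  # objective decreases monotonically
  expect_true(all(diff(dec$objective_trace) <=
                    1e-9 * dec$objective_trace[1]))
  # matched peak locations within one grid cell of the truth
  perm <- match_components(cs, dec$components)
  for (k in 1:3) {
    jt <- which.max(cs$spectra[, k])
    je <- which.max(dec$components$spectra[, perm[k]])
    it <- c((jt - 1) %/% 15, (jt - 1) %% 15)
    ie <- c((je - 1) %/% 15, (je - 1) %% 15)
    expect_lte(max(abs(it - ie)), 1)
  }
  # weights correlate strongly with the generating truth
  W <- dec$weight_maps[[1]]$weights[, perm, drop = FALSE]
  for (k in 1:3) {
    expect_gte(cor(W[, k], ph$truth$true_weights[, k]), 0.9)
  }
  # weight rows stay on the simplex, spectra at unit mass
  expect_equal(rowSums(W), rep(1, nrow(W)), tolerance = 1e-9)
  expect_equal(unname(colSums(dec$components$spectra)), rep(1, 3),
               tolerance = 1e-9)
})

test_that("decomposition is deterministic in data and seed", {
  sch <- tiny_scheme()
  g <- spectral_grid(12, 12)
  cs <- well_separated_components(g)
  ph <- make_phantom(c(8, 8, 4), sch, cs, class_weights = simple_cw(),
                     snr = 80, seed = 5)
  run <- function(seed) {
    fit_full(ph$stack, ph$mask, sch, K = 2, grid = g, lambda = 0.01,
             n_restarts = 2, seed = seed, max_iter = 40)
  }
  a <- run(3); b <- run(3); c <- run(4)
  expect_identical(a$components$spectra, b$components$spectra)
  expect_identical(a$weight_maps[[1]]$weights, b$weight_maps[[1]]$weights)
  expect_identical(a$objective_trace, b$objective_trace)
  expect_false(identical(a$objective_trace, c$objective_trace))
})

test_that("optimised fit dominates a reduced fit with its own initialisation", {
  sch <- tiny_scheme()
  g <- spectral_grid(12, 12)
  cs <- well_separated_components(g)
  ph <- make_phantom(c(8, 8, 4), sch, cs, class_weights = simple_cw(),
                     snr = 60, seed = 12)
  ms <- placentadr:::masked_signals(ph$stack, ph$mask)
  seed0 <- placentadr:::derive_seeds(17, 1)[1]
  A <- build_dictionary(sch, g)
  F0 <- placentadr:::init_spectra(ms$signals, A, crossprod(A), 3, g, seed0,
                                  150)
  init_set <- component_set(F0, g, reorder = FALSE)
  wm0 <- fit_weights_reduced(ms$signals, components = init_set, scheme = sch)
  sse0 <- reconstruction_sse(wm0, ms$signals, sch)
  dec <- fit_full(ph$stack, ph$mask, sch, K = 3, grid = g, lambda = 0,
                  n_restarts = 1, seed = 17)
  expect_lte(dec$sse, sse0 + 1e-9 * sse0)
})

test_that("pooling several scans uses every mask and errors usefully", {
  sch <- tiny_scheme()
  g <- spectral_grid(12, 12)
  cs <- well_separated_components(g)
  a <- make_phantom(c(8, 8, 4), sch, cs, class_weights = simple_cw(),
                    snr = Inf, seed = 1)
  b <- make_phantom(c(8, 8, 4), sch, cs, class_weights = simple_cw(),
                    snr = Inf, seed = 2)
  dec <- fit_full(list(a$stack, b$stack), list(a$mask, b$mask), sch, K = 2,
                  grid = g, lambda = 0, n_restarts = 1, seed = 2,
                  max_iter = 30)
  expect_length(dec$weight_maps, 2)
  expect_equal(nrow(dec$weight_maps[[1]]$weights), sum(a$mask$mask))
  expect_error(fit_full(a$stack, a$mask, sch, K = 0, grid = g), "K")
  expect_error(
    fit_full(matrix(runif(5 * 16), 5, 16), scheme = sch, K = 2, grid = g),
    "10\\*K"
  )
})
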