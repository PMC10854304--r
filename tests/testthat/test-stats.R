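test_that("shapiro-wilk behaves as documented at the contract edges", {
  # exact normal quantiles are as normal as a sample can be
  q <- qnorm(((1:20) - 0.5) / 20)
  res <- shapiro_wilk(q)
  expect_gt(res$W, 0.99)
  # exponentially spaced data are reliably non-normal at n = 50
  set.seed(1)
  rej <- mean(replicate(100, shapiro_wilk(rexp(50))$p_value < 0.05))
  expect_gte(rej, 0.95)
  expect_error(shapiro_wilk(rep(2, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("ancova equals the explicit normal-equations oracle", {
  # fixed 8-row table
  tab <- tibble::tibble(
    group = c("control", "control", "control", "control",
              "chd", "chd", "chd", "chd"),
    ga_weeks = c(24, 28, 31, 36, 25, 29, 32, 37),
    maternal_age = c(31, 35, 29, 38, 27, 33, 36, 30),
    outcome = c(61.2, 55.4, 50.1, 44.9, 52.3, 48.8, 45.0, 40.2)
  )
  a <- ancova_group_effect(tab, "outcome")
  o <- ancova_oracle(tab, "outcome")
  expect_equal(a$f_stat, o$f, tolerance = 1e-10)
  expect_equal(a$p_value, o$p, tolerance = 1e-10)
  expect_equal(a$group_effect, -unname(o$group_effect), tolerance = 1e-10)
  expect_equal(a$df_den, o$df_den)
  # random tables, 8-30 rows
  for (rep in 1:10) {
    tb <- random_cohort_table(sample(8:30, 1), seed = 100 + rep)
    a2 <- ancova_group_effect(tb, "outcome")
    o2 <- ancova_oracle(tb, "outcome")
    expect_equal(a2$f_stat, o2$f, tolerance = 1e-10)
    expect_equal(a2$p_value, o2$p, tolerance = 1e-10)
  }
})

test_that("ancova is invariant to outcome location shifts", {
  tb <- random_cohort_table(20, seed = 9)
  a <- ancova_group_effect(tb, "outcome")
  tb2 <- dplyr::mutate(tb, outcome = outcome + 1000)
  b <- ancova_group_effect(tb2, "outcome")
  expect_equal(a$f_stat, b$f_stat, tolerance = 1e-9)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-9)
})

test_that("ancova rejects degenerate designs and bad tables", {
  tb <- random_cohort_table(20, seed = 2)
  tb$maternal_age <- tb$ga_weeks  # collinear covariates
  expect_error(ancova_group_effect(tb, "outcome"), "rank-deficient")
  tb2 <- random_cohort_table(20, seed = 3)
  tb2$group <- "control"
  expect_error(ancova_group_effect(tb2, "outcome"), "two levels")
  expect_error(ancova_group_effect(tb2[0, ], "outcome"))
  tb3 <- random_cohort_table(20, seed = 4)
  tb3$outcome[3] <- NA
  expect_error(ancova_group_effect(tb3, "outcome"), "missing")
})

test_that("pearson trends recover exact linear relations", {
  tb <- tibble::tibble(group = "control", ga_weeks = c(22, 26, 30, 34, 38))
  tb$up <- 2 * tb$ga_weeks + 1
  tb$down <- -tb$ga_weeks
  expect_equal(pearson_trend(tb, "up", "control")$pearson_r, 1)
  expect_equal(pearson_trend(tb, "down", "control")$pearson_r, -1)
  # affine invariance (sign-preserving)
  set.seed(5)
  tb$noisy <- tb$ga_weeks + rnorm(5)
  r1 <- pearson_trend(tb, "noisy", "control")
  tb$noisy <- 3.2 * tb$noisy + 17
  r2 <- pearson_trend(tb, "noisy", "control")
  expect_equal(r1$pearson_r, r2$pearson_r, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  tb$flat <- 5
  expect_error(pearson_trend(tb, "flat", "control"), "constant")
  expect_error(pearson_trend(tb[1:2, ], "up", "control"), "3 rows")
})

test_that("fdr correction reproduces the worked step-up example", {
  res <- bh_fdr(c(0.005, 0.011, 0.02, 0.04, 0.1))
  expect_equal(res$p_fdr, c(0.025, 0.0275, 1 / 30, 0.05, 0.1),
               tolerance = 1e-12)
  expect_equal(res$significant, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(bh_fdr(0.03)$p_fdr, 0.03)  # single test: adjusted = raw
  z <- bh_fdr(rep(0, 4))
  expect_true(all(z$p_fdr == 0) && all(z$significant))
  expect_error(bh_fdr(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("fdr correction equals the brute-force definition on random input", {
  set.seed(99)
  for (rep in 1:200) {
    p <- runif(sample(1:25, 1))^sample(1:3, 1)
    expect_identical(bh_fdr(p)$p_fdr, bh_stepup_brute(p))
  }
})

test_that("component analysis emits three corrected families", {
  rec <- simulate_cohort(cohort_spec(), seed = 11)
  res <- component_weighting_analysis(rec, 7)
  expect_equal(nrow(res), 21)
  expect_equal(unname(table(res$family)), rep(7L, 3), ignore_attr = TRUE)
  # adjusted never below raw; correction applied within family
  expect_true(all(res$p_fdr >= res$p_raw - 1e-15))
  for (fam in unique(res$family)) {
    sub <- res[res$family == fam, ]
    expect_equal(sub$p_fdr, bh_stepup_brute(sub$p_raw), tolerance = 1e-12)
  }
  expect_error(component_weighting_analysis(rec[, 1:4], 7), "weighting")
})

test_that("the diverging component is flagged in the group family", {
  rec <- simulate_cohort(divergent_cohort_spec(component = 3), seed = 21)
  res <- component_weighting_analysis(rec, 7)
  expect_true(res$significant[res$family == "group_comparison" &
                                res$component == 3])
})

test_that("descriptives switch format on normality", {
  set.seed(8)
  tab <- tibble::tibble(
    group = rep(c("control", "chd"), each = 40),
    x = c(rnorm(40, 10), rexp(40))
  )
  d <- describe_by_group(tab, "x")
  expect_true(d$normal[d$group == "control"])
  expect_false(d$normal[d$group == "chd"])
  expect_match(d$label[d$group == "chd"], "-")
})
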