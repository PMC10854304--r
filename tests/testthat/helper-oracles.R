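# Independent oracles used across the suite. These deliberately use the
# most literal, brute-force formulation of each quantity and never call the
# package's own solvers.

# Exhaustive active-set NNLS: try every subset of columns, solve the
# unconstrained least squares on the subset, keep feasible solutions, return
# the feasible solution with minimal SSE. Exact for small K.
nnls_enumerate <- function(A, y) {
  K <- ncol(A)
  best <- rep(0, K)
  best_sse <- sum(y^2)
  subsets <- unlist(lapply(seq_len(K), function(k) {
    utils::combn(K, k, simplify = FALSE)
  }), recursive = FALSE)
  for (s in subsets) {
    As <- A[, s, drop = FALSE]
    coef <- tryCatch(qr.solve(As, y), error = function(e) NULL)
    if (is.null(coef) || any(coef < -1e-12)) next
    sse <- sum((y - As %*% pmax(coef, 0))^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- rep(0, K)
      best[s] <- pmax(coef, 0)
    }
  }
  best
}

# Exhaustive-search oracle for the voxelwise T2*-ADC fit: evaluate the SSE on
# a dense log-spaced (T2*, ADC) grid with the profiled-out optimal S0 per
# cell, and return the best cell.
grid_search_fit <- function(signal, scheme, n_t2 = 200, n_adc = 200,
                            t2_range = c(0.005, 0.5),
                            adc_range = c(1e-5, 1.0)) {
  t2_grid <- exp(seq(log(t2_range[1]), log(t2_range[2]), length.out = n_t2))
  adc_grid <- exp(seq(log(adc_range[1]), log(adc_range[2]),
                      length.out = n_adc))
  dte <- scheme$te - min(scheme$te)
  shapes_t2 <- exp(-outer(dte, 1 / t2_grid))     # M x n_t2
  shapes_adc <- exp(-outer(scheme$b, adc_grid))  # M x n_adc
  best <- c(sse = Inf, t2 = NA, adc = NA, i = NA, j = NA, s0 = NA)
  yy <- sum(signal^2)
  for (j in seq_len(n_adc)) {
    D <- shapes_t2 * shapes_adc[, j]             # M x n_t2
    dy <- crossprod(D, signal)                   # n_t2
    dd <- colSums(D^2)
    sse <- yy - dy^2 / dd
    i <- which.min(sse)
    if (sse[i] < best["sse"]) {
      best <- c(sse = sse[i], t2 = t2_grid[i], adc = adc_grid[j],
                i = i, j = j, s0 = dy[i] / dd[i])
    }
  }
  best
}

# Brute-force Benjamini-Hochberg step-up: the literal definition,
# p_(i) -> min_{j >= i} m p_(j) / j, capped at 1, mapped back to input order.
bh_stepup_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m / (i:m) * ps[i:m]))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Explicit normal-equations ANCOVA oracle: builds the design matrix by hand,
# solves via the projection matrix, and forms the partial F for the group
# column from the residual sums of squares of the two models.
ancova_oracle <- function(table, outcome,
                          covariates = c("ga_weeks", "maternal_age")) {
  y <- table[[outcome]]
  gind <- as.numeric(factor(table$group)) - 1
  X_full <- cbind(1, gind, as.matrix(table[covariates]))
  X_red <- cbind(1, as.matrix(table[covariates]))
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  rss_f <- rss(X_full)
  rss_r <- rss(X_red)
  df_den <- nrow(X_full) - ncol(X_full)
  f <- (rss_r - rss_f) / (rss_f / df_den)
  p <- stats::pf(f, 1, df_den, lower.tail = FALSE)
  beta_full <- solve(t(X_full) %*% X_full, t(X_full) %*% y)
  list(f = f, p = p, group_effect = beta_full[2], df_den = df_den)
}

# Exhaustive assignment oracle: minimum-cost bijection by enumerating all
# permutations (fine for K <= 7).
assignment_enumerate <- function(cost) {
  n <- nrow(cost)
  perms <- gtools_permutations(n)
  best <- NULL
  best_cost <- Inf
  for (r in seq_len(nrow(perms))) {
    pm <- perms[r, ]
    cc <- sum(cost[cbind(seq_len(n), pm)])
    if (cc < best_cost) { best_cost <- cc; best <- pm }
  }
  best
}

# all permutations of 1..n without extra dependencies
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

# small helpers shared by tests
tiny_scheme <- function() zebra_scheme("reduced_test")

well_separated_components <- function(grid = spectral_grid(20, 20)) {
  make_component_spectra(grid, list(
    list(list(t2star = 0.03, adc = 6e-4, log_width = 0, mass = 1)),
    list(list(t2star = 0.08, adc = 0.01, log_width = 0, mass = 1)),
    list(list(t2star = 0.15, adc = 0.05, log_width = 0, mass = 1))
  ))
}

simple_cw <- function() {
  matrix(c(1, 0, 0,
           0, 1, 0,
           0, 0, 1,
           0.5, 0.5, 0), 4, 3, byrow = TRUE)
}

random_cohort_table <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    group = sample(rep(c("control", "chd"), length.out = n)),
    ga_weeks = runif(n, 22, 40),
    maternal_age = runif(n, 25, 42),
    outcome = rnorm(n)
  )
}
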