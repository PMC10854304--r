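#' Non-negative least squares on a small design
#'
#' Thin wrapper around the Lawson-Hanson active-set solver
#' (`pracma::lsqnonneg`) used for all per-voxel weight solves (designs with
#' at most a few dozen columns).
#'
#' @param A M x K design matrix.
#' @param y Length-M response.
#' @return Non-negative coefficient vector of length K.
#' @keywords internal
nnls_small <- function(A, y) {
  res <- tryCatch(pracma::lsqnonneg(A, y)$x, error = function(e) NULL)
  if (is.null(res)) {
    # active-set cycling on (near-)degenerate designs: fall back to the
    # monotone projected-gradient solve of the same problem
    res <- as.numeric(nnls_gram(crossprod(A), as.numeric(crossprod(A, y)),
                                max_iter = 2000, tol = 1e-14))
  }
  res
}

# Non-negative quadratic minimisation given Gram matrix G = X'X (+ penalty)
# and g = X'y: accelerated projected gradient with a 1/L step (L = largest
# eigenvalue of G), monotone by restart. Used for the high-dimensional
# spectra solves where forming the stacked design would be wasteful.
nnls_gram <- function(G, g, x0 = NULL, max_iter = 300, tol = 1e-10) {
  J <- length(g)
  if (is.null(x0)) x0 <- pmax(g, 0) / max(diag(G))
  L <- pg_lipschitz(G)
  step <- 1 / L
  x <- pmax(x0, 0)
  zc <- x
  tt <- 1
  fx <- 0.5 * sum(x * (G %*% x)) - sum(g * x)
  for (it in seq_len(max_iter)) {
    grad <- G %*% zc - g
    x_new <- pmax(zc - step * grad, 0)
    f_new <- 0.5 * sum(x_new * (G %*% x_new)) - sum(g * x_new)
    if (f_new > fx) {  # restart acceleration from the last monotone iterate
      zc <- x
      x_new <- pmax(zc - step * (G %*% zc - g), 0)
      f_new <- 0.5 * sum(x_new * (G %*% x_new)) - sum(g * x_new)
      tt <- 1
    }
    t_new <- (1 + sqrt(1 + 4 * tt^2)) / 2
    zc <- x_new + ((tt - 1) / t_new) * (x_new - x)
    if (abs(fx - f_new) <= tol * max(1, abs(fx))) {
      x <- x_new
      break
    }
    x <- x_new
    fx <- f_new
    tt <- t_new
  }
  x
}

# power-iteration estimate of the largest eigenvalue (deterministic start)
pg_lipschitz <- function(G) {
  v <- rep(1 / sqrt(nrow(G)), nrow(G))
  lam <- 1
  for (i in 1:30) {
    w <- G %*% v
    lam <- sqrt(sum(w * w))
    if (lam == 0) return(1)
    v <- w / lam
  }
  lam * 1.01  # small safety margin
}
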