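#' Data-driven spectral decomposition (full mode)
#'
#' Learns K tissue-environment components -- each a non-negative unit-mass
#' spectrum over the (T2*, ADC) grid -- together with per-voxel non-negative
#' weights, from one or several scans pooled voxelwise. The model for voxel
#' v is
#'
#'   S_v  =  s0_v * sum_k w_vk * (A f_k),
#'
#' with A the signal dictionary over the grid and f_k the component spectra,
#' and the fit minimises the summed squared reconstruction error plus an
#' optional spectral roughness penalty lambda * ||L f_k||^2 (L a normalised
#' grid Laplacian).
#'
#' The solver is deterministic given a seed: per-voxel regularised
#' non-negative grid inversion provides voxel spectra, seeded k-means++
#' clustering of those spectra provides K initial components, and block
#' alternating non-negative least squares (exact active-set solves for the
#' weights, monotone projected-gradient solves for the spectra) refines them
#' until the relative objective decrease falls below `tol`. Several restarts
#' with distinct sub-seeds are run and the best objective kept. Components
#' are finally renormalised to unit mass, the scales folded into s0, and
#' ordered canonically (ascending spectrum-weighted mean log T2*).
#'
#' @param stacks A `volume_stack`, list of them, or a pooled V x M signal
#'   matrix.
#' @param masks An `roi_mask` or list matching `stacks` (ignored for matrix
#'   input).
#' @param scheme The acquisition scheme.
#' @param K Number of components (default 7, the number found to best
#'   explain placental and adjacent uterine-wall T2*-diffusion signal).
#' @param grid Spectral grid (default [spectral_grid()]).
#' @param lambda Roughness penalty weight (default 0.01; 0 disables).
#' @param n_restarts Restarts with distinct sub-seeds (default 5).
#' @param max_iter Maximum outer iterations (default 200).
#' @param tol Relative objective-decrease convergence threshold (1e-6).
#' @param seed Integer seed controlling all randomness.
#' @param inner_iter Projected-gradient iterations per spectra solve.
#' @return A `decomposition_result`: `components` (`component_set`),
#'   `weight_maps` (list, one per input scan), `objective_trace`
#'   (non-increasing), `sse`, `seed`, `restarts_used`, `converged`.
#' @export
fit_full <- function(stacks, masks = NULL, scheme, K = 7,
                     grid = spectral_grid(), lambda = 0.01,
                     n_restarts = 5, max_iter = 200, tol = 1e-6,
                     seed = 1, inner_iter = 150) {
  if (K < 1) stop("K must be >= 1")
  pooled <- pool_scans(stacks, masks)
  S <- pooled$signals
  V <- nrow(S)
  if (V < 10 * K) stop("need at least 10*K pooled masked voxels, got ", V)
  if (nrow(scheme) != ncol(S)) stop("signal length does not match scheme")

  A <- build_dictionary(scheme, grid)
  AtA <- crossprod(A)
  if (K > qr(S)$rank) {
    warning("K = ", K, " exceeds the numerical rank of the pooled data (",
            qr(S)$rank, "); proceeding")
  }
  LtL <- if (lambda > 0) {
    Lp <- grid_laplacian(grid)
    lambda * crossprod(Lp)
  } else NULL

  best <- NULL
  sub_seeds <- derive_seeds(seed, n_restarts)
  for (r in seq_len(n_restarts)) {
    run <- fit_full_once(S, A, AtA, LtL, K, grid, max_iter, tol,
                         sub_seeds[r], inner_iter)
    if (is.null(best) || run$objective < best$objective) best <- run
  }

  # fold spectrum masses into the coefficients, then normalise
  Fm <- best$F
  mass <- colSums(Fm)
  Fm <- sweep(Fm, 2, mass, "/")
  C <- sweep(best$C, 2, mass, "*")
  cs <- component_set(Fm, grid, reorder = TRUE)
  C <- C[, cs$permutation, drop = FALSE]
  s0 <- rowSums(C)
  flagged <- s0 <= 0
  W <- C
  W[!flagged, ] <- C[!flagged, , drop = FALSE] / s0[!flagged]

  wms <- purrr::map(seq_along(pooled$slices), function(i) {
    rows <- pooled$slices[[i]]
    structure(
      list(weights = W[rows, , drop = FALSE], s0 = s0[rows],
           flagged = flagged[rows], coords = pooled$coords[[i]],
           index = pooled$index[[i]], components = cs),
      class = "weight_maps"
    )
  })
  structure(
    list(components = cs, weight_maps = wms,
         objective_trace = best$trace, sse = best$sse, seed = seed,
         restarts_used = n_restarts, converged = best$converged),
    class = "decomposition_result"
  )
}

# pool masked voxel signals from one or several scans
pool_scans <- function(stacks, masks) {
  if (is.matrix(stacks)) {
    return(list(signals = stacks, slices = list(seq_len(nrow(stacks))),
                coords = list(NULL), index = list(NULL)))
  }
  if (inherits(stacks, "volume_stack")) {
    stacks <- list(stacks)
    masks <- list(masks)
  }
  sigs <- list(); slices <- list(); coords <- list(); index <- list()
  at <- 0
  for (i in seq_along(stacks)) {
    ms <- masked_signals(stacks[[i]], masks[[i]])
    sigs[[i]] <- ms$signals
    slices[[i]] <- at + seq_len(nrow(ms$signals))
    coords[[i]] <- tibble::as_tibble(ms$coords)
    index[[i]] <- ms$index
    at <- at + nrow(ms$signals)
  }
  if (at == 0) stop("empty pooled mask")
  list(signals = do.call(rbind, sigs), slices = slices,
       coords = coords, index = index)
}

# one restart of the alternating minimisation
fit_full_once <- function(S, A, AtA, LtL, K, grid, max_iter, tol, seed,
                          inner_iter) {
  Fm <- init_spectra(S, A, AtA, K, grid, seed, inner_iter)
  V <- nrow(S)
  C <- matrix(0, V, K)
  trace <- numeric(0)
  obj_prev <- Inf
  converged <- FALSE
  penalty <- function(Fm) {
    if (is.null(LtL)) 0 else sum(vapply(seq_len(ncol(Fm)), function(k) {
      sum(Fm[, k] * (LtL %*% Fm[, k]))
    }, numeric(1)))
  }
  for (it in seq_len(max_iter)) {
    # weights step: exact per-voxel NNLS given current spectra
    B <- A %*% Fm
    for (v in seq_len(V)) C[v, ] <- nnls_small(B, S[v, ])
    R <- S - C %*% t(B)
    # spectra step: monotone non-negative solve per component, warm-started
    for (k in seq_len(K)) {
      ck <- C[, k]
      c2 <- sum(ck^2)
      if (c2 == 0) next
      Rk_tc <- crossprod(R, ck) + c2 * (B[, k])   # t(R_k) %*% ck
      g <- crossprod(A, Rk_tc)
      G <- c2 * AtA
      if (!is.null(LtL)) G <- G + LtL
      f_new <- nnls_gram(G, as.numeric(g), x0 = Fm[, k],
                         max_iter = inner_iter)
      if (sum(f_new) > 0) {
        R <- R + ck %*% t(B[, k])          # remove old contribution
        Fm[, k] <- f_new
        B[, k] <- A %*% f_new
        R <- R - ck %*% t(B[, k])          # add new contribution
      }
    }
    obj <- sum(R^2) + penalty(Fm)
    trace <- c(trace, obj)
    if (is.finite(obj_prev) &&
        (obj_prev - obj) <= tol * max(obj_prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }
  # final exact weights for the final spectra
  B <- A %*% Fm
  for (v in seq_len(V)) C[v, ] <- nnls_small(B, S[v, ])
  sse <- sum((S - C %*% t(B))^2)
  list(F = Fm, C = C, objective = sse + penalty(Fm), sse = sse,
       trace = trace, converged = converged)
}

# initial spectra: regularised per-voxel grid inversion + seeded k-means++
init_spectra <- function(S, A, AtA, K, grid, seed, inner_iter) {
  J <- ncol(A)
  V <- nrow(S)
  alpha <- 1e-3 * mean(diag(AtA))
  G <- AtA + alpha * diag(J)
  L <- pg_lipschitz(G)
  step <- 1 / L
  Gm <- crossprod(A, t(S))            # J x V
  X <- pmax(Gm, 0) / max(diag(AtA))   # J x V start
  for (i in seq_len(100)) {
    X <- pmax(X - step * (G %*% X - Gm), 0)
  }
  mass <- colSums(X)
  keep <- mass > 0
  Xn <- t(sweep(X[, keep, drop = FALSE], 2, mass[keep], "/"))  # voxels x J
  centers <- with_local_seed(seed, kmeanspp_centers(Xn, K))
  km <- tryCatch(
    with_local_seed(seed, stats::kmeans(
      Xn, centers = centers, iter.max = 25, algorithm = "Lloyd"
    )),
    error = function(e) NULL
  )
  # Lloyd can fail on degenerate data (duplicate points, empty clusters);
  # the k-means++ seeds themselves are then used as the initial spectra
  Fm <- if (is.null(km)) t(centers) else t(km$centers)  # J x K
  Fm[Fm < 0] <- 0
  for (k in seq_len(K)) {
    if (sum(Fm[, k]) <= 0) Fm[, k] <- rep(1 / nrow(Fm), nrow(Fm))
  }
  sweep(Fm, 2, colSums(Fm), "/")
}

# k-means++ seeding (deterministic under the caller-set RNG state)
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  if (K > n) stop("more clusters than points")
  idx <- integer(K)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums((X - matrix(X[idx[1], ], n, ncol(X), byrow = TRUE))^2)
  for (k in seq_len(K)[-1]) {
    p <- d2 / sum(d2)
    if (all(!is.finite(p)) || sum(d2) == 0) {
      idx[k] <- sample.int(n, 1)
    } else {
      idx[k] <- sample.int(n, 1, prob = p)
    }
    d2k <- rowSums((X - matrix(X[idx[k], ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, d2k)
  }
  X[idx, , drop = FALSE] + 0  # plain matrix of K centers
}

# run code under a temporary RNG state, restoring the caller's state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# deterministic sub-seed derivation below 2^31
derive_seeds <- function(seed, n) {
  (as.numeric(seed) * 7919 + 104729 * seq_len(n)) %% 2147483647
}

# normalised 2-D lattice Laplacian over the spectral grid (J x J, sparse-ish
# dense matrix; J stays modest for the grids used here)
grid_laplacian <- function(grid) {
  n1 <- length(grid$t2star)  # slow axis in cell order
  n2 <- length(grid$adc)     # fast axis
  J <- grid$J
  L <- matrix(0, J, J)
  cell <- function(i_t2, i_adc) (i_t2 - 1) * n2 + i_adc
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      c0 <- cell(i, j)
      nbrs <- c(
        if (i > 1) cell(i - 1, j), if (i < n1) cell(i + 1, j),
        if (j > 1) cell(i, j - 1), if (j < n2) cell(i, j + 1)
      )
      L[c0, c0] <- 1
      L[c0, nbrs] <- -1 / length(nbrs)
    }
  }
  L
}
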