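#' Synthetic placental phantom
#'
#' Builds a digital phantom with the spatial organisation the decomposition
#' is sensitive to: a placental slab partitioned into lobules by seeded
#' nearest-centre assignment, with lobule-centre cores, peripheral annuli,
#' septa along inter-lobule boundaries, and a thin adjacent uterine-wall
#' layer. Each tissue class carries a fixed weight simplex over the supplied
#' components; the noiseless voxel signal is
#' `s0 * sum_k w_k * (dictionary signal of spectrum k)`, and Rician noise is
#' applied as `sqrt((S + e1)^2 + e2^2)` with `e ~ N(0, sigma^2)` and
#' `sigma = mean(s0) / snr`. Identical seeds give bit-identical phantoms.
#'
#' Class labels: 0 background, 1 lobule-centre, 2 lobule-periphery, 3 septa,
#' 4 uterine wall.
#'
#' @param shape Integer 3-vector (x, y, z), each >= (8, 8, 4).
#' @param scheme Acquisition scheme.
#' @param components A `component_set` (default
#'   [default_placenta_components()]).
#' @param class_weights 5-row (classes 1-4 + unused background row) x K
#'   matrix of simplex rows, or NULL for defaults matching the reported
#'   spatial contrasts (last component concentrated at lobule centres, first
#'   at peripheries, the septal component along boundaries and wall).
#' @param snr Signal-to-noise ratio at proton density (Inf for noiseless).
#' @param seed Integer seed.
#' @param n_lobules Number of lobule centres (default 5).
#' @param voxel_size Voxel size in mm (default 3).
#' @param noise Noise model, `"rician"` (default) or `"gaussian"` (analytic
#'   checks).
#' @param center_frac Radius fraction separating lobule-centre from
#'   periphery (default 0.6).
#' @return List: `stack` (`volume_stack`), `mask` (`roi_mask`), `truth`
#'   (class labels array, V x K true weight matrix + voxel index, true
#'   spectra, s0 map, noise sigma, seed).
#' @export
make_phantom <- function(shape, scheme,
                         components = default_placenta_components(),
                         class_weights = NULL, snr = Inf, seed = 1,
                         n_lobules = 5, voxel_size = 3,
                         noise = c("rician", "gaussian"),
                         center_frac = 0.6) {
  noise <- match.arg(noise)
  if (length(shape) != 3 || any(shape < c(8, 8, 4))) {
    stop("shape must be at least 8 x 8 x 4")
  }
  if (!(is.infinite(snr) || snr > 0)) stop("snr must be > 0 or Inf")
  K <- components$K
  if (is.null(class_weights)) class_weights <- default_class_weights(K)
  if (nrow(class_weights) < 4 || ncol(class_weights) != K) {
    stop("class_weights must have >= 4 rows and K columns")
  }
  if (any(class_weights < 0) ||
      any(abs(rowSums(class_weights[1:4, , drop = FALSE]) - 1) > 1e-9)) {
    stop("class weight rows must lie on the K-simplex")
  }

  geom <- with_local_seed(seed, phantom_geometry(shape, n_lobules,
                                                 center_frac))
  labels <- geom$labels
  mask <- labels > 0
  idx <- which(mask)
  V <- length(idx)

  # smooth multiplicative s0 field around 100 intensity units
  coords <- arrayInd(idx, shape)
  s0_vox <- 100 * (1 + 0.1 * sin(2 * pi * coords[, 1] / shape[1]) *
                     cos(2 * pi * coords[, 2] / shape[2]))
  s0_map <- array(0, shape)
  s0_map[idx] <- s0_vox

  W <- class_weights[labels[idx], , drop = FALSE]
  B <- component_signals(components, scheme)    # M x K
  noiseless <- (W %*% t(B)) * s0_vox            # V x M

  M <- nrow(scheme)
  arr <- array(0, c(shape, M))
  flat <- matrix(0, prod(shape), M)
  flat[idx, ] <- noiseless
  if (is.finite(snr)) {
    sigma <- mean(s0_vox) / snr
    flat <- with_local_seed(seed + 1, {
      if (noise == "rician") {
        e1 <- matrix(stats::rnorm(length(flat), 0, sigma), nrow(flat))
        e2 <- matrix(stats::rnorm(length(flat), 0, sigma), nrow(flat))
        sqrt((flat + e1)^2 + e2^2)
      } else {
        # magnitude data are non-negative; Gaussian noise is clipped at 0
        pmax(flat + matrix(stats::rnorm(length(flat), 0, sigma), nrow(flat)), 0)
      }
    })
    flat[-idx, ] <- 0
  } else {
    sigma <- 0
  }
  arr <- array(flat, c(shape, M))

  truth <- list(
    class_labels = labels,
    true_weights = W,
    voxel_index = idx,
    true_spectra = components,
    s0_map = s0_map,
    noise_sigma = sigma,
    seed = seed
  )
  list(
    stack = volume_stack(arr, voxel_size, scheme),
    mask = roi_mask(mask),
    truth = truth
  )
}

# default per-class component weights for K components: the last component
# dominates lobule centres, the first the periphery, a middle ("septal")
# component the septa and uterine wall
default_class_weights <- function(K) {
  if (K < 2) stop("need K >= 2 for distinct tissue classes")
  w <- matrix(0.05, nrow = 4, ncol = K)
  septal <- max(2, ceiling(K / 2))
  bump <- function(row, k, v) { row[k] <- row[k] + v; row }
  w[1, ] <- bump(w[1, ], K, 1)                       # lobule centre
  w[2, ] <- bump(w[2, ], 1, 1)                       # periphery
  w[3, ] <- bump(w[3, ], septal, 1)                  # septa
  w[4, ] <- bump(bump(w[4, ], septal, 0.6), max(1, septal - 1), 0.4)  # wall
  sweep(w, 1, rowSums(w), "/")
}

# lobule geometry by seeded rejection-sampled centres and nearest-centre
# assignment; septa where the two nearest centres are nearly equidistant
phantom_geometry <- function(shape, n_lobules, center_frac) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  wall_y <- 1:min(2, ny)                 # uterine wall slab at low y
  slab_y <- setdiff(seq_len(ny), wall_y)
  min_sep <- max(2, min(nx, length(slab_y)) / (n_lobules^(1 / 2) + 1))
  centers <- matrix(NA_real_, 0, 3)
  tries <- 0
  while (nrow(centers) < n_lobules && tries < 2000) {
    tries <- tries + 1
    cand <- c(stats::runif(1, 1, nx), stats::runif(1, min(slab_y), ny),
              stats::runif(1, 1, nz))
    if (nrow(centers) == 0 ||
        min(sqrt(colSums((t(centers) - cand)^2))) >= min_sep) {
      centers <- rbind(centers, cand)
    }
  }
  n_lob <- nrow(centers)
  labels <- array(0L, shape)
  territory <- array(0L, shape)
  for (x in seq_len(nx)) {
    for (y in seq_len(ny)) {
      for (z in seq_len(nz)) {
        d <- sqrt(colSums((t(centers) - c(x, y, z))^2))
        o <- order(d)
        d1 <- d[o[1]]
        d2 <- if (n_lob > 1) d[o[2]] else Inf
        territory[x, y, z] <- o[1]
        if (y %in% wall_y) {
          labels[x, y, z] <- 4L
        } else if (n_lob > 1 && (d2 - d1) <= 1) {
          labels[x, y, z] <- 3L
        } else if (d1 <= center_frac * (d1 + d2) / 2) {
          labels[x, y, z] <- 1L
        } else {
          labels[x, y, z] <- 2L
        }
      }
    }
  }
  list(labels = labels, centers = centers, territory = territory)
}
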