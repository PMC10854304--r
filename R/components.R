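#' Component sets: non-negative T2*-ADC spectra
#'
#' A `component_set` holds K tissue-environment spectra over a shared
#' spectral grid as a J x K non-negative matrix whose columns each sum to 1.
#' Components are kept in a canonical order, ascending in spectrum-weighted
#' mean log T2*, so that "component 1" is always the shortest-T2* (least
#' oxygenated) environment; component numbering from independent fits is
#' otherwise arbitrary and cross-run comparisons go through
#' [match_components()].
#'
#' @param spectra J x K non-negative matrix (columns are spectra).
#' @param grid The `spectral_grid` the rows are indexed by.
#' @param reorder Apply canonical ordering (default TRUE).
#' @return A `component_set`.
#' @export
component_set <- function(spectra, grid, reorder = TRUE) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) != grid$J) stop("spectra rows must equal grid$J")
  if (any(spectra < 0)) stop("spectra must be non-negative")
  mass <- colSums(spectra)
  if (any(mass <= 0)) stop("each spectrum must have positive mass")
  spectra <- sweep(spectra, 2, mass, "/")
  cs <- structure(list(spectra = spectra, grid = grid,
                       K = ncol(spectra)), class = "component_set")
  if (reorder) cs <- order_components(cs)
  cs
}

# spectrum-weighted mean log10 T2* per component (the canonical order key)
component_order_key <- function(cs) {
  as.numeric(crossprod(cs$spectra, log10(cs$grid$cells$t2star)))
}

order_components <- function(cs) {
  ord <- order(component_order_key(cs))
  cs$spectra <- cs$spectra[, ord, drop = FALSE]
  cs$permutation <- ord
  cs
}

#' Build component spectra from log-Gaussian peaks
#'
#' Each component is specified as a list of peaks; a peak is a list with
#' `t2star` (seconds), `adc` (mm^2/s), `log_width` (standard deviation in
#' log10 units, applied on both axes) and `mass` (fraction of the component,
#' summing to 1 over its peaks). The spectrum is the grid discretisation of
#' the sum of the peaks' bivariate log-Gaussians, renormalised to unit mass.
#' A `log_width` of 0 collapses the peak onto its nearest grid cell.
#'
#' @param grid A `spectral_grid`.
#' @param peaks_per_component List (length K) of lists of peak specs.
#' @return A `component_set` in canonical order.
#' @examples
#' g <- spectral_grid(20, 20)
#' cs <- make_component_spectra(g, list(
#'   list(list(t2star = 0.03, adc = 0.001, log_width = 0.05, mass = 1)),
#'   list(list(t2star = 0.15, adc = 0.3, log_width = 0.05, mass = 1))
#' ))
#' colSums(cs$spectra)
#' @export
make_component_spectra <- function(grid, peaks_per_component) {
  lt2 <- log10(grid$cells$t2star)
  ladc <- log10(grid$cells$adc)
  spectra <- vapply(peaks_per_component, function(peaks) {
    masses <- vapply(peaks, function(p) p$mass, numeric(1))
    if (abs(sum(masses) - 1) > 1e-6) {
      stop("peak masses of a component must sum to 1")
    }
    v <- numeric(grid$J)
    for (p in peaks) {
      if (p$t2star < min(grid$t2star) || p$t2star > max(grid$t2star) ||
          p$adc < min(grid$adc) || p$adc > max(grid$adc)) {
        stop("peak centre (", p$t2star, ", ", p$adc, ") outside grid range")
      }
      if (p$log_width <= 0) {
        j <- which.min((lt2 - log10(p$t2star))^2 + (ladc - log10(p$adc))^2)
        v[j] <- v[j] + p$mass
      } else {
        d2 <- (lt2 - log10(p$t2star))^2 + (ladc - log10(p$adc))^2
        kern <- exp(-d2 / (2 * p$log_width^2))
        v <- v + p$mass * kern / sum(kern)
      }
    }
    v
  }, numeric(grid$J))
  component_set(spectra, grid)
}

#' Default seven-component placental spectra
#'
#' A synthetic reference set of seven tissue-environment spectra chosen to
#' reproduce the qualitative landmarks reported for placental combined
#' diffusion-relaxation decompositions: the first component has two peaks
#' with low T2* (< 0.06 s) and low ADC (< 0.001 mm^2/s), poorly oxygenated
#' low-diffusivity tissue; a mid component mixes moderate-T2* tissue with a
#' high-ADC (> 0.1 mm^2/s) vascular peak, as expected for septa and
#' uterine-wall vessels; the last component has all its peaks above 0.09 s
#' T2*, well-oxygenated blood arriving at lobule centres. These synthetic
#' spectra are a modelling default, not fitted clinical values.
#'
#' @param grid A `spectral_grid` (default [spectral_grid()]).
#' @param log_width Peak width in log10 units (default 0.06).
#' @return A `component_set` with K = 7.
#' @export
default_placenta_components <- function(grid = spectral_grid(),
                                        log_width = 0.06) {
  pk <- function(t2, adc, mass) {
    list(t2star = t2, adc = adc, log_width = log_width, mass = mass)
  }
  make_component_spectra(grid, list(
    # 1: poorly oxygenated, low diffusivity (two low-T2*, low-ADC peaks)
    list(pk(0.030, 6e-4, 0.55), pk(0.050, 4e-4, 0.45)),
    # 2: short-T2* tissue with modest diffusivity
    list(pk(0.040, 3e-3, 1)),
    # 3: septa / uterine-wall vessels: tissue peak + fast (ADC > 0.1) peak
    list(pk(0.045, 0.01, 0.5), pk(0.080, 0.15, 0.5)),
    # 4: draining maternal blood: intermediate T2*, moderate-fast ADC
    list(pk(0.065, 0.03, 1)),
    # 5: intermediate oxygenation parenchyma
    list(pk(0.075, 2e-3, 1)),
    # 6: oxygenated tissue, slow flow
    list(pk(0.095, 8e-3, 0.6), pk(0.110, 0.05, 0.4)),
    # 7: well oxygenated (all peaks T2* > 0.09 s), incl. free-water flow
    list(pk(0.120, 4e-3, 0.4), pk(0.140, 0.05, 0.3), pk(0.130, 0.45, 0.3))
  ))
}

#' Summarise a component spectrum
#'
#' Reports the local maxima of the gridded spectrum above a mass threshold
#' (peaks within one grid cell of a larger peak are merged into it), the
#' spectrum-weighted mean T2* and ADC, and the fraction of mass above the
#' free-water diffusivity line (0.3 mm^2/s), the conventional marker of
#' perfusing or fast-flowing blood.
#'
#' @param spectrum Unit-mass J-vector (a column of a `component_set`), or a
#'   `component_set` whose columns are each summarised.
#' @param grid The spectral grid.
#' @param peak_threshold Minimum peak mass as a fraction of total (default
#'   0.01).
#' @param free_water_adc Free-water diffusivity line (default 0.3 mm^2/s).
#' @return A tibble of peaks (`t2star`, `adc`, `mass`) with attributes, or
#'   for a set a tibble with one row per component: `component`,
#'   `mean_t2star`, `mean_adc`, `free_water_fraction`, `n_peaks`, `peaks`
#'   (list column).
#' @export
spectrum_summary <- function(spectrum, grid = NULL, peak_threshold = 0.01,
                             free_water_adc = 0.3) {
  if (inherits(spectrum, "component_set")) {
    cs <- spectrum
    return(purrr::map_dfr(seq_len(cs$K), function(k) {
      s <- spectrum_summary(cs$spectra[, k], cs$grid, peak_threshold,
                            free_water_adc)
      tibble::tibble(
        component = k,
        mean_t2star = attr(s, "mean_t2star"),
        mean_adc = attr(s, "mean_adc"),
        free_water_fraction = attr(s, "free_water_fraction"),
        n_peaks = nrow(s),
        peaks = list(s)
      )
    }))
  }
  if (is.null(grid)) stop("grid is required when passing a bare spectrum")
  n1 <- length(grid$t2star); n2 <- length(grid$adc)
  # cells tibble is row-major with ADC fastest (crossing order)
  m <- matrix(spectrum, nrow = n2, ncol = n1)  # [adc, t2star]
  total <- sum(spectrum)
  is_peak <- matrix(FALSE, n2, n1)
  for (i in seq_len(n2)) {
    for (j in seq_len(n1)) {
      v <- m[i, j]
      if (v < peak_threshold * total || v == 0) next
      nb <- m[max(1, i - 1):min(n2, i + 1), max(1, j - 1):min(n1, j + 1)]
      if (v >= max(nb)) is_peak[i, j] <- TRUE
    }
  }
  # merge plateau/adjacent peaks: keep only the largest within one grid cell
  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) > 1) {
    vals <- m[idx]
    ord <- order(vals, decreasing = TRUE)
    keep <- rep(TRUE, nrow(idx))
    for (a in seq_along(ord)) {
      if (!keep[ord[a]]) next
      for (b in ord[seq_along(ord) > a]) {
        if (keep[b] && all(abs(idx[ord[a], ] - idx[b, ]) <= 1)) {
          keep[b] <- FALSE
        }
      }
    }
    idx <- idx[keep, , drop = FALSE]
  }
  # mass assigned to each peak: share of cells by nearest peak (log space)
  peaks <- tibble::tibble(
    t2star = grid$t2star[idx[, 2]],
    adc = grid$adc[idx[, 1]],
    mass = NA_real_
  )
  if (nrow(peaks) > 0) {
    lt2 <- log10(grid$cells$t2star); ladc <- log10(grid$cells$adc)
    d <- vapply(seq_len(nrow(peaks)), function(p) {
      (lt2 - log10(peaks$t2star[p]))^2 + (ladc - log10(peaks$adc[p]))^2
    }, numeric(grid$J))
    nearest <- max.col(-d)
    peaks$mass <- vapply(seq_len(nrow(peaks)), function(p) {
      sum(spectrum[nearest == p]) / total
    }, numeric(1))
    peaks <- dplyr::arrange(peaks, dplyr::desc(.data$mass))
  }
  structure(
    peaks,
    mean_t2star = sum(spectrum * grid$cells$t2star) / total,
    mean_adc = sum(spectrum * grid$cells$adc) / total,
    free_water_fraction = sum(spectrum[grid$cells$adc > free_water_adc]) / total
  )
}

#' Match components between two sets
#'
#' Optimal one-to-one assignment of the components of `set_b` to those of
#' `set_a`, minimising the summed Euclidean distance between spectra
#' (Hungarian algorithm). Needed whenever two independent fits -- or a fit
#' and a ground truth -- are compared, since component numbering is a
#' fitted-model artifact.
#'
#' @param set_a,set_b `component_set`s on the same grid with equal K.
#' @return Integer permutation p of 1..K: component k of `set_a` corresponds
#'   to component p[k] of `set_b`.
#' @export
match_components <- function(set_a, set_b) {
  if (set_a$K != set_b$K) stop("component sets have different K")
  if (set_a$grid$J != set_b$grid$J) stop("component sets use different grids")
  K <- set_a$K
  cost <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      cost[i, j] <- sqrt(sum((set_a$spectra[, i] - set_b$spectra[, j])^2))
    }
  }
  solve_assignment(cost)
}

# Hungarian algorithm (shortest augmenting path, O(n^3)).
# Returns p with p[i] = column assigned to row i, minimising sum cost[i, p[i]].
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- Inf
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)  # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1  # column 0 (index 1) is the virtual start
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1) break
    }
  }
  ans <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) ans[p[j]] <- j - 1
  ans
}
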