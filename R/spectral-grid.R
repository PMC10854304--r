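#' Discretised two-dimensional T2*-ADC spectral grid
#'
#' Component spectra live on a log-spaced grid of (T2*, ADC) pairs. Defaults
#' (50 x 50 points, T2* 0.01-0.3 s, ADC 1e-4 to 1.0 mm^2/s) cover the
#' landmarks that matter for placental tissue: the 0.06 s and 0.09 s T2*
#' oxygenation thresholds and the 0.001, 0.1 and 0.3 mm^2/s diffusivity
#' marks, 0.3 being the free-water line above which signal is read as
#' perfusing blood. Log spacing reflects the multiplicative action of decay
#' constants on the signal.
#'
#' @param n_t2star,n_adc Number of grid points per axis.
#' @param t2star_range,adc_range Axis ranges (seconds; mm^2/s).
#' @return A `spectral_grid` object: vectors `t2star`, `adc`, the expanded
#'   `cells` tibble (row-major over ADC fastest) and `J = n_t2star * n_adc`.
#' @export
spectral_grid <- function(n_t2star = 50, n_adc = 50,
                          t2star_range = c(0.01, 0.3),
                          adc_range = c(1e-4, 1.0)) {
  stopifnot(n_t2star >= 2, n_adc >= 2,
            t2star_range[1] > 0, t2star_range[2] > t2star_range[1],
            adc_range[1] > 0, adc_range[2] > adc_range[1])
  t2 <- exp(seq(log(t2star_range[1]), log(t2star_range[2]),
                length.out = n_t2star))
  adc <- exp(seq(log(adc_range[1]), log(adc_range[2]), length.out = n_adc))
  cells <- tidyr::crossing(t2star = t2, adc = adc)
  structure(
    list(t2star = t2, adc = adc, cells = cells, J = nrow(cells)),
    class = "spectral_grid"
  )
}

#' Signal dictionary over a spectral grid
#'
#' Dictionary matrix A with one row per scheme measurement and one column per
#' grid cell: A[m, j] = exp(-(TE_m - TE_min)/T2*_j) * exp(-b_m * ADC_j), the
#' unit-amplitude signal of a pure (T2*_j, ADC_j) environment. All entries
#' lie in (0, 1]; the row for (TE_min, b = 0) is identically 1.
#'
#' @param scheme An acquisition scheme.
#' @param grid A `spectral_grid`.
#' @return An M x J numeric matrix.
#' @export
build_dictionary <- function(scheme, grid) {
  tmin <- te_min(scheme)
  dte <- scheme$te - tmin
  relax <- exp(-outer(dte, 1 / grid$cells$t2star))
  diff <- exp(-outer(scheme$b, grid$cells$adc))
  relax * diff
}

#' Per-component predicted signals
#'
#' Contracts the dictionary with each component spectrum: column k is the
#' unit-S0 signal of a voxel made purely of component k. Because spectra have
#' unit mass and every dictionary entry is in (0, 1], so is every predicted
#' signal, and the (TE_min, b = 0) row equals 1 for every component.
#'
#' @param components A `component_set`.
#' @param scheme An acquisition scheme.
#' @return An M x K matrix.
#' @export
component_signals <- function(components, scheme) {
  A <- build_dictionary(scheme, components$grid)
  A %*% components$spectra
}
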