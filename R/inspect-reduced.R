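#' Voxelwise component weights with fixed spectra (reduced mode)
#'
#' Given a fixed set of component spectra -- learned beforehand from a
#' control cohort, or known ground truth -- solves, in every masked voxel, a
#' non-negative least squares of the measured signal on the per-component
#' predicted signals. The proton-density scale S0 is the sum of the
#' unnormalised coefficients and the weights are the coefficients divided by
#' S0, so each voxel's weights lie on the K-simplex. Voxels whose
#' coefficients are all zero carry no component information; they are
#' flagged and excluded from region means.
#'
#' @param stack A `volume_stack` (or plain V x M signal matrix).
#' @param mask An `roi_mask`; ignored when `stack` is already a matrix.
#' @param components A `component_set`.
#' @param scheme The acquisition scheme.
#' @return A `weight_maps` object: `weights` (V x K, rows on the simplex),
#'   `s0` (length V), `flagged` (logical V), `coords` (voxel coordinates, or
#'   NULL for matrix input), `components`.
#' @export
fit_weights_reduced <- function(stack, mask = NULL, components, scheme) {
  if (is.matrix(stack)) {
    sig <- stack
    coords <- NULL
    index <- NULL
  } else {
    ms <- masked_signals(stack, mask)
    sig <- ms$signals
    coords <- tibble::as_tibble(ms$coords)
    index <- ms$index
  }
  B <- component_signals(components, scheme)
  if (nrow(B) != ncol(sig)) stop("signal length does not match scheme")
  if (qr(B)$rank < ncol(B)) {
    warning("component signals are collinear to machine precision; ",
            "weights are a pseudo-solution")
  }
  V <- nrow(sig)
  K <- ncol(B)
  coef <- matrix(0, V, K)
  for (v in seq_len(V)) coef[v, ] <- nnls_small(B, sig[v, ])
  s0 <- rowSums(coef)
  flagged <- s0 <= 0
  weights <- coef
  weights[!flagged, ] <- coef[!flagged, , drop = FALSE] / s0[!flagged]
  structure(
    list(weights = weights, s0 = s0, flagged = flagged, coords = coords,
         index = index, components = components),
    class = "weight_maps"
  )
}

#' Mean region-of-interest component weightings
#'
#' The voxel-mean of the weight rows over unflagged voxels: the overall
#' contribution of each component to the region's signal, on the K-simplex.
#' This is the per-scan quantity plotted against gestational age and carried
#' into the cohort statistics.
#'
#' @param wm A `weight_maps` object.
#' @return Named numeric K-vector summing to 1.
#' @export
mean_roi_weightings <- function(wm) {
  ok <- !wm$flagged
  if (!any(ok)) stop("all voxels are flagged; no weights to average")
  w <- colMeans(wm$weights[ok, , drop = FALSE])
  names(w) <- paste0("weight_", seq_along(w))
  w
}

#' Reconstruction sum of squared errors of a weight fit
#'
#' @param wm A `weight_maps` from [fit_weights_reduced()].
#' @param signals The V x M matrix the weights were fitted to.
#' @param scheme The acquisition scheme.
#' @return Total SSE over voxels.
#' @export
reconstruction_sse <- function(wm, signals, scheme) {
  B <- component_signals(wm$components, scheme)
  pred <- (wm$weights * wm$s0) %*% t(B)
  sum((signals - pred)^2)
}

#' Write weight maps as a 4D NIfTI volume
#'
#' The fourth dimension indexes components, mirroring per-component spatial
#' weighting maps; voxels outside the mask are zero.
#'
#' @param wm A `weight_maps` with voxel coordinates (fitted from a volume).
#' @param dims Spatial dimensions of the original volume.
#' @param path Output path.
#' @param voxel_size Voxel size in mm.
#' @export
write_weight_maps <- function(wm, dims, path, voxel_size = 3) {
  if (is.null(wm$index)) stop("weight maps were fitted from a matrix, not a volume")
  K <- ncol(wm$weights)
  arr <- array(0, c(dims, K))
  for (k in seq_len(K)) {
    slice <- array(0, dims)
    slice[wm$index] <- wm$weights[, k]
    arr[, , , k] <- slice
  }
  attr(arr, "pixdim") <- c(rep(voxel_size, 3), 1)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  invisible(path)
}

#' Serialise / read a component set as CSV
#'
#' Columns `t2star_s`, `adc`, then `component_1..K` spectral values; one row
#' per grid cell in grid order.
#'
#' @param components A `component_set`.
#' @param path CSV path.
#' @export
write_components <- function(components, path) {
  df <- dplyr::bind_cols(
    tibble::tibble(t2star_s = components$grid$cells$t2star,
                   adc = components$grid$cells$adc),
    tibble::as_tibble(components$spectra,
                      .name_repair = ~ paste0("component_", seq_len(components$K)))
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' @param grid The `spectral_grid` the file was written from.
#' @rdname write_components
#' @export
read_components <- function(path, grid) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  cols <- grep("^component_", names(df), value = TRUE)
  component_set(as.matrix(df[cols]), grid, reorder = FALSE)
}
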