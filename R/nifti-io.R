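#' Volume stacks and region-of-interest masks
#'
#' A `volume_stack` holds the 4D intensity data of one combined
#' diffusion-relaxation scan: an (x, y, z, measurement) array whose fourth
#' dimension is ordered exactly as the rows of its acquisition scheme, plus
#' the isotropic voxel size in mm. A `roi_mask` is a 3D logical array marking
#' the placenta and adjacent uterine-wall voxels that enter the analysis.
#'
#' @param intensities 4D non-negative numeric array.
#' @param voxel_size Isotropic voxel edge length in mm.
#' @param scheme Optional `dr_scheme`; when given, the fourth dimension must
#'   match its number of rows.
#' @return A `volume_stack` object.
#' @export
volume_stack <- function(intensities, voxel_size, scheme = NULL) {
  if (length(dim(intensities)) != 4) {
    stop("intensities must be a 4D array (x, y, z, measurement); got rank ",
         length(dim(intensities)))
  }
  if (any(!is.finite(intensities))) stop("intensities must be finite")
  if (any(intensities < 0)) stop("intensities must be >= 0")
  if (!is.null(scheme) && dim(intensities)[4] != nrow(scheme)) {
    stop("4th dimension (", dim(intensities)[4],
         ") does not match scheme rows (", nrow(scheme), ")")
  }
  structure(
    list(intensities = intensities, voxel_size = as.numeric(voxel_size),
         scheme = scheme),
    class = "volume_stack"
  )
}

#' @param mask 3D logical (or 0/1 numeric) array.
#' @rdname volume_stack
#' @export
roi_mask <- function(mask) {
  if (length(dim(mask)) != 3) {
    stop("mask must be a 3D array; got rank ", length(dim(mask)))
  }
  m <- array(as.logical(mask), dim = dim(mask))
  if (!any(m)) stop("mask is empty (no TRUE voxels)")
  structure(list(mask = m), class = "roi_mask")
}

#' Read and write NIfTI-1 volumes and masks
#'
#' Volumes are 4D NIfTI-1 files; masks are 3D and thresholded at 0.5 on read
#' so that the in-memory mask is strictly boolean. The voxel size is taken
#' from the NIfTI header (first pixdim; the package assumes isotropic
#' voxels). Data are written as float64, so a write/read round trip
#' reproduces intensities bit-exactly.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param scheme Optional scheme to validate the fourth dimension against.
#' @return `read_volume()` returns a `volume_stack`; `read_mask()` an
#'   `roi_mask`.
#' @export
read_volume <- function(path, scheme = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 4) {
    stop("expected a 4D volume, got rank ", length(dim(arr)), ": ", path)
  }
  if (any(!is.finite(arr))) stop("non-finite values in ", path)
  vs <- RNifti::pixdim(img)[1]
  volume_stack(arr, vs, scheme)
}

#' @param stack A `volume_stack`.
#' @rdname read_volume
#' @export
write_volume <- function(stack, path) {
  arr <- stack$intensities
  attr(arr, "pixdim") <- c(rep(stack$voxel_size, 3), 1)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 3) {
    stop("expected a 3D mask, got rank ", length(dim(arr)), ": ", path)
  }
  roi_mask(arr > 0.5)
}

#' @param mask An `roi_mask`.
#' @param voxel_size Voxel size in mm recorded in the header.
#' @rdname read_volume
#' @export
write_mask <- function(mask, path, voxel_size = 3) {
  arr <- array(as.numeric(mask$mask), dim = dim(mask$mask))
  attr(arr, "pixdim") <- rep(voxel_size, 3)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "uint8"), path)
  invisible(path)
}

#' Region-of-interest volume
#'
#' Total volume of the mask in mm^3: the number of TRUE voxels times the cube
#' of the voxel size. Additive over disjoint masks.
#'
#' @param mask An `roi_mask` (or 3D logical array).
#' @param voxel_size Isotropic voxel edge length in mm.
#' @return Volume in mm^3.
#' @examples
#' m <- array(FALSE, c(4, 4, 2)); m[1:5] <- TRUE
#' roi_volume(roi_mask(m), voxel_size = 3)
#' @export
roi_volume <- function(mask, voxel_size) {
  if (inherits(mask, "roi_mask")) mask <- mask$mask
  n <- sum(mask)
  if (n == 0) stop("mask is empty")
  n * voxel_size^3
}

# Extract masked voxel signals as an V x M matrix plus voxel coordinates.
masked_signals <- function(stack, mask) {
  if (inherits(mask, "roi_mask")) mask <- mask$mask
  dims <- dim(stack$intensities)
  if (!all(dim(mask) == dims[1:3])) {
    stop("mask dimensions do not match volume spatial dimensions")
  }
  idx <- which(mask)
  m <- dims[4]
  flat <- matrix(stack$intensities, nrow = prod(dims[1:3]), ncol = m)
  sig <- flat[idx, , drop = FALSE]
  coords <- arrayInd(idx, dims[1:3])
  colnames(coords) <- c("x", "y", "z")
  list(signals = sig, index = idx, coords = coords)
}
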