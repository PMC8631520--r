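#' Construct a volume-with-mask object
#'
#' Bundles a 3D scalar intensity volume with an aligned binary volume of
#' interest (VOI) mask delineating the whole lesion. This is the input
#' container for texture extraction: all statistics are computed over the
#' mask's foreground voxels only.
#'
#' @param voxels 3D numeric array of intensities (arbitrary units).
#' @param mask 3D array of the same dimensions; any voxel with value > 0 is
#'   foreground. Stored internally as logical.
#' @param spacing numeric length-3 vector of voxel spacing in mm
#'   (informational only; no feature uses physical distance).
#' @return An object of class `voi_volume` with elements `voxels`, `mask`
#'   (logical array) and `spacing`.
#' @examples
#' vox <- array(rnorm(64), dim = c(4, 4, 4))
#' msk <- array(FALSE, dim = c(4, 4, 4)); msk[2:3, 2:3, 2:3] <- TRUE
#' vm <- voi_volume(vox, msk)
#' @export
voi_volume <- function(voxels, mask, spacing = c(1, 1, 1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  if (!is.array(mask) || !identical(dim(mask), dim(voxels)))
    stop("dimensional error: `mask` dimensions (",
         paste(dim(mask), collapse = "x"),
         ") do not match `voxels` (", paste(dim(voxels), collapse = "x"), ")",
         call. = FALSE)
  mask <- array(as.vector(mask) > 0, dim = dim(mask))
  if (!any(mask))
    stop("empty VOI: mask has no foreground voxel", call. = FALSE)
  if (!all(is.finite(voxels[mask])))
    stop("data error: non-finite intensities inside the VOI", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive lengths", call. = FALSE)
  structure(list(voxels = voxels, mask = mask, spacing = as.numeric(spacing)),
            class = "voi_volume")
}

#' @export
print.voi_volume <- function(x, ...) {
  cat("<voi_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, ", sum(x$mask), " in VOI\n", sep = "")
  invisible(x)
}

#' Number of foreground (VOI) voxels
#' @param vm a `voi_volume`
#' @return integer count of mask-foreground voxels
#' @export
n_foreground <- function(vm) {
  stopifnot(inherits(vm, "voi_volume"))
  sum(vm$mask)
}

#' Load a volume and VOI mask from NIfTI files
#'
#' Reads a scalar volume and an aligned binary lesion mask. The mask is
#' binarized at > 0. No reorientation is performed: the arrays are used in
#' the file's native layout, so the two files must share a grid.
#'
#' @param volume_path path to the intensity NIfTI (.nii or .nii.gz).
#' @param mask_path path to the mask NIfTI on the same grid.
#' @return A [voi_volume()].
#' @export
load_volume_mask <- function(volume_path, mask_path) {
  if (!file.exists(volume_path)) stop("volume file not found: ", volume_path, call. = FALSE)
  if (!file.exists(mask_path)) stop("mask file not found: ", mask_path, call. = FALSE)
  vol <- RNifti::readNifti(volume_path)
  msk <- RNifti::readNifti(mask_path)
  spacing <- tryCatch(RNifti::pixdim(vol)[seq_len(3)], error = function(e) c(1, 1, 1))
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    spacing <- c(1, 1, 1)
  voi_volume(array(as.numeric(vol), dim = dim(vol)),
             array(as.numeric(msk), dim = dim(msk)),
             spacing = spacing)
}

#' Write a volume/mask pair as NIfTI
#'
#' @param vm a `voi_volume`
#' @param volume_path,mask_path output paths (.nii or .nii.gz)
#' @return invisibly, the two paths
#' @export
write_volume_mask <- function(vm, volume_path, mask_path) {
  stopifnot(inherits(vm, "voi_volume"))
  RNifti::writeNifti(RNifti::asNifti(vm$voxels, pixdim = vm$spacing), volume_path)
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(vm$mask), dim = dim(vm$mask)),
                                     pixdim = vm$spacing), mask_path)
  invisible(c(volume_path, mask_path))
}

#' Gray-level normalization and quantization of a VOI
#'
#' Implements the "limitation of dynamics" normalization: intensities inside
#' the VOI are clipped to the window \eqn{[\mu - 3\sigma, \mu + 3\sigma]},
#' where \eqn{\mu} and \eqn{\sigma} are the mean and *population* standard
#' deviation (denominator Np) over the VOI voxels, then mapped linearly onto
#' `n_levels` discrete gray levels:
#' \deqn{level = 1 + \lfloor (x - (\mu-3\sigma)) / (6\sigma) \cdot N_g \rfloor}
#' with the exact upper endpoint mapped to \eqn{N_g}. The resulting levels
#' are invariant under any positive affine rescaling of the intensities,
#' which is the point: it removes scanner brightness/contrast variation.
#'
#' Degenerate case: a zero-variance VOI (\eqn{\sigma = 0}) maps every voxel
#' to level 1 with a warning, rather than erroring, so constant phantoms
#' remain usable.
#'
#' @param vm a [voi_volume()].
#' @param n_levels integer number of gray levels \eqn{N_g \ge 2}; default 64.
#' @return An object of class `quantized_voi`: list with `levels` (integer 3D
#'   array, `NA` outside the VOI), `n_levels`, `n_voxels` (Np), `shape`, and
#'   `params` (list `mu`, `sigma`, `window`, `n_levels`).
#' @seealso [extract_all()] which calls this internally.
#' @export
normalize_voi <- function(vm, n_levels = 64L) {
  stopifnot(inherits(vm, "voi_volume"))
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 2L)
    stop("`n_levels` must be an integer >= 2", call. = FALSE)
  x <- vm$voxels[vm$mask]
  np <- length(x)
  mu <- mean(x)
  sigma <- sqrt(sum((x - mu)^2) / np)   # population convention
  lo <- mu - 3 * sigma
  hi <- mu + 3 * sigma
  lev <- array(NA_integer_, dim = dim(vm$voxels))
  if (sigma == 0) {
    warning("zero-variance VOI: all voxels mapped to level 1", call. = FALSE)
    lev[vm$mask] <- 1L
  } else {
    xc <- pmin(pmax(x, lo), hi)
    l <- 1L + as.integer(floor((xc - lo) / (6 * sigma) * n_levels))
    l[l > n_levels] <- n_levels   # exact upper endpoint
    lev[vm$mask] <- l
  }
  structure(list(levels = lev,
                 n_levels = n_levels,
                 n_voxels = np,
                 shape = dim(vm$voxels),
                 params = list(mu = mu, sigma = sigma,
                               window = c(lo, hi), n_levels = n_levels)),
            class = "quantized_voi")
}

#' @export
print.quantized_voi <- function(x, ...) {
  cat("<quantized_voi> Np = ", x$n_voxels, ", Ng = ", x$n_levels,
      ", window = [", format(x$params$window[1]), ", ",
      format(x$params$window[2]), "]\n", sep = "")
  invisible(x)
}
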