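#' Write a volumetric SWV map as NIfTI-1
#'
#' The value volume goes to `path` (undefined voxels as NaN); the companion
#' per-voxel sample counts go to a sibling file with suffix `_counts`. The
#' NIfTI sform/qform encode the grid: isotropic spacing on the diagonal and
#' the world position of the first voxel center in the translation column.
#'
#' @param volume An [swv_volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return Invisibly, `c(path, counts_path)`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "swv_volume"))
  paths <- c(path, counts_path(path))
  write_nifti_grid(volume$values, volume$grid, paths[1])
  write_nifti_grid(volume$counts * 1, volume$grid, paths[2])
  invisible(paths)
}

#' Read a volumetric SWV map from NIfTI-1
#'
#' Requires isotropic voxel spacing and a matching `_counts` companion file;
#' a missing companion yields a volume with counts 1 where defined.
#'
#' @param path Path written by [write_volume()].
#' @return An [swv_volume()].
#' @export
read_volume <- function(path) {
  vv <- read_nifti_grid(path)
  cp <- counts_path(path)
  if (file.exists(cp)) {
    cc <- read_nifti_grid(cp)
    if (!all(dim(cc$values) == dim(vv$values))) {
      stop("values and counts volumes have mismatched dimensions", call. = FALSE)
    }
    counts <- cc$values
    counts[is.na(counts)] <- 0
  } else {
    counts <- (!is.na(vv$values)) * 1
  }
  swv_volume(vv$grid, vv$values, counts)
}

#' Write a segmentation mask as NIfTI-1
#' @param mask A [segmentation_mask()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "segmentation_mask"))
  write_nifti_grid(mask$voxels * 1, mask$grid, path)
  invisible(path)
}

#' Read a segmentation mask from NIfTI-1
#' @param path Path to a binary NIfTI volume.
#' @return A [segmentation_mask()].
#' @export
read_mask <- function(path) {
  x <- read_nifti_grid(path)
  v <- x$values
  v[is.na(v)] <- 0
  segmentation_mask(x$grid, v > 0.5)
}

counts_path <- function(path) {
  sub("(\\.nii(\\.gz)?)$", "_counts\\1", path)
}

write_nifti_grid <- function(arr, grid, path) {
  img <- RNifti::asNifti(arr)
  s <- grid$spacing
  xf <- structure(rbind(cbind(diag(3) * s, grid$origin), c(0, 0, 0, 1)),
                  code = 2L)
  RNifti::qform(img) <- xf
  RNifti::sform(img) <- xf
  RNifti::pixdim(img) <- c(s, s, s)
  RNifti::writeNifti(img, path)
}

read_nifti_grid <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  sp <- sqrt(colSums(xf[1:3, 1:3]^2))
  if (max(sp) - min(sp) > 1e-6 * max(sp)) {
    stop(sprintf("anisotropic voxel spacing in %s (%s); isotropic required",
                 path, paste(signif(sp, 6), collapse = " x ")), call. = FALSE)
  }
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D volume in ", path, call. = FALSE)
  arr <- array(as.vector(arr), dim(arr))  # strip niftiImage attributes
  list(values = arr, grid = voxel_grid(xf[1:3, 4], mean(sp), dim(arr)))
}
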