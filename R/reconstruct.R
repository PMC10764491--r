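#' Fit a voxel grid around a frame set
#'
#' Returns the axis-aligned bounding box of all valid pixel world positions,
#' padded by one voxel on every side.
#'
#' @param frames List of [swv_frame()] objects.
#' @param spacing_mm Isotropic voxel spacing (mm); default 1, on the order of
#'   the probe's elevation resolution.
#' @return A [voxel_grid()].
#' @export
auto_grid <- function(frames, spacing_mm = 1) {
  check_frameset(frames)
  rng <- matrix(c(Inf, Inf, Inf, -Inf, -Inf, -Inf), 3L, 2L)
  any_valid <- FALSE
  for (f in frames) {
    if (!any(f$valid)) next
    any_valid <- TRUE
    w <- frame_pixel_world(f)$points
    rng[, 1] <- pmin(rng[, 1], apply(w, 2L, min))
    rng[, 2] <- pmax(rng[, 2], apply(w, 2L, max))
  }
  if (!any_valid) stop("no valid pixels in frame set", call. = FALSE)
  dims <- floor((rng[, 2] - rng[, 1]) / spacing_mm + 0.5) + 1 + 2
  voxel_grid(rng[, 1] - spacing_mm, spacing_mm, dims)
}

#' Reconstruct a volumetric SWV map from tracked frames
#'
#' Projects every valid pixel into the world through its frame's pose and
#' accumulates it into the containing voxel (nearest-voxel assignment,
#' half-open voxel cubes). A voxel's value is the arithmetic mean of its
#' samples (compounding); untouched voxels stay undefined (`NA`). Samples
#' are put into a canonical order before summation, so any permutation of
#' the input frames yields bit-identical output.
#'
#' With `fill_holes = TRUE`, undefined voxels whose 6-neighbourhood is fully
#' defined (single-voxel holes) are filled with the neighbour mean and
#' flagged in the volume's `filled` array; no larger gap is ever inpainted.
#'
#' @param frames List of [swv_frame()] objects.
#' @param grid A [voxel_grid()], e.g. from [auto_grid()].
#' @param fill_holes Interpolate single-voxel holes (default `FALSE`).
#' @return An [swv_volume()].
#' @export
reconstruct <- function(frames, grid, fill_holes = FALSE) {
  check_frameset(frames)
  stopifnot(inherits(grid, "voxel_grid"))
  idx_all <- vector("list", length(frames))
  val_all <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    fw <- frame_pixel_world(frames[[i]])
    if (length(fw$values) == 0L) next
    vi <- world_to_index(grid, fw$points)
    keep <- !is.na(vi[, 1])
    if (!any(keep)) next
    lin <- 1 + vi[keep, 1] + grid$dims[1] * (vi[keep, 2] +
                                               grid$dims[2] * vi[keep, 3])
    idx_all[[i]] <- lin
    val_all[[i]] <- fw$values[keep]
  }
  lin <- unlist(idx_all)
  vals <- unlist(val_all)
  if (length(lin) == 0L) stop("grid does not cover scan", call. = FALSE)
  # Canonical order -> frame-permutation-invariant floating-point sums.
  o <- order(lin, vals)
  lin <- lin[o]; vals <- vals[o]
  nvox <- prod(grid$dims)
  counts <- tabulate(lin, nbins = nvox)
  sums <- numeric(nvox)
  rs <- rowsum(vals, lin, reorder = TRUE)
  sums[as.integer(rownames(rs))] <- rs[, 1]
  values <- rep(NA_real_, nvox)
  def <- counts > 0L
  # Compounded voxel values are snapped back to the frames' single precision
  # so that downstream aggregation sums stay exactly associative.
  values[def] <- snap_single(sums[def] / counts[def])
  dim(values) <- grid$dims
  counts <- array(as.integer(counts), grid$dims)
  filled <- array(FALSE, grid$dims)
  if (fill_holes) {
    filled <- single_voxel_holes(values)
    if (any(filled)) values[filled] <- neighbor_mean(values, filled)
  }
  swv_volume(grid, values, counts, filled)
}

single_voxel_holes <- function(values) {
  d <- dim(values)
  def <- !is.na(values)
  hole <- !def
  for (ax in 1:3) {
    for (dir in c(-1L, 1L)) {
      hole <- hole & shift_array(def, ax, dir, fill = FALSE)
    }
  }
  hole
}

neighbor_mean <- function(values, which_voxels) {
  s <- array(0, dim(values)); n <- array(0, dim(values))
  for (ax in 1:3) {
    for (dir in c(-1L, 1L)) {
      v <- shift_array(values, ax, dir, fill = NA_real_)
      ok <- !is.na(v)
      s[ok] <- s[ok] + v[ok]
      n[ok] <- n[ok] + 1
    }
  }
  (s / n)[which_voxels]
}

shift_array <- function(a, axis, dir, fill) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- lapply(d, seq_len)
  if (dir > 0) {
    src[[axis]] <- seq_len(d[axis] - 1L)
    dst[[axis]] <- seq_len(d[axis] - 1L) + 1L
  } else {
    src[[axis]] <- seq_len(d[axis] - 1L) + 1L
    dst[[axis]] <- seq_len(d[axis] - 1L)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Extract the masked, defined voxels as a point set
#'
#' Emits exactly the voxels that are inside the segmentation mask AND carry a
#' reconstructed value, as world-coordinate points. Coverage is the fraction
#' of mask voxels that are defined.
#'
#' @param volume An [swv_volume()].
#' @param mask A [segmentation_mask()] on the same grid.
#' @return A list of class `masked_point_set`: `points` (N x 3 world mm,
#'   voxel centers), `swv` (numeric N, m/s), `coverage` (scalar in 0-1),
#'   `grid`.
#' @export
apply_mask <- function(volume, mask) {
  stopifnot(inherits(volume, "swv_volume"), inherits(mask, "segmentation_mask"))
  if (!grids_equal(volume$grid, mask$grid)) {
    stop("volume and mask grids do not match", call. = FALSE)
  }
  sel <- mask$voxels & !is.na(volume$values)
  coverage <- sum(sel) / sum(mask$voxels)
  if (coverage == 0) {
    warning("mask is disjoint from the reconstructed region (coverage 0)")
  }
  which_idx <- which(sel, arr.ind = TRUE) - 1L
  structure(list(points = voxel_centers(volume$grid, which_idx),
                 swv = volume$values[sel],
                 coverage = coverage,
                 grid = volume$grid),
            class = "masked_point_set")
}

#' @export
print.masked_point_set <- function(x, ...) {
  cat(sprintf("<masked_point_set> %d points, coverage %.1f%%, mean %.3f m/s\n",
              length(x$swv), 100 * x$coverage, mean(x$swv)))
  invisible(x)
}
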