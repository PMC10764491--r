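#' Isotropic voxel grid specification
#'
#' Defines a world-aligned voxel lattice. `origin` is the world position (mm)
#' of the *center* of voxel `(0, 0, 0)`; indices are 0-based; a voxel with
#' center `c` owns the half-open cube `[c - s/2, c + s/2)` along each axis.
#'
#' @param origin World mm of the first voxel center (length 3).
#' @param spacing Isotropic voxel edge length (mm, > 0).
#' @param dims Integer grid dimensions `(nx, ny, nz)`, each >= 1.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(origin, spacing, dims) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  dims <- as.integer(dims)
  if (length(origin) != 3L || anyNA(origin)) stop("origin must be length 3", call. = FALSE)
  if (length(spacing) != 1L || !is.finite(spacing) || spacing <= 0) {
    stop("spacing must be a single positive number (mm)", call. = FALSE)
  }
  if (length(dims) != 3L || anyNA(dims) || any(dims < 1L)) {
    stop("dims must be three integers >= 1", call. = FALSE)
  }
  structure(list(origin = origin, spacing = spacing, dims = dims),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d @ %g mm, origin [%s] mm\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              paste(signif(x$origin, 6), collapse = ", ")))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-9) {
  all(a$dims == b$dims) && abs(a$spacing - b$spacing) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Map world coordinates to 0-based voxel indices
#'
#' Points on a voxel boundary belong to the higher-index voxel (half-open
#' convention). Points outside the grid get index `NA`.
#'
#' @param grid A `voxel_grid`.
#' @param points N x 3 world coordinates (mm).
#' @return N x 3 integer matrix of 0-based indices (NA outside the grid).
#' @export
world_to_index <- function(grid, points) {
  points <- as_points3(points)
  idx <- floor(sweep(points, 2L, grid$origin, "-") / grid$spacing + 0.5)
  out <- idx < 0 | idx >= matrix(grid$dims, nrow(idx), 3L, byrow = TRUE)
  idx[rowSums(out) > 0, ] <- NA_real_
  storage.mode(idx) <- "integer"
  idx
}

#' World coordinates of voxel centers
#'
#' @param grid A `voxel_grid`.
#' @param index N x 3 matrix of 0-based voxel indices; if `NULL`, all voxels
#'   in column-major order.
#' @return N x 3 matrix of world mm.
#' @export
voxel_centers <- function(grid, index = NULL) {
  if (is.null(index)) {
    index <- as.matrix(expand.grid(x = 0:(grid$dims[1] - 1),
                                   y = 0:(grid$dims[2] - 1),
                                   z = 0:(grid$dims[3] - 1)))
  }
  sweep(as_points3(index) * grid$spacing, 2L, grid$origin, "+")
}

#' Gridded volumetric SWV map
#'
#' A 3D scalar field of shear wave velocity (m/s) on a [voxel_grid()], with a
#' per-voxel sample count. Voxels never touched by a measurement are `NA`
#' (the missing-value sentinel); `counts == 0` exactly where values are `NA`.
#' Voxels filled by optional hole interpolation are flagged in `filled` and
#' carry count 0.
#'
#' @param grid A `voxel_grid`.
#' @param values 3D numeric array (m/s) matching `grid$dims`, NA = undefined.
#' @param counts 3D integer array of per-voxel sample counts.
#' @param filled Optional 3D logical array flagging interpolated voxels.
#' @return An object of class `swv_volume`.
#' @export
swv_volume <- function(grid, values, counts, filled = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  values <- as.array(values); counts <- as.array(counts)
  if (!identical(dim(values), as.integer(grid$dims)) ||
      !identical(dim(counts), as.integer(grid$dims))) {
    stop("values/counts dimensions must match grid dims", call. = FALSE)
  }
  storage.mode(values) <- "double"
  storage.mode(counts) <- "integer"
  if (is.null(filled)) filled <- array(FALSE, dim(values))
  defined <- counts > 0L | filled
  if (any(is.na(values[defined])) || any(!is.na(values[!defined]))) {
    stop("counts == 0 must coincide exactly with NA values", call. = FALSE)
  }
  if (any(values[defined] <= 0, na.rm = TRUE)) {
    stop("defined SWV values must be strictly positive (m/s)", call. = FALSE)
  }
  structure(list(grid = grid, values = values, counts = counts,
                 filled = filled),
            class = "swv_volume")
}

#' @export
print.swv_volume <- function(x, ...) {
  nd <- sum(x$counts > 0L)
  cat(sprintf("<swv_volume> %s voxels, %d defined (%.1f%%), mean %.3f m/s\n",
              paste(x$grid$dims, collapse = " x "), nd,
              100 * nd / prod(x$grid$dims),
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Binary segmentation mask on a voxel grid
#'
#' @param grid A `voxel_grid` (must match the paired volume's grid).
#' @param voxels 3D logical array; must select at least one voxel.
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(grid, voxels) {
  stopifnot(inherits(grid, "voxel_grid"))
  voxels <- as.array(voxels)
  storage.mode(voxels) <- "logical"
  if (!identical(dim(voxels), as.integer(grid$dims))) {
    stop("mask dimensions must match grid dims", call. = FALSE)
  }
  if (!any(voxels)) stop("segmentation mask is empty", call. = FALSE)
  structure(list(grid = grid, voxels = voxels), class = "segmentation_mask")
}
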