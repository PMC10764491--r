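#' Generative parameters for a synthetic muscle phantom
#'
#' The phantom is an elongated muscle-like solid: a superellipse cross-section
#' (exponent `superellipse_n`) extruded along z over `length_mm`, with a
#' linear taper of the cross-section over the last `taper_frac` of each end
#' down to `taper_min_scale` of the full size. Its ground-truth shear wave
#' velocity field is
#'
#' `swv(p) = base + radial_gain * r_rel + angular_gain * cos(phi)
#'          + longitudinal_gain * z_rel + smooth(p)`
#'
#' where `r_rel` is the relative superellipse radius (0 on the central axis,
#' 1 on the surface), `phi = atan2(y, x)`, `z_rel = z / (length/2)` in
#' `[-1, 1]`, and `smooth` is a seeded band-limited random field: a low-order
#' 3D cosine series with fixed per-mode amplitude and random integer mode
#' vectors and phases, scaled so its pointwise SD is `smooth_sd`.
#'
#' @param base_swv Baseline SWV (m/s), must be > 0. Default 1.6, a typical
#'   resting skeletal-muscle value.
#' @param radial_gain Coefficient of `r_rel` (m/s over the full radius).
#' @param angular_gain Coefficient of `cos(phi)` (m/s).
#' @param longitudinal_gain Coefficient of `z_rel` (m/s over the half-length).
#' @param smooth_sd Pointwise SD of the smooth random component (m/s).
#' @param length_mm Phantom length (mm).
#' @param radius_x_mm,radius_y_mm Cross-section semi-axes (mm).
#' @param superellipse_n Superellipse exponent (>= 2); 2 is an ellipse,
#'   larger values are boxier.
#' @param taper_frac Fraction of each end over which the section tapers.
#' @param taper_min_scale Cross-section scale at the very ends (0-1].
#' @param smooth_order Highest integer mode per axis of the cosine series.
#' @param smooth_modes Number of random cosine modes.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(base_swv = 1.6, radial_gain = 0.4,
                           angular_gain = 0, longitudinal_gain = 0.1,
                           smooth_sd = 0, length_mm = 200,
                           radius_x_mm = 25, radius_y_mm = 15,
                           superellipse_n = 2.5, taper_frac = 0.15,
                           taper_min_scale = 0.4, smooth_order = 3,
                           smooth_modes = 12) {
  p <- list(base_swv = base_swv, radial_gain = radial_gain,
            angular_gain = angular_gain,
            longitudinal_gain = longitudinal_gain, smooth_sd = smooth_sd,
            length_mm = length_mm, radius_x_mm = radius_x_mm,
            radius_y_mm = radius_y_mm, superellipse_n = superellipse_n,
            taper_frac = taper_frac, taper_min_scale = taper_min_scale,
            smooth_order = as.integer(smooth_order),
            smooth_modes = as.integer(smooth_modes))
  if (p$base_swv <= 0) stop("base_swv must be positive (m/s)", call. = FALSE)
  if (p$length_mm <= 0 || p$radius_x_mm <= 0 || p$radius_y_mm <= 0) {
    stop("geometric extents must be positive", call. = FALSE)
  }
  if (p$superellipse_n < 2) stop("superellipse_n must be >= 2", call. = FALSE)
  if (p$taper_frac < 0 || p$taper_frac > 0.5) {
    stop("taper_frac must be in [0, 0.5]", call. = FALSE)
  }
  if (p$taper_min_scale <= 0 || p$taper_min_scale > 1) {
    stop("taper_min_scale must be in (0, 1]", call. = FALSE)
  }
  if (p$smooth_sd < 0) stop("smooth_sd must be >= 0", call. = FALSE)
  class(p) <- "phantom_params"
  p
}

#' Construct a synthetic muscle phantom
#'
#' Builds the deterministic mask and ground-truth field closures from
#' [phantom_params()]. All randomness (the smooth-field mode vectors and
#' phases) is drawn once here from `seed`; evaluating `mask_fn`/`field_fn`
#' afterwards involves no RNG, so the same seed always yields the identical
#' phantom.
#'
#' @param params A [phantom_params()] list.
#' @param seed Integer seed for the smooth random field component.
#' @return An object of class `phantom` with elements `mask_fn(points)`,
#'   `field_fn(points)`, `r_rel_fn(points)`, `params`, `seed`.
#' @examples
#' ph <- make_phantom(phantom_params(smooth_sd = 0.05), seed = 7)
#' ph$field_fn(c(0, 0, 0))
#' @export
make_phantom <- function(params = phantom_params(), seed = 1) {
  stopifnot(inherits(params, "phantom_params"))
  # Seeded cosine series for the smooth component.
  K <- params$smooth_modes
  smooth <- NULL
  if (params$smooth_sd > 0 && K > 0) {
    smooth <- with_seed(split_seed(seed, 1L), {
      modes <- matrix(sample(0:params$smooth_order, 3L * K, replace = TRUE),
                      K, 3L)
      zero <- rowSums(modes) == 0L
      modes[zero, 1L] <- 1L
      ext <- c(2 * params$radius_x_mm, 2 * params$radius_y_mm,
               params$length_mm)
      omega <- 2 * pi * sweep(modes, 2L, ext, "/")  # rad/mm
      list(omega = omega,
           amp = rep(params$smooth_sd * sqrt(2 / K), K),
           phase = stats::runif(K, 0, 2 * pi))
    })
  }
  # Worst-case field minimum must stay physical (> 0).
  smooth_max <- if (is.null(smooth)) 0 else sum(smooth$amp)
  fmin <- params$base_swv + min(0, params$radial_gain) -
    abs(params$angular_gain) - abs(params$longitudinal_gain) - smooth_max
  if (fmin <= 0) {
    stop(sprintf(paste0("field can reach %.3f m/s <= 0 inside the mask; ",
                        "SWV must be strictly positive"), fmin), call. = FALSE)
  }

  taper_scale <- function(z) {
    zq <- pmin(abs(z) / (params$length_mm / 2), 1)
    s <- rep(1, length(zq))
    if (params$taper_frac > 0) {
      edge <- 1 - params$taper_frac
      tp <- zq > edge
      s[tp] <- 1 - (1 - params$taper_min_scale) * (zq[tp] - edge) /
        params$taper_frac
    }
    s
  }
  r_rel_fn <- function(points) {
    pts <- as_points3(points)
    s <- taper_scale(pts[, 3])
    X <- abs(pts[, 1] / (params$radius_x_mm * s))
    Y <- abs(pts[, 2] / (params$radius_y_mm * s))
    (X^params$superellipse_n + Y^params$superellipse_n)^(1 / params$superellipse_n)
  }
  mask_fn <- function(points) {
    pts <- as_points3(points)
    abs(pts[, 3]) <= params$length_mm / 2 & r_rel_fn(pts) <= 1
  }
  field_fn <- function(points) {
    pts <- as_points3(points)
    f <- params$base_swv + params$radial_gain * r_rel_fn(pts)
    if (params$angular_gain != 0) {
      f <- f + params$angular_gain * cos(atan2(pts[, 2], pts[, 1]))
    }
    if (params$longitudinal_gain != 0) {
      f <- f + params$longitudinal_gain * pts[, 3] / (params$length_mm / 2)
    }
    if (!is.null(smooth)) {
      f <- f + as.vector(cos(pts %*% t(smooth$omega) +
                               matrix(smooth$phase, nrow(pts), length(smooth$phase),
                                      byrow = TRUE)) %*% smooth$amp)
    }
    f
  }
  structure(list(mask_fn = mask_fn, field_fn = field_fn, r_rel_fn = r_rel_fn,
                 params = params, seed = as.integer(seed), smooth = smooth),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("<phantom> %g mm x (%g x %g) mm, base %.2f m/s, ",
                     "radial %.2f, angular %.2f, longitudinal %.2f, ",
                     "smooth_sd %.2f, seed %d\n"),
              p$length_mm, p$radius_x_mm, p$radius_y_mm, p$base_swv,
              p$radial_gain, p$angular_gain, p$longitudinal_gain,
              p$smooth_sd, x$seed))
  invisible(x)
}

#' Lipschitz bound of a phantom's field
#'
#' Analytic upper bound on the gradient norm of the ground-truth field inside
#' the mask, used to bound reconstruction interpolation error (max voxel
#' error <= bound x voxel diagonal). Valid for `superellipse_n >= 2`. An
#' angular gradient has unbounded slope at the phantom axis, so for
#' `angular_gain != 0` the bound is `Inf`.
#'
#' @param phantom A [make_phantom()] object.
#' @return Lipschitz constant in (m/s)/mm.
#' @export
phantom_lipschitz <- function(phantom) {
  p <- phantom$params
  if (p$angular_gain != 0) {
    warning("angular gradient has unbounded slope at the axis; bound is Inf")
    return(Inf)
  }
  smin <- if (p$taper_frac > 0) p$taper_min_scale else 1
  grad_r_plane <- sqrt(1 / p$radius_x_mm^2 + 1 / p$radius_y_mm^2) / smin
  grad_r_z <- if (p$taper_frac > 0) {
    (1 - p$taper_min_scale) / (p$taper_frac * p$length_mm / 2) / smin
  } else 0
  l <- abs(p$radial_gain) * (grad_r_plane + grad_r_z) +
    abs(p$longitudinal_gain) * 2 / p$length_mm
  if (!is.null(phantom$smooth)) {
    l <- l + sum(phantom$smooth$amp * sqrt(rowSums(phantom$smooth$omega^2)))
  }
  l
}

#' Rasterize a phantom mask onto a voxel grid
#'
#' @param phantom A [make_phantom()] object.
#' @param grid A [voxel_grid()].
#' @return A [segmentation_mask()].
#' @export
phantom_mask <- function(phantom, grid) {
  inside <- phantom$mask_fn(voxel_centers(grid))
  segmentation_mask(grid, array(inside, grid$dims))
}
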