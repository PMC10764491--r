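# Shared fixtures: small phantoms, clean protocols and random tables.

# Taper-free phantom with a purely radial + longitudinal gradient, for which
# the analytic Lipschitz bound is tight and finite.
smooth_phantom <- function(length_mm = 80, radius_x_mm = 18, radius_y_mm = 12,
                           base = 1.5, radial = 0.4, longitudinal = 0.1,
                           seed = 1) {
  make_phantom(phantom_params(base_swv = base, radial_gain = radial,
                              angular_gain = 0, longitudinal_gain = longitudinal,
                              smooth_sd = 0, length_mm = length_mm,
                              radius_x_mm = radius_x_mm,
                              radius_y_mm = radius_y_mm, taper_frac = 0),
               seed = seed)
}

# Noise- and jitter-free protocol with dense lateral coverage.
clean_protocol <- function(n_swipes = 10, lateral = 4, spacing = 4,
                           width = 40, depth = 30, px = c(1, 1)) {
  scan_protocol(n_swipes = n_swipes, frame_spacing_mm = spacing,
                swipe_lateral_offset_mm = lateral,
                pose_jitter_trans_sd_mm = 0, pose_jitter_rot_sd_deg = 0,
                noise_sd_mps = 0, frame_width_mm = width,
                frame_depth_mm = depth, pixel_spacing_mm = px)
}

# Voxel-center point cloud of a phantom with ground-truth field values
# (bypasses the scan simulator for parameterization tests).
phantom_cloud <- function(phantom, spacing = 2) {
  p <- phantom$params
  g <- voxel_grid(c(-p$radius_x_mm, -p$radius_y_mm, -p$length_mm / 2),
                  spacing,
                  c(ceiling(2 * p$radius_x_mm / spacing) + 1,
                    ceiling(2 * p$radius_y_mm / spacing) + 1,
                    ceiling(p$length_mm / spacing) + 1))
  pts <- voxel_centers(g)
  keep <- phantom$mask_fn(pts)
  list(points = pts[keep, , drop = FALSE],
       swv = phantom$field_fn(pts[keep, , drop = FALSE]))
}

random_table <- function(n, k, sd_row = 1, sd_err = 0.5) {
  matrix(rnorm(n, 0, sd_row), n, k) + matrix(rnorm(n * k, 0, sd_err), n, k)
}

# Independent ICC(2,1) oracle built on stats::aov mean squares.
icc_oracle <- function(X) {
  n <- nrow(X); k <- ncol(X)
  df <- data.frame(y = as.vector(X),
                   row = factor(rep(seq_len(n), k)),
                   col = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ row + col, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

random_rotation <- function() {
  q <- rnorm(4)
  quaternion_to_matrix(q / sqrt(sum(q^2)))
}

expect_map_equal <- function(a, b, tol = 0) {
  expect_identical(a$n, b$n)
  if (tol == 0) {
    expect_identical(a$sum, b$sum)
    expect_identical(a$mean, b$mean)
  } else {
    expect_equal(a$mean, b$mean, tolerance = tol)
  }
}
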