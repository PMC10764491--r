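test_that("principal axis of a box point cloud is the long axis", {
  set.seed(1)
  pts <- cbind(runif(4000, -100, 100), runif(4000, -15, 15),
               runif(4000, -10, 10))
  pa <- principal_axis(pts, orientation_hint = c(1, 0, 0))
  expect_lt(max(abs(abs(pa$axis) - c(1, 0, 0))), 1e-2)
  expect_gt(sum(pa$axis * c(1, 0, 0)), 0)
  # flipped hint negates the axis
  pa2 <- principal_axis(pts, orientation_hint = c(-1, 0, 0))
  expect_equal(pa2$axis, -pa$axis)
})

test_that("principal axis is equivariant under an analytically known rotation", {
  set.seed(2)
  pts <- cbind(runif(3000, -100, 100), runif(3000, -15, 15),
               runif(3000, -10, 10))
  th <- 30 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  pa0 <- principal_axis(pts, orientation_hint = c(1, 0, 0))
  # oracle: eigenvectors of the rotated covariance are the rotated eigenvectors
  pa1 <- principal_axis(pts %*% t(Rz), orientation_hint = Rz %*% c(1, 0, 0))
  expect_lt(max(abs(pa1$axis - as.vector(Rz %*% pa0$axis))), 1e-6)
})

test_that("isotropic point clouds have no dominant axis", {
  set.seed(3)
  pts <- matrix(rnorm(3000), ncol = 3)  # spherical
  expect_error(principal_axis(pts, tol = 0.5), "no dominant axis")
  expect_error(principal_axis(pts[1:2, ]), "at least 3")
})

test_that("slice partition is uniform, half-open and exhaustive", {
  z <- seq(0, 100, by = 0.5)
  s <- slice_partition(z, 8)
  expect_identical(sort(unique(s)), 0:7)
  expect_identical(s[length(z)], 7L)  # max-z point in the last slice
  # uniform fill: each slice ~12.5%
  expect_equal(as.vector(table(s)) / length(z), rep(1 / 8, 8),
               tolerance = 0.05)
  # internal edge point goes to the higher slice
  z2 <- c(0, 25, 50, 75, 100)
  expect_identical(slice_partition(z2, 4), c(0L, 1L, 2L, 3L, 3L))
  # single slice is the identity
  expect_true(all(slice_partition(z, 1) == 0L))
})

test_that("circle fit is exact on circles and matches the normal-equation oracle", {
  # exact circle
  cf <- fit_circle(cbind(c(0, 1, 0, -1), c(1, 0, -1, 0)))
  expect_equal(cf$center, c(0, 0), tolerance = 1e-12)
  expect_equal(cf$radius, 1, tolerance = 1e-12)
  expect_equal(cf$rms_residual, 0, tolerance = 1e-12)
  # exact 120-degree arc
  th <- seq(0, 2 * pi / 3, length.out = 50)
  arc <- cbind(3 + 40 * cos(th), -2 + 40 * sin(th))
  cf2 <- fit_circle(arc)
  expect_equal(cf2$center, c(3, -2), tolerance = 1e-9)
  expect_equal(cf2$radius, 40, tolerance = 1e-9)
  # noisy arc: equals the explicit 3x3 least-squares solve
  set.seed(4)
  noisy <- arc + matrix(rnorm(100, 0, 0.5), ncol = 2)
  cf3 <- fit_circle(noisy)
  x <- noisy[, 1]; y <- noisy[, 2]
  A <- cbind(x, y, 1); b <- -(x^2 + y^2)
  theta <- solve(t(A) %*% A, t(A) %*% b)
  ctr <- -theta[1:2] / 2
  expect_equal(cf3$center, as.vector(ctr), tolerance = 1e-9)
  expect_equal(cf3$radius, sqrt(sum(ctr^2) - theta[3]), tolerance = 1e-9)
  # collinear points are rejected
  expect_error(fit_circle(cbind(1:5, 2 * (1:5))), "collinear")
})

test_that("slice origins: centroid by symmetry, circle fit on the outer boundary", {
  set.seed(5)
  th <- runif(3000, 0, 2 * pi); r <- sqrt(runif(3000))
  disc <- cbind(r * cos(th), r * sin(th))
  expect_equal(slice_origin(disc, "centroid"), c(0, 0), tolerance = 0.05)
  expect_error(slice_origin(disc[1, , drop = FALSE], "centroid"),
               "degenerate slice")

  # crescent: disc radius 20 with a bite taken at (16, 0); the fitted circle
  # center stays near the outer circle's center, displaced from the crescent
  # centroid toward the concave (bite) side
  th2 <- runif(20000, 0, 2 * pi); r2 <- 20 * sqrt(runif(20000))
  pts <- cbind(r2 * cos(th2), r2 * sin(th2))
  crescent <- pts[sqrt((pts[, 1] - 16)^2 + pts[, 2]^2) > 8, ]
  org <- slice_origin(crescent, "circle_fit")
  expect_lt(sqrt(sum(org^2)), 2.5)
  expect_gt(org[1], mean(crescent[, 1]))  # toward the concave side
  # oracle: geometric (nonlinear) circle fit to the same boundary; agreement
  # within a bound set by the boundary's deviation from circularity
  boundary <- swvmap:::outer_boundary(crescent, 72)
  geom <- optim(c(0, 0, 20), function(p) {
    sum((sqrt((boundary[, 1] - p[1])^2 + (boundary[, 2] - p[2])^2) - p[3])^2)
  })$par
  expect_lt(sqrt(sum((org - geom[1:2])^2)), 2)
})

test_that("relative polar coordinates normalize radius and angular span", {
  set.seed(6)
  # annulus: inner rim 0, outer rim 1
  th <- runif(2000, 0, 2 * pi)
  rim <- rep(c(5, 10), each = 1000)
  ann <- cbind(rim * cos(th), rim * sin(th))
  rp <- relative_polar(ann, c(0, 0), "centroid", n_norm_sectors = 12)
  expect_equal(rp$r_rel[1:1000], rep(0, 1000), tolerance = 1e-9)
  expect_equal(rp$r_rel[1001:2000], rep(1, 1000), tolerance = 1e-9)

  # uniform disc: quadrants get equal point counts
  r <- sqrt(runif(8000)); th2 <- runif(8000, 0, 2 * pi)
  disc <- cbind(r * cos(th2), r * sin(th2))
  rp2 <- relative_polar(disc, c(0, 0), "centroid")
  q <- table(pmin(floor(rp2$phi_rel * 4), 3))
  expect_equal(as.vector(q) / 8000, rep(0.25, 4), tolerance = 0.05)

  # 90-degree arc mask in circle_fit mode spans exactly [0, 1]
  th3 <- seq(pi / 6, pi / 6 + pi / 2, length.out = 500)
  arc <- cbind(30 * cos(th3), 30 * sin(th3)) +
    matrix(runif(1000, -0.5, 0.5), ncol = 2)
  rp3 <- relative_polar(arc, c(0, 0), "circle_fit")
  expect_equal(min(rp3$phi_rel), 0, tolerance = 1e-9)
  expect_equal(max(rp3$phi_rel), 1, tolerance = 1e-9)

  # flat sector: all points on one ray at equal radius
  ray <- cbind(rep(5, 10), rep(0, 10))
  expect_warning(rp4 <- relative_polar(ray, c(0, 0), "centroid"),
                 "flat angular sector")
  expect_true(all(rp4$r_rel == 0.5))
})

test_that("parameterization conserves points and reproduces a constant field", {
  ph <- make_phantom(phantom_params(base_swv = 1.5, radial_gain = 0,
                                    longitudinal_gain = 0, smooth_sd = 0),
                     seed = 1)
  cl <- phantom_cloud(ph, spacing = 2)
  cfg <- muscle_config("centroid", n_slices = 8)
  pm <- suppressWarnings(parameterize(cl$points, cfg, swv = cl$swv))
  expect_identical(sum(pm$n), length(cl$swv))  # exact conservation
  expect_true(all(abs(pm$mean[pm$n > 0] - 1.5) < 1e-6))
})

test_that("a radial-gradient field yields cell means increasing in radial index", {
  ph <- smooth_phantom(length_mm = 120, radius_x_mm = 25, radius_y_mm = 15,
                       longitudinal = 0)
  cl <- phantom_cloud(ph, spacing = 1.5)
  cfg <- muscle_config("centroid", n_slices = 4, n_angular = 4, n_radial = 4)
  pm <- suppressWarnings(parameterize(cl$points, cfg, swv = cl$swv))
  # within every (slice, angular) with full radial coverage, means increase
  checked <- 0L
  for (s in 1:4) for (a in 1:4) {
    m <- pm$mean[s, a, ]
    if (all(pm$n[s, a, ] > 30)) {
      checked <- checked + 1L
      expect_true(all(diff(m) > 0),
                  info = sprintf("slice %d angular %d", s, a))
    }
  }
  expect_gt(checked, 8)
  # and the radial axis profile is monotone with slope near the true gain
  rs <- radial_slope(pm)
  expect_true(all(diff(rs$profile$mean) > 0))
  expect_equal(rs$slope, 0.4, tolerance = 0.15)
})

test_that("cell means are rigid-motion invariant", {
  # generic (random) interior points: grid-aligned clouds put points exactly
  # on bin edges, where assignment is legitimately discontinuous
  ph <- smooth_phantom(length_mm = 100)
  set.seed(70)
  cand <- cbind(runif(30000, -18, 18), runif(30000, -12, 12),
                runif(30000, -50, 50))
  keep <- ph$mask_fn(cand)
  cl <- list(points = cand[keep, , drop = FALSE],
             swv = ph$field_fn(cand[keep, , drop = FALSE]))
  cfg <- muscle_config("centroid", n_slices = 4, n_angular = 6, n_radial = 3)
  pm0 <- suppressWarnings(parameterize(cl$points, cfg, swv = cl$swv))
  set.seed(7)
  for (i in 1:3) {
    Rt <- random_rotation()
    t <- rnorm(3, 0, 100)
    moved <- sweep(cl$points %*% t(Rt), 2, t, "+")
    cfg_t <- cfg
    cfg_t$orientation_hint <- as.vector(Rt %*% cfg$orientation_hint)
    pm1 <- suppressWarnings(parameterize(moved, cfg_t, swv = cl$swv))
    expect_identical(pm0$n, pm1$n)
    expect_equal(pm0$mean, pm1$mean, tolerance = 1e-6)
  }
})

test_that("refining then merging angular/radial cells is exact", {
  ph <- smooth_phantom(length_mm = 90)
  frames <- simulate_scan(ph, clean_protocol(n_swipes = 8, lateral = 4,
                                             spacing = 6, width = 40,
                                             depth = 28, px = c(2, 2)),
                          seed = 8)
  vol <- reconstruct(frames, auto_grid(frames, 2))
  mps <- apply_mask(vol, phantom_mask(ph, vol$grid))
  coarse_cfg <- muscle_config("centroid", n_slices = 4, n_angular = 3,
                              n_radial = 2)
  fine_cfg <- muscle_config("centroid", n_slices = 4, n_angular = 6,
                            n_radial = 4)
  coarse <- suppressWarnings(parameterize(mps, coarse_cfg))
  fine <- suppressWarnings(parameterize(mps, fine_cfg))
  merged <- merge_map(fine, fa = 2, fr = 2)
  expect_map_equal(coarse, merged, tol = 0)  # bit-exact
})

test_that("aggregate_maps averages pairwise and flags missing cells", {
  cfg <- muscle_config("centroid", 2, 2, 2)
  mk <- function(v, n = 5L) {
    swvmap:::new_param_map(array(v, c(2, 2, 2)),
                           array(n, c(2, 2, 2)), cfg)
  }
  a <- mk(1.5); b <- mk(1.5)
  agg <- aggregate_maps(list(a, b))
  expect_true(all(agg$mean == 1.5))
  expect_true(all(agg$sem == 0))
  # half-range SEM for n = 2
  c2 <- mk(3.5)
  agg2 <- aggregate_maps(list(a, c2))
  expect_true(all(agg2$mean == 2.5))
  expect_true(all(agg2$sem == 1))
  # a cell empty in one of the maps is flagged and aggregated over the rest
  d <- mk(2.0)
  d$n[1, 1, 1] <- 0L; d$mean[1, 1, 1] <- NA; d$sum[1, 1, 1] <- 0
  agg3 <- aggregate_maps(list(a, c2, d))
  expect_true(agg3$flagged[1, 1, 1])
  expect_identical(agg3$n_maps[1, 1, 1], 2L)
  expect_equal(agg3$mean[1, 1, 1], 2.5)
  expect_equal(agg3$mean[2, 2, 2], mean(c(1.5, 3.5, 2.0)))
})

test_that("axis profiles: flat for constant maps, SEM omitted for one subject", {
  cfg <- muscle_config("centroid", 3, 2, 2)
  m <- swvmap:::new_param_map(array(1.7, c(3, 2, 2)),
                              array(4L, c(3, 2, 2)), cfg)
  for (ax in c("radial", "angular", "longitudinal")) {
    pr <- axis_profile(m, ax)
    expect_true(all(pr$mean == 1.7))
    expect_true(all(is.na(pr$sem)))  # single map: SEM undefined
  }
  pr2 <- axis_profile(list(m, m), "radial")
  expect_true(all(pr2$sem == 0))
})
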