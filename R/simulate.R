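#' Freehand scan protocol
#'
#' Describes a simulated freehand sweep of a tracked elastography probe over
#' a phantom. The probe images a longitudinal plane (frame width along the
#' muscle axis, depth into the tissue) and is swept along the muscle in
#' `n_swipes` laterally offset swipes; frames are spaced `frame_spacing_mm`
#' apart along the sweep, standing in for a 2 Hz frame rate at the (unstated)
#' manual sweep speed. Pose jitter emulates independent per-frame optical
#' tracking error; `noise_sd_mps` is additive Gaussian measurement noise on
#' SWV.
#'
#' @param n_swipes Number of laterally offset swipes (>= 1).
#' @param frame_spacing_mm Longitudinal distance between consecutive frames.
#' @param swipe_lateral_offset_mm Lateral (x) distance between swipe planes.
#' @param pose_jitter_trans_sd_mm Per-frame translation jitter SD (mm).
#' @param pose_jitter_rot_sd_deg Per-frame rotation jitter SD (degrees).
#' @param noise_sd_mps Additive SWV measurement noise SD (m/s).
#' @param frame_width_mm Image width along the sweep direction (mm);
#'   default 50, a 5 cm linear transducer.
#' @param frame_depth_mm Image depth (mm).
#' @param pixel_spacing_mm Length-2 `(du, dv)` pixel spacing (mm).
#' @param standoff_mm Gap between the probe face (first image row) and the
#'   top of the phantom (mm).
#' @return A list of class `scan_protocol`.
#' @export
scan_protocol <- function(n_swipes = 5, frame_spacing_mm = 2.5,
                          swipe_lateral_offset_mm = 8,
                          pose_jitter_trans_sd_mm = 0.5,
                          pose_jitter_rot_sd_deg = 0.5,
                          noise_sd_mps = 0.1,
                          frame_width_mm = 50, frame_depth_mm = 40,
                          pixel_spacing_mm = c(1, 1), standoff_mm = 2) {
  p <- list(n_swipes = as.integer(n_swipes),
            frame_spacing_mm = frame_spacing_mm,
            swipe_lateral_offset_mm = swipe_lateral_offset_mm,
            pose_jitter_trans_sd_mm = pose_jitter_trans_sd_mm,
            pose_jitter_rot_sd_deg = pose_jitter_rot_sd_deg,
            noise_sd_mps = noise_sd_mps,
            frame_width_mm = frame_width_mm,
            frame_depth_mm = frame_depth_mm,
            pixel_spacing_mm = as.numeric(pixel_spacing_mm),
            standoff_mm = standoff_mm)
  if (p$n_swipes < 1L) stop("n_swipes must be >= 1", call. = FALSE)
  if (p$frame_spacing_mm <= 0) stop("frame_spacing_mm must be > 0", call. = FALSE)
  nonneg <- c("swipe_lateral_offset_mm", "pose_jitter_trans_sd_mm",
              "pose_jitter_rot_sd_deg", "noise_sd_mps", "standoff_mm")
  for (f in nonneg) {
    if (p[[f]] < 0) stop(f, " must be >= 0", call. = FALSE)
  }
  if (p$frame_width_mm <= 0 || p$frame_depth_mm <= 0 ||
      any(p$pixel_spacing_mm <= 0) || length(p$pixel_spacing_mm) != 2L) {
    stop("frame geometry must be positive", call. = FALSE)
  }
  class(p) <- "scan_protocol"
  p
}

#' Simulate a freehand tracked scan of a phantom
#'
#' Sweeps longitudinal frame planes over the phantom. Frame planes contain
#' the muscle axis direction (probe parallel to the fibres): image columns
#' run along world +z, image rows into the tissue along world +y, and swipes
#' are offset along world x. Each swipe starts from a randomized end
#' (distal/proximal). Every pixel samples the ground-truth field at its
#' posed world position plus Gaussian noise; pixels outside the mask are
#' invalid. The frame count is `n_swipes * ceiling(travel / frame_spacing)`,
#' with `travel = max(length - frame_width, frame_spacing)`.
#'
#' @param phantom A [make_phantom()] object.
#' @param protocol A [scan_protocol()].
#' @param seed Integer seed (drives swipe direction, jitter and noise).
#' @return List of [swv_frame()] objects.
#' @examples
#' ph <- make_phantom(phantom_params(length_mm = 60), seed = 1)
#' pr <- scan_protocol(n_swipes = 2, noise_sd_mps = 0,
#'                     pose_jitter_trans_sd_mm = 0, pose_jitter_rot_sd_deg = 0)
#' frames <- simulate_scan(ph, pr, seed = 2)
#' @export
simulate_scan <- function(phantom, protocol, seed = 1) {
  stopifnot(inherits(phantom, "phantom"), inherits(protocol, "scan_protocol"))
  p <- phantom$params; pr <- protocol
  travel <- max(p$length_mm - pr$frame_width_mm, pr$frame_spacing_mm)
  n_per_swipe <- as.integer(ceiling(travel / pr$frame_spacing_mm))
  nc <- as.integer(floor(pr$frame_width_mm / pr$pixel_spacing_mm[1])) + 1L
  nr <- as.integer(floor(pr$frame_depth_mm / pr$pixel_spacing_mm[2])) + 1L
  y_top <- -(p$radius_y_mm + pr$standoff_mm)
  # Image u (columns) -> world +z, v (rows) -> world +y, normal -> world -x.
  R0 <- cbind(c(0, 0, 1), c(0, 1, 0), c(-1, 0, 0))

  frames <- with_seed(split_seed(seed, 2L), {
    out <- vector("list", pr$n_swipes * n_per_swipe)
    fi <- 0L
    tstamp <- 0
    for (sw in seq_len(pr$n_swipes)) {
      x_off <- (sw - (pr$n_swipes + 1) / 2) * pr$swipe_lateral_offset_mm
      z0s <- -p$length_mm / 2 + (seq_len(n_per_swipe) - 1L) * pr$frame_spacing_mm
      if (stats::runif(1L) < 0.5) z0s <- rev(z0s)  # randomized start end
      for (z0 in z0s) {
        fi <- fi + 1L
        nominal <- rigid_pose(R0, c(x_off, y_top, z0))
        pose <- nominal
        if (pr$pose_jitter_trans_sd_mm > 0 || pr$pose_jitter_rot_sd_deg > 0) {
          jit <- random_jitter_pose(pr$pose_jitter_trans_sd_mm,
                                    pr$pose_jitter_rot_sd_deg)
          # Rotate about the frame center, then translate.
          ctr <- pose_apply(nominal, c((nc - 1) * pr$pixel_spacing_mm[1] / 2,
                                       (nr - 1) * pr$pixel_spacing_mm[2] / 2, 0))
          pose <- rigid_pose(jit$rotation %*% R0,
                             as.vector(ctr) +
                               as.vector(jit$rotation %*%
                                           (nominal$translation - as.vector(ctr))) +
                               jit$translation)
        }
        u <- (seq_len(nc) - 1L) * pr$pixel_spacing_mm[1]
        v <- (seq_len(nr) - 1L) * pr$pixel_spacing_mm[2]
        local <- cbind(rep(u, each = nr), rep(v, nc), 0)
        world <- pose_apply(pose, local)
        inside <- phantom$mask_fn(world)
        vals <- rep(NA_real_, nr * nc)
        if (any(inside)) {
          vals[inside] <- phantom$field_fn(world[inside, , drop = FALSE])
        }
        if (pr$noise_sd_mps > 0) {
          vals <- vals + stats::rnorm(nr * nc, 0, pr$noise_sd_mps)
        }
        tstamp <- tstamp + 0.5  # 2 Hz acquisition clock
        out[[fi]] <- swv_frame(matrix(vals, nr, nc),
                               matrix(inside, nr, nc),
                               pixel_spacing = pr$pixel_spacing_mm,
                               pose = pose, timestamp = tstamp)
      }
    }
    out
  })
  if (sum(vapply(frames, function(f) sum(f$valid), integer(1))) == 0L) {
    stop("empty scan: no frame plane intersects the phantom mask", call. = FALSE)
  }
  frames
}

#' Specification of a simulated test-retest cohort
#'
#' Generative model for fast reliability studies that bypasses the scan
#' simulator: the parameterized-map cell value for subject i, session j,
#' cell c is
#'
#' `y[i,j,c] = base + region[c] + subject[i] + error[i,j,c]`
#'
#' with `region ~ N(0, sigma_region^2)` drawn once per cohort (systematic
#' regional field shared by all subjects), `subject ~ N(0, sigma_subject^2)`,
#' and iid `error ~ N(0, sigma_error^2)` per cell and session. Under this
#' model the expected ICC(2,1) of any single cell across subjects is
#' `sigma_subject^2 / (sigma_subject^2 + sigma_error^2)`.
#'
#' @param n_subjects Number of subjects (>= 2). Default 16, a typical
#'   reliability-study cohort size.
#' @param sigma_subject Between-subject SD (m/s).
#' @param sigma_region SD of the shared systematic regional offsets (m/s).
#' @param sigma_error Test-retest measurement SD per cell (m/s).
#' @param n_sessions Number of sessions (>= 2).
#' @param base_swv Grand-mean SWV (m/s).
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 16, sigma_subject = 0.15,
                        sigma_region = 0.2, sigma_error = 0.1,
                        n_sessions = 2, base_swv = 1.6, seed = 1) {
  s <- list(n_subjects = as.integer(n_subjects),
            sigma_subject = sigma_subject, sigma_region = sigma_region,
            sigma_error = sigma_error, n_sessions = as.integer(n_sessions),
            base_swv = base_swv, seed = as.integer(seed))
  if (s$n_subjects < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  if (s$n_sessions < 2L) stop("n_sessions must be >= 2", call. = FALSE)
  if (s$sigma_subject < 0 || s$sigma_region < 0 || s$sigma_error < 0) {
    stop("variance-component SDs must be >= 0", call. = FALSE)
  }
  class(s) <- "cohort_spec"
  s
}

#' Simulate a multi-subject test-retest cohort of parameterized maps
#'
#' Draws per-subject, per-session parameterized maps from the [cohort_spec()]
#' generative model, together with the ground truth needed to validate
#' reliability estimators.
#'
#' @param spec A [cohort_spec()].
#' @param map_shape Integer `(S, A, R)` cell-grid shape.
#' @param cell_counts Voxel count attached to every cell (affects weighting
#'   only).
#' @return A list with `maps` (list over subjects of lists over sessions of
#'   `param_map` objects), `truth` (list: `region_offsets`, `subject_effects`,
#'   `expected_icc`) and `spec`.
#' @examples
#' ch <- simulate_cohort(cohort_spec(n_subjects = 4, seed = 3), c(2, 3, 2))
#' ch$truth$expected_icc
#' @export
simulate_cohort <- function(spec, map_shape = c(8, 6, 4), cell_counts = 100L) {
  stopifnot(inherits(spec, "cohort_spec"))
  map_shape <- as.integer(map_shape)
  if (length(map_shape) != 3L || any(map_shape < 1L)) {
    stop("map_shape must be three positive integers (S, A, R)", call. = FALSE)
  }
  ncell <- prod(map_shape)
  cfg <- muscle_config(origin_mode = "centroid", n_slices = map_shape[1],
                       n_angular = map_shape[2], n_radial = map_shape[3])
  with_seed(split_seed(spec$seed, 3L), {
    region <- array(stats::rnorm(ncell, 0, spec$sigma_region), map_shape)
    subj <- stats::rnorm(spec$n_subjects, 0, spec$sigma_subject)
    maps <- lapply(seq_len(spec$n_subjects), function(i) {
      lapply(seq_len(spec$n_sessions), function(j) {
        err <- array(stats::rnorm(ncell, 0, spec$sigma_error), map_shape)
        vals <- spec$base_swv + region + subj[i] + err
        new_param_map(vals, array(as.integer(cell_counts), map_shape), cfg)
      })
    })
    expected_icc <- if (spec$sigma_subject == 0 && spec$sigma_error == 0) {
      NA_real_
    } else {
      spec$sigma_subject^2 / (spec$sigma_subject^2 + spec$sigma_error^2)
    }
    list(maps = maps,
         truth = list(region_offsets = region, subject_effects = subj,
                      expected_icc = expected_icc),
         spec = spec)
  })
}
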