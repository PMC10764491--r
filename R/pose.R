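#' Rigid pose of a tracked ultrasound frame
#'
#' A rigid pose maps frame-plane coordinates `(u, v, 0)` (mm) into the
#' right-handed world frame (mm): `world = R %*% c(u, v, 0) + t`. Poses come
#' from an optical tracking system in the acquisition this package models;
#' here they are plain rotation + translation pairs.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1 (tolerance 1e-8).
#' @param translation Numeric length-3 translation (mm).
#' @return An object of class `rigid_pose`.
#' @examples
#' p <- rigid_pose(diag(3), c(1, 2, 3))
#' pose_apply(p, matrix(0, 1, 3))
#' @export
rigid_pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L))) {
    stop("rotation must be a 3x3 matrix", call. = FALSE)
  }
  if (length(translation) != 3L || anyNA(translation)) {
    stop("translation must be a finite length-3 vector", call. = FALSE)
  }
  ortho_err <- max(abs(crossprod(rotation) - diag(3)))
  if (ortho_err > 1e-8) {
    stop(sprintf("rotation is not orthonormal (max deviation %.3g)", ortho_err),
         call. = FALSE)
  }
  if (abs(det(rotation) - 1) > 1e-8) {
    stop("rotation must have determinant +1 (proper rotation)", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat("<rigid_pose> t = [", paste(signif(x$translation, 6), collapse = ", "),
      "] mm\n")
  invisible(x)
}

#' Apply a rigid pose to points
#'
#' @param pose A `rigid_pose`.
#' @param points N x 3 matrix of coordinates (mm).
#' @return N x 3 matrix of transformed coordinates.
#' @export
pose_apply <- function(pose, points) {
  points <- as_points3(points)
  sweep(points %*% t(pose$rotation), 2L, pose$translation, "+")
}

#' Compose two rigid poses
#'
#' `pose_compose(a, b)` is the pose that first applies `b`, then `a`.
#'
#' @param a,b `rigid_pose` objects.
#' @return A `rigid_pose`.
#' @export
pose_compose <- function(a, b) {
  rigid_pose(a$rotation %*% b$rotation,
             as.vector(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid pose
#'
#' @param pose A `rigid_pose`.
#' @return The inverse `rigid_pose`.
#' @export
pose_inverse <- function(pose) {
  rt <- t(pose$rotation)
  rigid_pose(rt, -as.vector(rt %*% pose$translation))
}

#' Convert a unit quaternion to a rotation matrix
#'
#' Quaternions use the `(w, x, y, z)` scalar-first convention. The input is
#' normalized before conversion.
#'
#' @param q Numeric length-4 quaternion.
#' @return 3x3 rotation matrix.
#' @export
quaternion_to_matrix <- function(q) {
  q <- as.numeric(q)
  if (length(q) != 4L || anyNA(q)) stop("quaternion must be length 4", call. = FALSE)
  n <- sqrt(sum(q^2))
  if (n == 0) stop("zero quaternion", call. = FALSE)
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

#' Convert a rotation matrix to a unit quaternion
#'
#' Returns the `(w, x, y, z)` quaternion with non-negative scalar part
#' (Shepperd's numerically stable branch selection).
#'
#' @param R 3x3 rotation matrix.
#' @return Numeric length-4 unit quaternion.
#' @export
matrix_to_quaternion <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

#' Small random rigid perturbation
#'
#' Draws an independent pose jitter: translation components `N(0, trans_sd)`
#' (mm) and a rotation by an angle `N(0, rot_sd_deg)` degrees about a uniformly
#' random axis. Used to emulate per-frame optical tracking error.
#'
#' @param trans_sd_mm Translation SD per axis (mm).
#' @param rot_sd_deg Rotation angle SD (degrees).
#' @return A `rigid_pose`.
#' @keywords internal
random_jitter_pose <- function(trans_sd_mm, rot_sd_deg) {
  t <- stats::rnorm(3L, 0, trans_sd_mm)
  if (rot_sd_deg > 0) {
    ax <- stats::rnorm(3L)
    ax <- ax / sqrt(sum(ax^2))
    ang <- stats::rnorm(1L, 0, rot_sd_deg) * pi / 180
    R <- axis_angle_matrix(ax, ang)
  } else {
    R <- diag(3)
  }
  rigid_pose(R, t)
}

axis_angle_matrix <- function(axis, angle) {
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3L, 3L,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

as_points3 <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 3L) stop("points must be N x 3", call. = FALSE)
    points <- matrix(points, 1L, 3L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be N x 3", call. = FALSE)
  storage.mode(points) <- "double"
  points
}
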