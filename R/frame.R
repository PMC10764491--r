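#' A single 2D shear wave velocity (or B-mode) frame
#'
#' One tracked elastography measurement: a 2D image of shear wave velocity
#' (m/s), a validity mask, the physical pixel spacing and the rigid pose that
#' places the frame plane in the world. Pixel `(i, j)` (row, column, 1-based)
#' has frame-plane coordinates `u = (j - 1) * du`, `v = (i - 1) * dv`; the
#' pose maps `(u, v, 0)` to world mm. B-mode images travel through the same
#' container with `channel = "bmode"`.
#'
#' Values are snapped to single precision on construction: the scanner
#' delivers 32-bit floats and keeping frames exactly representable in that
#' width makes file round trips bit-exact.
#'
#' @param values Numeric matrix (m/s). Non-finite entries are marked invalid.
#' @param valid Logical matrix of the same shape; defaults to finite `values`.
#' @param pixel_spacing Length-2 positive numeric `(du, dv)` in mm
#'   (column step, row step).
#' @param pose A [rigid_pose()].
#' @param timestamp Acquisition time in seconds.
#' @param channel `"swv"` or `"bmode"`.
#' @return An object of class `swv_frame`.
#' @examples
#' fr <- swv_frame(matrix(1.5, 4, 5), pixel_spacing = c(1, 1))
#' dim(fr$values)
#' @export
swv_frame <- function(values, valid = NULL, pixel_spacing = c(1, 1),
                      pose = rigid_pose(), timestamp = 0,
                      channel = c("swv", "bmode")) {
  channel <- match.arg(channel)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(valid)) valid <- is.finite(values)
  valid <- as.matrix(valid)
  storage.mode(valid) <- "logical"
  if (!identical(dim(values), dim(valid))) {
    stop("values and valid must have identical dimensions", call. = FALSE)
  }
  valid[!is.finite(values)] <- FALSE
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) != 2L || any(!is.finite(pixel_spacing)) ||
      any(pixel_spacing <= 0)) {
    stop("pixel_spacing must be two positive numbers (mm)", call. = FALSE)
  }
  if (!inherits(pose, "rigid_pose")) stop("pose must be a rigid_pose", call. = FALSE)
  structure(list(
    values = snap_single(values),
    valid = valid,
    pixel_spacing = pixel_spacing,
    pose = pose,
    timestamp = as.numeric(timestamp),
    channel = channel
  ), class = "swv_frame")
}

#' @export
print.swv_frame <- function(x, ...) {
  cat(sprintf("<swv_frame> %d x %d px, %.3g x %.3g mm/px, channel %s, %d valid\n",
              nrow(x$values), ncol(x$values), x$pixel_spacing[1],
              x$pixel_spacing[2], x$channel, sum(x$valid)))
  invisible(x)
}

# Round doubles to the nearest single-precision float.
snap_single <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.vector(x), raw(), size = 4L), "double",
               n = length(x), size = 4L)
  dim(y) <- d
  y
}

#' World coordinates of frame pixels
#'
#' @param frame An `swv_frame`.
#' @param valid_only If `TRUE` (default) return only valid pixels.
#' @return A list with `points` (N x 3 world mm) and `values` (numeric N).
#' @export
frame_pixel_world <- function(frame, valid_only = TRUE) {
  nr <- nrow(frame$values); nc <- ncol(frame$values)
  u <- (col(frame$values) - 1) * frame$pixel_spacing[1]
  v <- (row(frame$values) - 1) * frame$pixel_spacing[2]
  keep <- if (valid_only) as.vector(frame$valid) else rep(TRUE, nr * nc)
  nk <- sum(keep)
  local <- matrix(c(as.vector(u)[keep], as.vector(v)[keep], rep(0, nk)),
                  nrow = nk, ncol = 3L)
  list(points = pose_apply(frame$pose, local),
       values = as.vector(frame$values)[keep])
}

check_frameset <- function(frames) {
  if (length(frames) == 0L) stop("frame set is empty", call. = FALSE)
  if (!all(vapply(frames, inherits, logical(1), "swv_frame"))) {
    stop("all elements must be swv_frame objects", call. = FALSE)
  }
  dims <- vapply(frames, function(f) dim(f$values), integer(2))
  sp <- vapply(frames, function(f) f$pixel_spacing, numeric(2))
  if (any(dims != dims[, 1]) || any(sp != sp[, 1])) {
    stop("frames must share image dimensions and pixel spacing", call. = FALSE)
  }
  invisible(frames)
}
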