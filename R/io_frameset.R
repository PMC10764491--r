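#' Write a frame set to disk
#'
#' Persists a tracked frame set as a directory of standard, inspectable
#' files: `values.nii.gz` and `valid.nii.gz` (image stacks, pages along the
#' third axis), `poses.csv` (unit quaternion + translation + timestamp per
#' frame, full precision) and `manifest.json` (geometry and channel). The
#' round trip is lossless: values bit-exactly (frames are single-precision by
#' construction), poses to better than 1e-12.
#'
#' @param frames List of [swv_frame()] objects with homogeneous geometry.
#' @param path Directory to create/overwrite.
#' @return Invisibly, the manifest list.
#' @seealso [read_frameset()]
#' @export
write_frameset <- function(frames, path) {
  check_frameset(frames)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  nr <- nrow(frames[[1]]$values); nc <- ncol(frames[[1]]$values)
  n <- length(frames)
  vals <- array(NA_real_, c(nr, nc, n))
  vld <- array(0, c(nr, nc, n))
  for (i in seq_len(n)) {
    vals[, , i] <- frames[[i]]$values
    vld[, , i] <- frames[[i]]$valid * 1
  }
  RNifti::writeNifti(RNifti::asNifti(vals), file.path(path, "values.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(vld), file.path(path, "valid.nii.gz"))
  pose_df <- do.call(rbind, lapply(seq_len(n), function(i) {
    q <- matrix_to_quaternion(frames[[i]]$pose$rotation)
    t <- frames[[i]]$pose$translation
    data.frame(frame = i - 1L, qw = q[1], qx = q[2], qy = q[3], qz = q[4],
               tx = t[1], ty = t[2], tz = t[3],
               timestamp = frames[[i]]$timestamp)
  }))
  write_csv_full(pose_df, file.path(path, "poses.csv"))
  manifest <- list(
    format = "swvmap-frameset-1",
    n_frames = n,
    image_rows = nr,
    image_cols = nc,
    pixel_spacing_mm = frames[[1]]$pixel_spacing,
    channel = frames[[1]]$channel
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a frame set from disk
#'
#' @param path Directory written by [write_frameset()].
#' @return List of [swv_frame()] objects.
#' @export
read_frameset <- function(path) {
  man_file <- file.path(path, "manifest.json")
  if (!file.exists(man_file)) stop("no manifest.json in ", path, call. = FALSE)
  man <- jsonlite::read_json(man_file, simplifyVector = TRUE)
  vals <- as.array(RNifti::readNifti(file.path(path, "values.nii.gz")))
  vld <- as.array(RNifti::readNifti(file.path(path, "valid.nii.gz")))
  if (length(dim(vals)) == 2L) dim(vals) <- c(dim(vals), 1L)
  if (length(dim(vld)) == 2L) dim(vld) <- c(dim(vld), 1L)
  n <- man$n_frames
  if (dim(vals)[3] != n) {
    stop(sprintf("manifest declares %d frames but values stack has %d",
                 n, dim(vals)[3]), call. = FALSE)
  }
  poses <- utils::read.csv(file.path(path, "poses.csv"))
  lapply(seq_len(n) - 1L, function(i) {
    row <- poses[poses$frame == i, , drop = FALSE]
    if (nrow(row) == 0L) stop("pose missing for frame ", i, call. = FALSE)
    if (nrow(row) > 1L) stop("duplicate pose rows for frame ", i, call. = FALSE)
    pose <- rigid_pose(quaternion_to_matrix(c(row$qw, row$qx, row$qy, row$qz)),
                       c(row$tx, row$ty, row$tz))
    swv_frame(vals[, , i + 1L], vld[, , i + 1L] > 0.5,
              pixel_spacing = man$pixel_spacing_mm, pose = pose,
              timestamp = row$timestamp, channel = man$channel)
  })
}

# CSV writer preserving full double precision (%.17g survives a read round
# trip bit-exactly).
write_csv_full <- function(df, path) {
  fmt <- vapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  }, FUN.VALUE = character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L, dimnames = list(NULL, names(df)))
  lines <- c(paste(names(df), collapse = ","),
             apply(fmt, 1L, paste, collapse = ","))
  writeLines(lines, path)
}
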