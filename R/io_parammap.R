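#' Write parameterized maps as long-format CSV
#'
#' One row per cell, including empty cells (`n_voxels = 0`, empty mean
#' field), with columns exactly `subject, session, muscle, slice_idx,
#' angular_idx, radial_idx, mean_swv_mps, n_voxels`. Indices are 0-based.
#' Means are written at full precision and round-trip exactly.
#'
#' @param map A `param_map` (or a data.frame already in long format).
#' @param path Output CSV path.
#' @param subject,session,muscle Identifiers stored with every row.
#' @return Invisibly, the long-format data.frame.
#' @export
write_param_map <- function(map, path, subject = "s01", session = 1L,
                            muscle = "muscle") {
  df <- if (is.data.frame(map)) map else {
    param_map_to_df(map, subject = subject, session = session, muscle = muscle)
  }
  check_param_map_df(df)
  out <- df
  out$mean_swv_mps <- ifelse(is.na(df$mean_swv_mps), "",
                             sprintf("%.17g", df$mean_swv_mps))
  lines <- c(paste(names(out), collapse = ","),
             do.call(paste, c(unname(out), sep = ",")))
  writeLines(lines, path)
  invisible(df)
}

#' Convert a `param_map` to the long-format data.frame
#'
#' @inheritParams write_param_map
#' @return A data.frame, one row per cell.
#' @export
param_map_to_df <- function(map, subject = "s01", session = 1L,
                            muscle = "muscle") {
  stopifnot(inherits(map, "param_map"))
  d <- dim(map$mean)
  idx <- expand.grid(slice_idx = 0:(d[1] - 1), angular_idx = 0:(d[2] - 1),
                     radial_idx = 0:(d[3] - 1))
  data.frame(subject = subject, session = as.integer(session),
             muscle = muscle, idx,
             mean_swv_mps = as.vector(map$mean),
             n_voxels = as.vector(map$n))
}

#' Read parameterized maps from long-format CSV
#'
#' @param path CSV written by [write_param_map()].
#' @param as_map If `TRUE` and the file holds a single subject/session,
#'   return a `param_map`; otherwise the long data.frame.
#' @return A data.frame or `param_map`.
#' @export
read_param_map <- function(path, as_map = FALSE) {
  df <- utils::read.csv(path, colClasses = list(mean_swv_mps = "numeric"))
  check_param_map_df(df)
  if (!as_map) return(df)
  key <- unique(df[, c("subject", "session", "muscle")])
  if (nrow(key) != 1L) {
    stop("file holds multiple subject/session maps; use as_map = FALSE",
         call. = FALSE)
  }
  df_to_param_map(df)
}

df_to_param_map <- function(df) {
  S <- max(df$slice_idx) + 1L; A <- max(df$angular_idx) + 1L
  R <- max(df$radial_idx) + 1L
  means <- array(NA_real_, c(S, A, R)); counts <- array(0L, c(S, A, R))
  lin <- 1 + df$slice_idx + S * (df$angular_idx + A * df$radial_idx)
  means[lin] <- df$mean_swv_mps
  counts[lin] <- df$n_voxels
  cfg <- muscle_config(origin_mode = "centroid", n_slices = S,
                       n_angular = A, n_radial = R)
  new_param_map(means, counts, cfg)
}

check_param_map_df <- function(df) {
  required <- c("subject", "session", "muscle", "slice_idx", "angular_idx",
                "radial_idx", "mean_swv_mps", "n_voxels")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  key <- df[, c("subject", "session", "muscle", "slice_idx", "angular_idx",
                "radial_idx")]
  dup <- duplicated(key)
  if (any(dup)) {
    d <- key[which(dup)[1], ]
    stop(sprintf("duplicate cell key: subject %s session %s slice %d angular %d radial %d",
                 d$subject, d$session, d$slice_idx, d$angular_idx,
                 d$radial_idx), call. = FALSE)
  }
  bad <- !is.na(df$mean_swv_mps) & df$n_voxels == 0
  if (any(bad)) stop("cells with n_voxels = 0 must have empty mean", call. = FALSE)
  invisible(df)
}
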