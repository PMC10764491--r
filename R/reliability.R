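#' Two-way ANOVA mean squares without replication
#'
#' Decomposes an n-targets x k-sessions table into row (target), column
#' (session) and residual mean squares: `SS_total = SS_rows + SS_cols +
#' SS_err` with degrees of freedom `n - 1`, `k - 1`, `(n - 1)(k - 1)`. This
#' is the decomposition underlying the two-way random-effects ICC.
#'
#' @param X Numeric n x k matrix, n >= 2 rows (targets), k >= 2 columns
#'   (sessions/raters).
#' @return List: `msr`, `msc`, `mse`, `n`, `k`.
#' @export
two_way_mean_squares <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must not contain missing values", call. = FALSE)
  n <- nrow(X); k <- ncol(X)
  if (n < 2L || k < 2L) stop("need at least 2 rows and 2 columns", call. = FALSE)
  grand <- mean(X)
  ssr <- k * sum((rowMeans(X) - grand)^2)
  ssc <- n * sum((colMeans(X) - grand)^2)
  sst <- sum((X - grand)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = max(sse, 0) / ((n - 1) * (k - 1)), n = n, k = k)
}

#' ICC(2,1): two-way random effects, absolute agreement, single measure
#'
#' Point estimate `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with
#' the F-based 95% confidence interval for the absolute-agreement
#' single-measure coefficient (McGraw & Wong convention), the standard error
#' of measurement `SD * sqrt(1 - ICC)` and the qualitative band of
#' [classify_icc()]. Rows containing missing values are dropped (listwise)
#' and counted in `n_dropped`. An all-constant table has no defined ICC and
#' is returned with `status = "undefined"`; a perfect-agreement table yields
#' ICC 1 with a degenerate (NA) interval and `status = "degenerate_ci"`.
#'
#' @param X Numeric n x k matrix (targets x sessions).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `reliability_result`: `icc`, `ci` (lo, hi),
#'   `sem`, `band`, `anova`, `status`, `n_dropped`.
#' @examples
#' icc_2_1(cbind(c(1, 2, 3), c(1.1, 2.2, 2.9)))
#' @export
icc_2_1 <- function(X, conf_level = 0.95) {
  X <- as.matrix(X)
  complete <- stats::complete.cases(X)
  n_dropped <- sum(!complete)
  X <- X[complete, , drop = FALSE]
  if (nrow(X) < 2L) {
    stop("fewer than 2 complete rows; ICC not estimable", call. = FALSE)
  }
  ms <- two_way_mean_squares(X)
  n <- ms$n; k <- ms$k
  denom <- ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse)
  if (abs(denom) < .Machine$double.eps * max(1, abs(ms$msr))) {
    return(structure(list(icc = NA_real_, ci = c(NA_real_, NA_real_),
                          sem = 0, band = NA_character_, anova = ms,
                          status = "undefined", n_dropped = n_dropped),
                     class = "reliability_result"))
  }
  icc <- (ms$msr - ms$mse) / denom
  alpha <- 1 - conf_level
  if (1 - icc < 1e-12) {
    ci <- c(NA_real_, NA_real_)
    status <- "degenerate_ci"
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * ms$msc + b * ms$mse)^2 /
      ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (ms$msr - fl * ms$mse) /
      (fl * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    upper <- n * (fu * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * fu * ms$msr)
    ci <- c(lower, upper)
    status <- "ok"
  }
  structure(list(icc = icc, ci = ci, sem = sem_measure(X, icc),
                 band = classify_icc(icc), anova = ms, status = status,
                 n_dropped = n_dropped),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  if (identical(x$status, "undefined")) {
    cat("<reliability_result> undefined (constant table)\n")
  } else {
    cat(sprintf("<reliability_result> ICC(2,1) %.3f (%.3f, %.3f), SEm %.3f m/s, %s\n",
                x$icc, x$ci[1], x$ci[2], x$sem, x$band))
  }
  invisible(x)
}

#' Standard error of measurement
#'
#' Default definition `SEm = SD * sqrt(1 - ICC)`, with the SD taken over all
#' n x k table entries (sample SD). The ANOVA-based alternative
#' `sqrt(MSE)` is available as `method = "anova"`.
#'
#' @param X The measurement table used for the ICC.
#' @param icc The ICC estimate.
#' @param method `"sd"` (default) or `"anova"`.
#' @return SEm in the measurement's units (m/s).
#' @export
sem_measure <- function(X, icc, method = c("sd", "anova")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (method == "anova") {
    return(sqrt(two_way_mean_squares(X)$mse))
  }
  if (is.na(icc)) return(NA_real_)
  stats::sd(as.vector(X)) * sqrt(max(0, 1 - icc))
}

#' Qualitative ICC band
#'
#' Thresholds: poor (<= 0.2), fair (0.2, 0.4], moderate (0.4, 0.6],
#' good (0.6, 0.8], very good (> 0.8).
#'
#' @param v Numeric vector of ICC values.
#' @return Character vector of bands.
#' @examples
#' classify_icc(c(0.941, 0.578, 0.752))
#' @export
classify_icc <- function(v) {
  out <- rep(NA_character_, length(v))
  out[!is.na(v) & v <= 0.2] <- "poor"
  out[!is.na(v) & v > 0.2 & v <= 0.4] <- "fair"
  out[!is.na(v) & v > 0.4 & v <= 0.6] <- "moderate"
  out[!is.na(v) & v > 0.6 & v <= 0.8] <- "good"
  out[!is.na(v) & v > 0.8] <- "very_good"
  out
}

#' Whole-muscle scalar of a parameterized map
#'
#' Voxel-count-weighted mean SWV over all cells (exact, via stored sums).
#'
#' @param map A `param_map`.
#' @return Scalar m/s.
#' @export
whole_muscle_scalar <- function(map) {
  stopifnot(inherits(map, "param_map"))
  sum(map$sum) / sum(map$n)
}

#' Whole-muscle test-retest reliability
#'
#' Reduces every subject-session map to its voxel-count-weighted mean and
#' computes ICC(2,1) on the resulting n-subjects x 2 table.
#'
#' @param maps_session1,maps_session2 Lists of `param_map` objects, one per
#'   subject, in matching subject order.
#' @return A `reliability_result`.
#' @export
whole_muscle_reliability <- function(maps_session1, maps_session2) {
  if (length(maps_session1) != length(maps_session2)) {
    stop("sessions must have the same subjects", call. = FALSE)
  }
  if (length(maps_session1) < 2L) {
    stop("need at least 2 subjects for reliability", call. = FALSE)
  }
  X <- cbind(vapply(maps_session1, whole_muscle_scalar, numeric(1)),
             vapply(maps_session2, whole_muscle_scalar, numeric(1)))
  icc_2_1(X)
}

#' Regional test-retest reliability
#'
#' Two complementary framings of cell-level reliability:
#' `inter_regional` asks how reproducibly the regions *within* one
#' subject-muscle are measured (one ICC per subject; table rows = cells,
#' columns = sessions); `inter_subject` asks how reproducibly one region is
#' measured *across* subjects (one ICC per cell; rows = subjects). Tables
#' with fewer than 2 complete rows yield no estimate and are logged in
#' `n_undefined`. Summaries are the median and interquartile range over the
#' defined estimates.
#'
#' @param maps_session1,maps_session2 Lists of `param_map` objects (one per
#'   subject, matching order and shape).
#' @param domain `"inter_regional"` or `"inter_subject"`.
#' @return List of class `regional_reliability`: `domain`, `results` (list
#'   of `reliability_result`), `icc` (vector), `sem` (vector),
#'   `icc_median`, `icc_iqr`, `sem_median`, `sem_iqr`, `n_undefined`.
#' @export
regional_reliability <- function(maps_session1, maps_session2,
                                 domain = c("inter_regional", "inter_subject")) {
  domain <- match.arg(domain)
  check_map_list(c(maps_session1, maps_session2))
  if (length(maps_session1) != length(maps_session2)) {
    stop("sessions must have the same subjects", call. = FALSE)
  }
  n_subj <- length(maps_session1)
  ncell <- length(maps_session1[[1]]$mean)

  tables <- if (domain == "inter_regional") {
    lapply(seq_len(n_subj), function(i) {
      cbind(as.vector(maps_session1[[i]]$mean),
            as.vector(maps_session2[[i]]$mean))
    })
  } else {
    m1 <- vapply(maps_session1, function(m) as.vector(m$mean), numeric(ncell))
    m2 <- vapply(maps_session2, function(m) as.vector(m$mean), numeric(ncell))
    lapply(seq_len(ncell), function(c) cbind(m1[c, ], m2[c, ]))
  }
  results <- lapply(tables, function(X) {
    ok <- sum(stats::complete.cases(X)) >= 2L
    if (!ok) return(NULL)
    icc_2_1(X)
  })
  defined <- !vapply(results, is.null, logical(1))
  iccs <- vapply(results[defined], function(r) r$icc, numeric(1))
  sems <- vapply(results[defined], function(r) r$sem, numeric(1))
  est <- !is.na(iccs)
  structure(list(domain = domain, results = results,
                 icc = iccs[est], sem = sems[est],
                 icc_median = stats::median(iccs[est]),
                 icc_iqr = unname(stats::quantile(iccs[est], c(0.25, 0.75))),
                 sem_median = stats::median(sems[est]),
                 sem_iqr = unname(stats::quantile(sems[est], c(0.25, 0.75))),
                 n_undefined = sum(!defined) + sum(!est)),
            class = "regional_reliability")
}

#' @export
print.regional_reliability <- function(x, ...) {
  cat(sprintf("<regional_reliability> %s: median ICC %.3f (IQR %.3f-%.3f), median SEm %.3f (IQR %.3f-%.3f), %d undefined\n",
              x$domain, x$icc_median, x$icc_iqr[1], x$icc_iqr[2],
              x$sem_median, x$sem_iqr[1], x$sem_iqr[2], x$n_undefined))
  invisible(x)
}

#' Paired t-test on subject-level scalars
#'
#' Classical paired t: `t = mean(d) / (sd(d) / sqrt(n))` with `d = post -
#' pre`, `df = n - 1`, two-sided p. Zero-variance nonzero differences have
#' no defined t and are returned with `status = "degenerate"`.
#'
#' @param pre,post Numeric vectors of equal length (n >= 2).
#' @return List: `t`, `df`, `p`, `mean_diff`, `n`, `status`.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre/post lengths differ", call. = FALSE)
  ok <- is.finite(pre) & is.finite(post)
  d <- post[ok] - pre[ok]
  n <- length(d)
  if (n < 2L) stop("need at least 2 paired observations", call. = FALSE)
  sd_d <- stats::sd(d)
  # constant differences up to floating-point resolution carry no pairing
  # information
  if (sd_d <= 1e-9 * mean(abs(d))) sd_d <- 0
  if (sd_d == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0, n = n,
                  status = "ok"))
    }
    return(list(t = NA_real_, df = n - 1, p = NA_real_, mean_diff = mean(d),
                n = n, status = "degenerate"))
  }
  t <- mean(d) / (sd_d / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1),
       mean_diff = mean(d), n = n, status = "ok")
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties averaged). The two-sided p-value
#' uses the t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` by
#' default; for n <= 8 an exact permutation p-value is available.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @param p_method `"t_approx"` (default) or `"exact"` (n <= 8 only).
#' @return List: `rho`, `p`, `n`, `status`.
#' @examples
#' spearman_rho(1:8, c(2, 1, 4, 3, 6, 5, 8, 7))
#' @export
spearman_rho <- function(x, y, p_method = c("t_approx", "exact")) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) stop("x/y lengths differ", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, status = "degenerate"))
  }
  rho <- stats::cor(rx, ry)
  if (p_method == "exact") {
    if (n > 8L) stop("exact permutation p only available for n <= 8", call. = FALSE)
    perms <- all_permutations(n)
    rho_null <- apply(perms, 1L, function(pm) stats::cor(rx, ry[pm]))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  list(rho = rho, p = p, n = n, status = "ok")
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Per-bin paired contrast of pre vs post maps
#'
#' Collapses each subject's pre and post maps onto one anatomical axis
#' ([axis_profile()]) and runs a paired t-test per bin. P-values are
#' unadjusted by default; `adjust = TRUE` adds Benjamini-Hochberg adjusted
#' values.
#'
#' @param pre_maps,post_maps Lists of `param_map` objects (one per subject,
#'   matching order).
#' @param axis `"radial"`, `"angular"` or `"longitudinal"`.
#' @param adjust Add BH-adjusted p-values (default `FALSE`).
#' @return data.frame: `bin`, `mean_pre`, `mean_post`, `mean_diff`, `t`,
#'   `df`, `p`, `status` (+ `p_adj` when `adjust`).
#' @export
regional_contrast <- function(pre_maps, post_maps,
                              axis = c("radial", "angular", "longitudinal"),
                              adjust = FALSE) {
  axis <- match.arg(axis)
  if (length(pre_maps) != length(post_maps)) {
    stop("pre/post subject counts differ", call. = FALSE)
  }
  pre <- attr(axis_profile(pre_maps, axis), "per_map")
  post <- attr(axis_profile(post_maps, axis), "per_map")
  res <- lapply(seq_len(ncol(pre)), function(b) {
    tt <- paired_t(pre[, b], post[, b])
    data.frame(bin = b - 1L, mean_pre = mean(pre[, b], na.rm = TRUE),
               mean_post = mean(post[, b], na.rm = TRUE),
               mean_diff = tt$mean_diff, t = tt$t, df = tt$df, p = tt$p,
               status = tt$status)
  })
  out <- do.call(rbind, res)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Per-bin rank association of regional SWV with a covariate
#'
#' Collapses each subject's map onto one axis and correlates each bin's
#' values across subjects with the covariate (Spearman). Bins are flagged
#' significant at `p < alpha` (unadjusted). With fewer than 4 subjects the
#' p-value is undefined and the bin is flagged.
#'
#' @param maps List of `param_map` objects, one per subject.
#' @param covariate Numeric vector, one value per subject (e.g. normalized
#'   maximal eccentric hamstring strength, N/kg).
#' @param axis `"radial"`, `"angular"` or `"longitudinal"`.
#' @param alpha Significance threshold (default 0.05).
#' @return data.frame: `bin`, `rho`, `p`, `n`, `significant`, `status`.
#' @export
regional_association <- function(maps, covariate,
                                 axis = c("radial", "angular", "longitudinal"),
                                 alpha = 0.05) {
  axis <- match.arg(axis)
  if (length(maps) != length(covariate)) {
    stop("covariate must have one value per subject", call. = FALSE)
  }
  prof <- attr(axis_profile(maps, axis), "per_map")
  res <- lapply(seq_len(ncol(prof)), function(b) {
    v <- prof[, b]
    ok <- is.finite(v) & is.finite(covariate)
    if (sum(ok) < 4L) {
      return(data.frame(bin = b - 1L, rho = NA_real_, p = NA_real_,
                        n = sum(ok), significant = NA,
                        status = "too_few_subjects"))
    }
    sr <- spearman_rho(v[ok], covariate[ok])
    data.frame(bin = b - 1L, rho = sr$rho, p = sr$p, n = sr$n,
               significant = !is.na(sr$p) && sr$p < alpha,
               status = sr$status)
  })
  do.call(rbind, res)
}

#' Normalized maximal eccentric hamstring strength
#'
#' Median of the six per-repetition maximum forces divided by body mass.
#'
#' @param forces6 Numeric vector of exactly six repetition maxima (N).
#' @param body_mass_kg Body mass (kg, > 0).
#' @return Normalized strength (N/kg).
#' @examples
#' normalized_mehs(c(300, 310, 320, 330, 340, 350), 70)
#' @export
normalized_mehs <- function(forces6, body_mass_kg) {
  if (length(forces6) != 6L) stop("six repetitions required", call. = FALSE)
  if (!is.numeric(body_mass_kg) || length(body_mass_kg) != 1L ||
      !is.finite(body_mass_kg) || body_mass_kg <= 0) {
    stop("body_mass_kg must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(forces6))) stop("forces must be finite", call. = FALSE)
  stats::median(forces6) / body_mass_kg
}
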