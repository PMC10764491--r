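test_that("two-way mean squares match hand-computed ANOVA sums", {
  X <- cbind(c(1, 2, 3), c(1, 2, 3))
  ms <- two_way_mean_squares(X)
  expect_equal(ms$msr, 2)   # rows 1,2,3 -> SSR = 2*2, df 2
  expect_equal(ms$msc, 0)
  expect_equal(ms$mse, 0)
  # constant table: all mean squares zero
  msc <- two_way_mean_squares(matrix(5, 4, 2))
  expect_equal(c(msc$msr, msc$msc, msc$mse), c(0, 0, 0))
  # adding a constant to one column changes MSC only
  set.seed(1)
  X2 <- random_table(10, 3)
  X3 <- X2; X3[, 2] <- X3[, 2] + 1.7
  a <- two_way_mean_squares(X2); b <- two_way_mean_squares(X3)
  expect_equal(a$msr, b$msr, tolerance = 1e-12)
  expect_equal(a$mse, b$mse, tolerance = 1e-12)
  expect_gt(b$msc, a$msc)
  expect_error(two_way_mean_squares(matrix(1, 1, 2)), "at least 2")
})

test_that("icc_2_1 equals the aov-based oracle on random tables", {
  set.seed(2)
  for (i in 1:60) {
    n <- sample(4:30, 1); k <- sample(2:4, 1)
    X <- random_table(n, k, sd_row = runif(1, 0.1, 3),
                      sd_err = runif(1, 0.1, 2))
    expect_equal(icc_2_1(X)$icc, icc_oracle(X), tolerance = 1e-12)
  }
})

test_that("icc_2_1 handles perfect agreement, reversal and degeneracy", {
  X <- cbind(c(1, 2, 3), c(1, 2, 3))
  r <- icc_2_1(X)
  expect_equal(r$icc, 1)
  expect_equal(r$sem, 0)
  expect_identical(r$status, "degenerate_ci")
  # reversed columns: equals the explicit ANOVA formula
  X2 <- cbind(c(1, 2, 3), c(3, 2, 1))
  expect_equal(icc_2_1(X2)$icc, icc_oracle(X2), tolerance = 1e-12)
  # all-constant table: undefined with explicit status
  r3 <- icc_2_1(matrix(2, 5, 2))
  expect_identical(r3$status, "undefined")
  expect_true(is.na(r3$icc))
  # rows with missing entries are dropped and counted
  X4 <- rbind(cbind(rnorm(5), rnorm(5)), c(NA, 1))
  r4 <- icc_2_1(X4)
  expect_identical(r4$n_dropped, 1L)
  expect_identical(r4$anova$n, 5L)
})

test_that("icc_2_1 confidence interval brackets the estimate and covers truth", {
  set.seed(3)
  # bracket property on random tables
  for (i in 1:20) {
    X <- random_table(12, 2)
    r <- icc_2_1(X)
    if (r$status == "ok") {
      expect_lte(r$ci[1], r$icc)
      expect_gte(r$ci[2], r$icc)
    }
  }
  # quick coverage check at true ICC 0.5 (full calibration in acceptance)
  cover <- vapply(1:300, function(i) {
    X <- matrix(rnorm(60, 0, 1), 60, 1)[, c(1, 1)] + matrix(rnorm(120), 60, 2)
    ci <- icc_2_1(X)$ci
    ci[1] <= 0.5 && 0.5 <= ci[2]
  }, logical(1))
  expect_gt(mean(cover), 0.88)
})

test_that("SEm follows SD * sqrt(1 - ICC) with the ANOVA variant available", {
  set.seed(4)
  X <- random_table(10, 2)
  r <- icc_2_1(X)
  expect_equal(r$sem, sd(as.vector(X)) * sqrt(1 - r$icc), tolerance = 1e-12)
  expect_equal(sem_measure(X, 0), sd(as.vector(X)))
  expect_equal(sem_measure(X, 1), 0)
  expect_equal(sem_measure(X, r$icc, method = "anova"),
               sqrt(two_way_mean_squares(X)$mse), tolerance = 1e-12)
})

test_that("ICC bands match the published thresholds exactly", {
  eps <- 1e-9
  expect_identical(classify_icc(c(-0.5, 0, 0.2)), rep("poor", 3))
  expect_identical(classify_icc(c(0.2 + eps, 0.3, 0.4)), rep("fair", 3))
  expect_identical(classify_icc(c(0.4 + eps, 0.5, 0.6)), rep("moderate", 3))
  expect_identical(classify_icc(c(0.6 + eps, 0.7, 0.8)), rep("good", 3))
  expect_identical(classify_icc(c(0.8 + eps, 0.9, 1)), rep("very_good", 3))
  # published whole-muscle and regional estimates fall in the stated bands
  expect_identical(classify_icc(0.941), "very_good")
  expect_identical(classify_icc(0.578), "moderate")
  expect_identical(classify_icc(0.752), "good")
})

test_that("whole-muscle reliability is exact for identical sessions", {
  ch <- simulate_cohort(cohort_spec(n_subjects = 6, seed = 9), c(3, 2, 2))
  s1 <- lapply(ch$maps, `[[`, 1)
  r <- whole_muscle_reliability(s1, s1)
  expect_equal(r$icc, 1)
  expect_equal(r$sem, 0)
  expect_error(whole_muscle_reliability(s1[1], s1[1]), "at least 2 subjects")
})

test_that("whole-muscle reliability recovers the cohort's closed-form ICC", {
  est <- vapply(1:100, function(r) {
    ch <- simulate_cohort(cohort_spec(n_subjects = 200,
                                      sigma_subject = sqrt(3),
                                      sigma_region = 0, sigma_error = 1,
                                      seed = 5000 + r), c(1, 1, 1))
    whole_muscle_reliability(lapply(ch$maps, `[[`, 1),
                             lapply(ch$maps, `[[`, 2))$icc
  }, numeric(1))
  expect_equal(mean(est), 0.75, tolerance = 0.03)
})

test_that("regional reliability separates inter-regional from inter-subject", {
  ch <- simulate_cohort(cohort_spec(n_subjects = 10, seed = 10), c(3, 2, 2))
  s1 <- lapply(ch$maps, `[[`, 1)
  # identical sessions: every ICC 1, IQR width 0
  rr <- regional_reliability(s1, s1, "inter_regional")
  expect_true(all(abs(rr$icc - 1) < 1e-12))
  expect_equal(diff(rr$icc_iqr), 0)
  # strong shared regional structure, weak subject effects:
  # inter-regional reliability must exceed inter-subject reliability
  ch2 <- simulate_cohort(cohort_spec(n_subjects = 12, sigma_subject = 0.05,
                                     sigma_region = 0.5, sigma_error = 0.15,
                                     seed = 11), c(4, 3, 2))
  m1 <- lapply(ch2$maps, `[[`, 1); m2 <- lapply(ch2$maps, `[[`, 2)
  ir <- regional_reliability(m1, m2, "inter_regional")
  is_ <- regional_reliability(m1, m2, "inter_subject")
  expect_gt(ir$icc_median, is_$icc_median)
  expect_error(regional_reliability(m1, m2, "interregional"))
})

test_that("paired t matches the closed form and flags degenerate differences", {
  expect_equal(paired_t(c(1, 2, 3), c(3, 2, 1))[c("t", "p")],
               list(t = 0, p = 1))
  # constant nonzero difference: undefined t with explicit status
  r <- paired_t(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_identical(r$status, "degenerate")
  expect_true(is.na(r$t))
  set.seed(5)
  for (i in 1:20) {
    pre <- rnorm(10); post <- rnorm(10)
    r2 <- paired_t(pre, post)
    d <- post - pre
    expect_equal(r2$t, mean(d) / (sd(d) / sqrt(10)), tolerance = 1e-12)
    tt <- t.test(post, pre, paired = TRUE)  # independent oracle
    expect_equal(r2$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(r2$p, tt$p.value, tolerance = 1e-12)
  }
})

test_that("spearman rho: endpoints, midrank oracle and monotone invariance", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_rho(1:10, -(1:10))$rho, -1)
  set.seed(6)
  for (i in 1:20) {
    x <- sample(1:5, 12, replace = TRUE)  # heavy ties
    y <- rnorm(12)
    r <- spearman_rho(x, y)
    # oracle: Pearson on mid-ranks computed from first principles
    midrank <- function(v) {
      vapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2, numeric(1))
    }
    rx <- midrank(x); ry <- midrank(y)
    oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(r$rho, oracle, tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(spearman_rho(exp(x), y)$rho, r$rho)
    expect_equal(spearman_rho(x, qlogis(plogis(y)))$rho, r$rho,
                 tolerance = 1e-12)
  }
  # p-value matches cor.test t-approximation
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8, 4, 5)
  r <- spearman_rho(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(r$rho, unname(ct$estimate), tolerance = 1e-12)
  # exact permutation p on a small sample is a valid probability and
  # consistent with the approximation
  r8 <- spearman_rho(1:7, c(2, 1, 4, 3, 7, 5, 6), p_method = "exact")
  expect_gt(r8$p, 0); expect_lt(r8$p, 0.1)
})

test_that("regional contrast detects a uniform shift and flags degeneracy", {
  ch <- simulate_cohort(cohort_spec(n_subjects = 8, sigma_error = 0.05,
                                    seed = 12), c(3, 2, 3))
  pre <- lapply(ch$maps, `[[`, 1)
  # exact uniform shift: zero-variance differences are degenerate per bin
  shift <- function(m, d) {
    swvmap:::new_param_map(m$mean + d, m$n, m$config)
  }
  post0 <- lapply(pre, shift, d = 0.2)
  rc0 <- regional_contrast(pre, post0, "radial")
  expect_true(all(rc0$status == "degenerate"))
  # shift plus independent session noise: every bin t > 0
  post1 <- lapply(ch$maps, function(ss) shift(ss[[2]], 0.2))
  rc1 <- regional_contrast(pre, post1, "radial")
  expect_true(all(rc1$status == "ok"))
  expect_true(all(rc1$t > 0))
  rc2 <- regional_contrast(pre, post1, "longitudinal", adjust = TRUE)
  expect_true(all(rc2$p_adj >= rc2$p - 1e-15))
  expect_error(regional_contrast(pre, post1, "diagonal"))
})

test_that("regional association finds a planted identity covariate", {
  ch <- simulate_cohort(cohort_spec(n_subjects = 12, sigma_subject = 0.3,
                                    seed = 13), c(2, 2, 3))
  maps <- lapply(ch$maps, `[[`, 1)
  prof <- attr(axis_profile(maps, "radial"), "per_map")
  ra <- regional_association(maps, prof[, 2], "radial")
  expect_equal(ra$rho[2], 1)
  expect_true(ra$significant[2])
  # under 4 subjects: undefined, flagged
  ra2 <- regional_association(maps[1:3], prof[1:3, 2], "radial")
  expect_true(all(ra2$status == "too_few_subjects"))
  expect_true(all(is.na(ra2$p)))
  expect_error(regional_association(maps, 1:3, "radial"), "one value per subject")
})

test_that("normalized strength is the median of six maxima over body mass", {
  expect_equal(normalized_mehs(c(300, 310, 320, 330, 340, 350), 70), 325 / 70)
  expect_equal(normalized_mehs(rep(280, 6), 80), 3.5)
  expect_error(normalized_mehs(c(300, 310, 320, 330, 340), 70),
               "six repetitions required")
  expect_error(normalized_mehs(rep(280, 6), 0), "positive")
})
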