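test_that("roc_auc matches pair counting on canonical examples", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0))$auc, 0.75)
  expect_equal(roc_auc(rep(0.5, 10), rep(0:1, 5))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  r <- roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_true(all(r$ci >= 0 & r$ci <= 1))
  expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))
})

test_that("roc_auc equals brute-force concordance on random instances", {
  set.seed(11)
  for (i in 1:300) {
    m <- sample(2:8, 1)
    n <- sample(2:8, 1)
    s <- sample(seq(0, 1, by = 0.1), m + n, replace = TRUE)  # forces ties
    y <- c(rep(1, m), rep(0, n))
    # both are rationals with denominator 2mn: compare the integerized form
    expect_identical(round(2 * m * n * roc_auc(s, y)$auc),
                     round(2 * m * n * brute_auc(s, y)))
  }
})

test_that("DeLong comparison: identical models, variance vs bootstrap", {
  y <- rep(1:0, each = 5)
  s <- c(runif(5, 0.5, 1), runif(5, 0, 0.5))
  same <- delong_compare(s, s, y)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  expect_error(delong_compare(s[1:9], s, y), "paired")

  # 6-subject toy: DeLong variance within 15% of a stratified bootstrap
  sc <- c(0.9, 0.7, 0.4, 0.6, 0.3, 0.1)
  y6 <- c(1, 1, 1, 0, 0, 0)
  pl <- smfdx:::delong_placements(sc, y6)
  v_delong <- var(pl$v10) / 3 + var(pl$v01) / 3
  set.seed(1)
  boot <- replicate(10000, {
    ci <- sample(1:3, replace = TRUE)
    co <- sample(4:6, replace = TRUE)
    smfdx:::delong_placements(sc[c(ci, co)], y6)$auc
  })
  expect_lt(abs(var(boot) - v_delong) / v_delong, 0.15)
})

test_that("DeLong CI covers the true binormal AUC at nominal rate", {
  set.seed(3)
  mu <- sqrt(2) * qnorm(0.8)
  y <- rep(1:0, each = 100)
  hits <- replicate(600, {
    ci <- roc_auc(c(rnorm(100, mu), rnorm(100)), y)$ci
    ci[1] <= 0.8 && 0.8 <= ci[2]
  })
  expect_gte(mean(hits), 0.92)
  expect_lte(mean(hits), 0.98)
})

test_that("Youden threshold maximizes J with the documented tie-break", {
  yt <- youden_threshold(c(0.9, 0.6, 0.3, 0.7, 0.2, 0.1),
                         c(1, 1, 1, 0, 0, 0))
  expect_equal(yt$threshold, 0.3)
  expect_equal(yt$sensitivity, 1)
  expect_equal(yt$specificity, 2 / 3)
  expect_equal(yt$youden_j, 2 / 3)
  expect_identical(yt$youden_j, yt$sensitivity + yt$specificity - 1)
  perfect <- youden_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$youden_j, 1)
  # J ties: the larger threshold (higher specificity) wins
  tied <- youden_threshold(c(0.8, 0.6, 0.4, 0.2), c(1, 1, 0, 0))
  expect_equal(tied$specificity, 1)
})

test_that("threshold metrics satisfy the confusion identities", {
  set.seed(5)
  s <- runif(40)
  y <- rbinom(40, 1, 0.5)
  m <- threshold_metrics(s, y, 0.5)
  expect_equal(m$tp + m$fp + m$fn + m$tn, 40)
  expect_equal(m$sensitivity, m$tp / (m$tp + m$fn))
  expect_equal(m$accuracy, (m$tp + m$tn) / 40)
})

test_that("operating-point rates match the brute-force scan and are monotone", {
  expect_equal(rate_at_operating_point(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0),
                                       "specificity", 0.98)$rate, 1.0)
  set.seed(6)
  y <- rep(0:1, 30)
  s <- 0.5 * y + runif(60)          # overlapping score distributions
  for (lv in c(0.5, 0.8, 0.9)) {
    expect_equal(rate_at_operating_point(s, y, "specificity", lv)$rate,
                 brute_sens_at_spec(s, y, lv))
  }
  sens_at <- vapply(c(0.5, 0.7, 0.9, 0.98), function(lv)
    rate_at_operating_point(s, y, "specificity", lv)$rate, numeric(1))
  expect_true(all(diff(sens_at) <= 1e-12))
  # pinning sensitivity at 1 on overlapping scores costs specificity
  r <- rate_at_operating_point(s, y, "sensitivity", 1.0)
  expect_lt(r$rate, 1)
  expect_equal(r$sensitivity, 1)
})

test_that("permutation AUC test: extremes, null centering, lower bound", {
  set.seed(7)
  y <- rep(1:0, each = 12)
  s <- c(runif(12, 0.6, 1), runif(12, 0, 0.4))
  r <- permutation_auc_test(s, y, n_perm = 999, seed = 5)
  expect_equal(r$auc, 1)
  expect_equal(r$p, 1 / 1000)

  s0 <- runif(24)
  r0 <- permutation_auc_test(s0, y, n_perm = 499, seed = 8)
  mc_se <- sd(r0$null_auc) / sqrt(499)
  expect_lt(abs(mean(r0$null_auc) - 0.5), 3 * mc_se + 0.01)
  expect_gte(r0$p, 1 / 500)
  expect_error(permutation_auc_test(s0, y, n_perm = 50), "n_perm")
})

test_that("AUC power: design points, alpha limit, monotonicity", {
  p1 <- auc_test_power(99, 136, 0.95, 0.9)
  p2 <- auc_test_power(73, 25, 0.9, 0.8)
  expect_equal(p1, 0.8016, tolerance = 1e-3)
  expect_equal(p2, 0.7942, tolerance = 1e-3)
  # vanishing effect: power collapses to alpha
  expect_equal(auc_test_power(99, 136, 0.9 + 1e-9, 0.9), 0.05,
               tolerance = 5e-3)
  # monotone in n and in the AUC gap
  small <- auc_test_power(40, 50, 0.95, 0.9)
  expect_gt(p1, small)
  expect_gt(auc_test_power(99, 136, 0.97, 0.9), p1)
  expect_error(auc_test_power(99, 136, 0.85, 0.9), "auc_alt")
})

test_that("Monte-Carlo power cross-checks the closed form", {
  p_hm <- auc_test_power(99, 136, 0.95, 0.9)
  # model-consistent (exponential) simulation agrees tightly
  p_exp <- auc_test_power(99, 136, 0.95, 0.9, method = "monte-carlo",
                          mc_model = "exponential", n_sims = 4000,
                          seed = 11)
  expect_lt(abs(p_exp - p_hm), 0.03)
  # binormal world: Hanley-McNeil variance is conservative, allow 0.06
  p_bin <- auc_test_power(99, 136, 0.95, 0.9, method = "monte-carlo",
                          n_sims = 4000, seed = 11)
  expect_lt(abs(p_bin - p_hm), 0.06)
})

test_that("secondary tests: Wilcoxon enumeration, correlation, stage table", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(w$p, 1 / 20)
  x <- rnorm(30)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_lt(pearson_correlation(x, x + rnorm(30, 0, 1e-8))$p, 1e-20)

  det <- rep(c(0, 1), c(40, 60))
  stage <- factor(rep(c("0", "I", "II"), 34)[1:100])
  r <- stage_detection_test(det, stage)
  expect_equal(r$df, 2)
  expect_true(r$p > 0 && r$p <= 1)
  strong_det <- c(rep(0, 30), rep(1, 30))
  strong_stage <- factor(rep(c("0", "IV"), each = 30))
  expect_lt(stage_detection_test(strong_det, strong_stage)$p, 1e-10)
  tr <- stage_detection_test(strong_det, strong_stage, method = "trend")
  expect_lt(tr$p, 1e-10)
  expect_error(stage_detection_test(rep(1, 10),
                                    factor(rep("I", 10))), "both classes")
})

test_that("Hosmer-Lemeshow is calibrated under the null and flags miscalibration", {
  set.seed(13)
  # df = g - 2 presumes fitted probabilities: refit the calibration model
  # before grouping, as in real use
  rej <- replicate(250, {
    p <- runif(1000, 0.05, 0.95)
    y <- rbinom(1000, 1, p)
    fit <- stats::glm(y ~ qlogis(p), family = stats::binomial)
    hosmer_lemeshow(stats::fitted(fit), y)$p < 0.05
  })
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.11)
  # grossly miscalibrated probabilities are rejected
  p <- runif(1000, 0.05, 0.95)
  y <- rbinom(1000, 1, plogis(3 * qlogis(p)))
  expect_lt(hosmer_lemeshow(p, y)$p, 1e-4)
  hl <- hosmer_lemeshow(runif(500), rbinom(500, 1, 0.5))
  expect_equal(hl$df, 8)
})
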