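# Evaluation statistics: empirical ROC/AUC with DeLong variance machinery,
# Youden-index thresholding, operating-point rates, a permutation
# overfitting test, Hanley-McNeil AUC power analysis, and the secondary
# tests (Wilcoxon, chi-square incl. trend, Hosmer-Lemeshow, Pearson).

as_binary_labels <- function(labels) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  u <- sort(unique(labels))
  if (!all(u %in% c(0, 1))) stop_input("labels must be binary (0/1)")
  if (length(u) < 2L) stop_input("both classes must be present")
  as.integer(labels)
}

# DeLong placement values. V10[i]: fraction of controls scored below case i
# (ties count 1/2); V01[j]: fraction of cases scored above control j.
delong_placements <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (any(!is.finite(scores))) stop_input("scores must be finite")
  x <- scores[y == 1L]
  z <- scores[y == 0L]
  m <- length(x)
  n <- length(z)
  r_all <- rank(c(x, z), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(x, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(z, ties.method = "average")) / m
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' Empirical ROC curve with DeLong confidence interval
#'
#' AUC is the Mann-Whitney concordance probability (ties count one half);
#' its standard error comes from the DeLong placement-value variance, and
#' the 95% CI is `auc +/- 1.96 * se` clipped to [0, 1].
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels binary labels (1/TRUE = case).
#' @param conf_level confidence level for the CI.
#' @return object of class `roc_summary`: `auc`, `se`, `ci`, `n_case`,
#'   `n_control`, and a `points` data frame (threshold, fpr, tpr).
#' @export
#' @examples
#' roc_auc(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0))$auc
roc_auc <- function(scores, labels, conf_level = 0.95) {
  pl <- delong_placements(scores, labels)
  se <- sqrt(stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(pl$auc + c(-1, 1) * zq * se, 0), 1)
  y <- as_binary_labels(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[y == 1L] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[y == 0L] >= t), numeric(1))
  structure(list(auc = pl$auc, se = se, ci = ci,
                 n_case = pl$m, n_control = pl$n,
                 points = data.frame(threshold = thr, fpr = fpr, tpr = tpr)),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), %d cases / %d controls\n",
              x$auc, x$ci[1], x$ci[2], x$n_case, x$n_control))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two models scored on the same subjects, using the
#' covariance of their placement values.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels binary labels (shared).
#' @return list: `auc_a`, `auc_b`, `z`, `p` (two-sided).
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) {
    stop_input("score vectors must be paired (lengths %d vs %d)",
               length(scores_a), length(scores_b))
  }
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  var_a <- stats::var(pa$v10) / pa$m + stats::var(pa$v01) / pa$n
  var_b <- stats::var(pb$v10) / pb$m + stats::var(pb$v01) / pb$n
  cv <- stats::cov(pa$v10, pb$v10) / pa$m + stats::cov(pa$v01, pb$v01) / pa$n
  v <- var_a + var_b - 2 * cv
  d <- pa$auc - pb$auc
  z <- if (v <= 0) {
    if (d == 0) 0 else sign(d) * Inf
  } else d / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

rates_at_threshold <- function(scores, y, t) {
  pos <- scores >= t
  tp <- sum(pos & y == 1L); fp <- sum(pos & y == 0L)
  fn <- sum(!pos & y == 1L); tn <- sum(!pos & y == 0L)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       accuracy = (tp + tn) / length(y))
}

#' Operating point maximizing the Youden index
#'
#' Scans every observed score as a "positive iff score >= t" threshold and
#' returns the one maximizing J = sensitivity + specificity - 1; ties break
#' toward the higher-specificity (larger) threshold.
#'
#' @param scores,labels as in [roc_auc()].
#' @return list: `threshold`, `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy`, `youden_j`, and confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
youden_threshold <- function(scores, labels) {
  y <- as_binary_labels(labels)
  cand <- sort(unique(scores))
  sens <- vapply(cand, function(t) mean(scores[y == 1L] >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(scores[y == 0L] < t), numeric(1))
  j <- sens + spec - 1
  best <- max(which(j == max(j)))           # ties -> larger t, higher spec
  out <- rates_at_threshold(scores, y, cand[best])
  c(list(threshold = cand[best],
         youden_j = out$sensitivity + out$specificity - 1), out)
}

#' Apply a fixed threshold and report operating metrics
#'
#' @param scores,labels as in [roc_auc()].
#' @param threshold positivity threshold ("positive iff score >= t").
#' @return list of rates and confusion counts as in [youden_threshold()].
#' @export
threshold_metrics <- function(scores, labels, threshold) {
  y <- as_binary_labels(labels)
  out <- rates_at_threshold(scores, y, threshold)
  c(list(threshold = threshold,
         youden_j = out$sensitivity + out$specificity - 1), out)
}

#' Detection rate at a fixed specificity (or sensitivity)
#'
#' Fixing specificity at `level` picks the smallest observed score whose
#' ">= t" rule attains at least that specificity and returns the resulting
#' sensitivity; fixing sensitivity picks the largest observed score
#' attaining at least that sensitivity and returns the specificity.
#'
#' @param scores,labels as in [roc_auc()].
#' @param fixed which rate to pin: "specificity" or "sensitivity".
#' @param level required rate, in (0, 1].
#' @return list: `threshold`, `sensitivity`, `specificity`, plus the
#'   requested `rate` (the complementary class's rate).
#' @export
rate_at_operating_point <- function(scores, labels,
                                    fixed = c("specificity", "sensitivity"),
                                    level) {
  fixed <- match.arg(fixed)
  check_number(level, "level", lower = 0, upper = 1, strict_lower = TRUE)
  y <- as_binary_labels(labels)
  cand <- sort(unique(scores))
  sens <- vapply(cand, function(t) mean(scores[y == 1L] >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(scores[y == 0L] < t), numeric(1))
  if (fixed == "specificity") {
    ok <- which(spec >= level)
    if (!length(ok)) stop_input("specificity %.3f unattainable at observed scores",
                                level)
    i <- ok[1]                               # smallest t => best sensitivity
    rate <- sens[i]
  } else {
    ok <- which(sens >= level)
    if (!length(ok)) stop_input("sensitivity %.3f unattainable at observed scores",
                                level)
    i <- ok[length(ok)]                      # largest t => best specificity
    rate <- spec[i]
  }
  list(threshold = cand[i], sensitivity = sens[i], specificity = spec[i],
       rate = rate)
}

#' Permutation test of the AUC (overfitting check)
#'
#' Permutes the evaluation labels `n_perm` times and compares the observed
#' AUC to the null distribution; `p = (1 + #{null >= observed}) /
#' (n_perm + 1)`.
#'
#' @param scores,labels as in [roc_auc()].
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return list: `auc`, `null_auc` (vector), `p`.
#' @export
permutation_auc_test <- function(scores, labels, n_perm = 999, seed = 1L) {
  n_perm <- check_count(n_perm, "n_perm", lower = 99)
  y <- as_binary_labels(labels)
  m <- sum(y == 1L)
  n <- sum(y == 0L)
  r <- rank(scores, ties.method = "average")
  auc_of <- function(yy) (sum(r[yy == 1L]) - m * (m + 1) / 2) / (m * n)
  obs <- auc_of(y)
  null_auc <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) auc_of(sample(y)), numeric(1))
  })
  list(auc = obs, null_auc = null_auc,
       p = (1 + sum(null_auc >= obs)) / (n_perm + 1))
}

# Hanley-McNeil variance of an empirical AUC given the true AUC and
# case/control counts.
hanley_mcneil_var <- function(auc, n_case, n_control) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  (auc * (1 - auc) + (n_case - 1) * (q1 - auc^2) +
      (n_control - 1) * (q2 - auc^2)) / (n_case * n_control)
}

#' Power of a one-sided test that the AUC exceeds a null value
#'
#' Closed form (`"hanley-mcneil"`): with `se0`/`se1` the Hanley-McNeil
#' standard errors at the null and alternative AUC,
#' `power = Phi((auc_alt - auc_null - z_{1-alpha} * se0) / se1)`. Monte
#' Carlo (`"monte-carlo"`): simulates binormal scores with the alternative
#' AUC, applies the same one-sided normal test against `auc_null`, and
#' reports the rejection fraction.
#'
#' @param n_case,n_control design sample sizes.
#' @param auc_alt true (alternative) AUC, in (auc_null, 1].
#' @param auc_null null AUC, in [0.5, 1).
#' @param alpha one-sided type-I error rate.
#' @param method "hanley-mcneil" (default) or "monte-carlo".
#' @param mc_model score model for the Monte-Carlo method: "binormal"
#'   (equal-variance Gaussians) or "exponential" (the bi-negative
#'   exponential model underlying the Hanley-McNeil variance; use this for
#'   a model-consistent cross-check of the closed form).
#' @param n_sims Monte-Carlo replicates.
#' @param seed Monte-Carlo seed.
#' @return power in [0, 1].
#' @export
#' @examples
#' auc_test_power(99, 136, auc_alt = 0.95, auc_null = 0.9)
auc_test_power <- function(n_case, n_control, auc_alt, auc_null,
                           alpha = 0.05,
                           method = c("hanley-mcneil", "monte-carlo"),
                           mc_model = c("binormal", "exponential"),
                           n_sims = 10000L, seed = 1L) {
  mc_model <- match.arg(mc_model)
  method <- match.arg(method)
  n_case <- check_count(n_case, "n_case", lower = 2)
  n_control <- check_count(n_control, "n_control", lower = 2)
  check_number(auc_null, "auc_null", lower = 0.5, upper = 1,
               strict_upper = TRUE)
  check_number(auc_alt, "auc_alt", lower = auc_null, upper = 1,
               strict_lower = TRUE)
  check_number(alpha, "alpha", lower = 0, upper = 0.5,
               strict_lower = TRUE, strict_upper = TRUE)
  se0 <- sqrt(hanley_mcneil_var(auc_null, n_case, n_control))
  if (method == "hanley-mcneil") {
    se1 <- sqrt(hanley_mcneil_var(auc_alt, n_case, n_control))
    return(stats::pnorm(
      (auc_alt - auc_null - stats::qnorm(1 - alpha) * se0) / se1))
  }
  n_sims <- check_count(n_sims, "n_sims", lower = 100)
  mu <- sqrt(2) * stats::qnorm(auc_alt)
  case_rate <- (1 - auc_alt) / auc_alt
  zcrit <- stats::qnorm(1 - alpha)
  with_seed(seed, {
    rej <- vapply(seq_len(n_sims), function(i) {
      if (mc_model == "binormal") {
        x <- stats::rnorm(n_case, mu)
        z <- stats::rnorm(n_control)
      } else {
        x <- stats::rexp(n_case, case_rate)
        z <- stats::rexp(n_control, 1)
      }
      r <- rank(c(x, z))
      auc <- (sum(r[seq_len(n_case)]) - n_case * (n_case + 1) / 2) /
        (n_case * n_control)
      (auc - auc_null) / se0 > zcrit
    }, logical(1))
    mean(rej)
  })
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk chi-square: subjects are grouped by quantiles of the
#' predicted probability; the statistic sums `(O - E)^2 / E` over observed
#' and expected events and non-events per group, with `groups - 2` degrees
#' of freedom.
#'
#' @param prob predicted probabilities in [0, 1].
#' @param y binary outcomes.
#' @param groups number of quantile groups (default 10).
#' @return list: `statistic`, `df`, `p`, and the per-group table.
#' @export
hosmer_lemeshow <- function(prob, y, groups = 10L) {
  groups <- check_count(groups, "groups", lower = 2)
  y <- as_binary_labels(y)
  if (any(prob < 0 | prob > 1)) stop_input("`prob` must lie in [0, 1]")
  br <- unique(stats::quantile(prob, probs = seq(0, 1, length.out = groups + 1)))
  if (length(br) < 3L) stop_input("too few distinct probabilities to group")
  g <- cut(prob, breaks = br, include.lowest = TRUE)
  obs1 <- tapply(y, g, sum)
  n_g <- tapply(y, g, length)
  exp1 <- tapply(prob, g, sum)
  keep <- !is.na(n_g) & n_g > 0
  obs1 <- obs1[keep]; n_g <- n_g[keep]; exp1 <- exp1[keep]
  if (any(exp1 <= 0) || any(n_g - exp1 <= 0)) {
    stop_input("degenerate expected counts in Hosmer-Lemeshow groups")
  }
  stat <- sum((obs1 - exp1)^2 / exp1 +
                ((n_g - obs1) - (n_g - exp1))^2 / (n_g - exp1))
  df <- length(n_g) - 2L
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       table = data.frame(n = as.vector(n_g), observed = as.vector(obs1),
                          expected = as.vector(exp1)))
}

#' Detection-by-stage association test
#'
#' Pearson chi-square (default) on the detection x stage contingency table,
#' or a Cochran-Armitage trend test with equally spaced stage scores.
#'
#' @param detected logical/binary detection calls.
#' @param stage ordered stage factor (e.g. 0, I, II, III, IV).
#' @param method "chisq" or "trend".
#' @return the `htest`-like list (`statistic`, `df`, `p`).
#' @export
stage_detection_test <- function(detected, stage,
                                 method = c("chisq", "trend")) {
  method <- match.arg(method)
  detected <- as_binary_labels(detected)
  stage <- droplevels(as.factor(stage))
  tab <- table(detected, stage)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_input("degenerate detection x stage table (zero margin)")
  }
  if (method == "chisq") {
    ht <- stats::chisq.test(tab, correct = FALSE)
    return(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value, table = tab))
  }
  sc <- seq_len(ncol(tab)) - 1
  n_k <- colSums(tab)
  d_k <- tab["1", ]
  n <- sum(n_k)
  d <- sum(d_k)
  num <- sum(sc * (d_k - n_k * d / n))
  pbar <- d / n
  v <- pbar * (1 - pbar) * (sum(sc^2 * n_k) - sum(sc * n_k)^2 / n)
  z <- num / sqrt(v)
  list(statistic = z, df = NA_integer_, p = 2 * stats::pnorm(-abs(z)),
       table = tab)
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Thin wrapper with the package conventions: exact enumeration for small
#' tie-free samples, normal approximation with tie correction otherwise.
#'
#' @param x,y numeric samples.
#' @param alternative "two.sided", "less" or "greater" (for `x` vs `y`).
#' @return list: `statistic` (rank-sum W), `p`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "less",
                                              "greater")) {
  alternative <- match.arg(alternative)
  ht <- stats::wilcox.test(x, y, alternative = alternative)
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors.
#' @return list: `r`, `p`.
#' @export
pearson_correlation <- function(x, y) {
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value)
}
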