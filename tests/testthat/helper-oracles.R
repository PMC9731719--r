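# Independent brute-force oracles, kept deliberately naive.

# White top-hat by literal sliding min then sliding max (reflect boundary
# with edge repetition, matching the package convention).
brute_tophat <- function(x, w) {
  r <- (w - 1L) %/% 2L
  n <- length(x)
  pad <- function(v) c(v[pmin(r:1, n)], v, v[pmax(n - (1:r) + 1L, 1L)])
  xe <- pad(x)
  er <- vapply(seq_len(n), function(i) min(xe[i:(i + 2L * r)]), numeric(1))
  ee <- pad(er)
  op <- vapply(seq_len(n), function(i) max(ee[i:(i + 2L * r)]), numeric(1))
  pmax(x - op, 0)
}

# AUC by exhaustive pair counting, ties half.
brute_auc <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  tot <- 0
  for (a in x) for (b in y) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(x) * length(y))
}

# Sensitivity at fixed specificity by literal threshold scan over observed
# scores ("positive iff score >= t").
brute_sens_at_spec <- function(scores, labels, level) {
  cand <- sort(unique(scores))
  best <- NULL
  for (t in cand) {
    spec <- mean(scores[labels == 0] < t)
    if (spec >= level) { best <- t; break }
  }
  if (is.null(best)) stop("unattainable")
  mean(scores[labels == 1] >= best)
}

as_binned <- function(x, width = 1) {
  structure(list(bin_lower_edges = (seq_along(x) - 1) * width,
                 intensity = as.double(x), bin_width = width,
                 subject_id = "toy"),
            class = "binned_spectrum")
}
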