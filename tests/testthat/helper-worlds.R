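# Shared synthetic worlds for the test suite. Scales are desk-sized; the
# signal-structure parameters are the package defaults unless a scenario
# states otherwise.

tiny_cohort <- function(seed = 1L, ...) {
  generate_cohort(desk_cohort_config(n_hc = 6, n_lbd = 4, n_luad = 8,
                                     seed = seed, ...))
}

# Complementary-signal nodule world: moderate metabolic effect, informative
# CEA, default image-AI score. Mirrors a 480-subject nodule cohort.
scenario_cohort_config <- function(seed = 1L, ...) {
  desk_cohort_config(
    n_hc = 0, n_lbd = 140, n_luad = 340,
    effect_size = 0.35,
    cea_params = list(hc = c(meanlog = log(1.8), sdlog = 0.55),
                      lbd = c(meanlog = log(2.0), sdlog = 0.60),
                      luad = c(meanlog = log(6.0), sdlog = 0.90)),
    seed = seed, ...)
}

# A toy two-class feature matrix with a known number of informative columns.
toy_features <- function(n = 100L, p = 50L, informative = 2L, delta = 2,
                         seed = 1L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  for (j in seq_len(informative)) X[, j] <- X[, j] + delta * y
  rownames(X) <- sprintf("T%03d", seq_len(n))
  list(X = X, y = y)
}

small_net <- function(input_dim, use_fusion = FALSE, dropout = 0,
                      blocks = 2L, hidden = 16L, seed = 7L) {
  build_network(net_config(input_dim = input_dim, n_blocks = blocks,
                           hidden_units = hidden, dropout_rate = dropout,
                           use_fusion = use_fusion), seed = seed)
}
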