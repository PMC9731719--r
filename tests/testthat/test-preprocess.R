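test_that("Gaussian smoothing: unit-sum kernel, mass preservation", {
  const <- raw_spectrum(1:5, rep(5, 5))
  expect_equal(smooth_spectrum(const, 1)$intensity, rep(5, 5),
               tolerance = 1e-12)
  # interior unit impulse: center value is the normalized discrete kernel
  imp <- raw_spectrum(1:21, c(rep(0, 10), 1, rep(0, 10)))
  sm <- smooth_spectrum(imp, 1)
  kern <- dnorm(-4:4)
  expect_equal(sm$intensity[11], dnorm(0) / sum(kern), tolerance = 1e-9)
  expect_equal(sum(sm$intensity), 1, tolerance = 1e-9)
  expect_error(smooth_spectrum(imp, 0), "sigma")
})

test_that("binning: half-open max bins, bin count, monotone halving", {
  sp <- raw_spectrum(c(100.00, 100.02, 100.04, 100.06), c(1, 2, 3, 4))
  b <- bin_spectrum(sp, 0.05, 100, c(100, 100.1))
  expect_equal(b$intensity, c(3, 4))
  expect_equal(b$bin_lower_edges, c(100, 100.05))

  single <- bin_spectrum(raw_spectrum(500.3, 7), 0.05, 100, c(100, 1000))
  expect_equal(sum(single$intensity > 0), 1)
  expect_equal(max(single$intensity), 7)

  wide <- raw_spectrum(seq(100, 999.5, by = 0.5), rep(1, 1800))
  expect_length(bin_spectrum(wide, 0.05)$intensity, 18000)
  expect_length(bin_spectrum(wide, 0.025)$intensity, 36000)
  expect_equal(sum(bin_spectrum(wide, 0.5, agg = "sum")$intensity), 1800)
  expect_error(bin_spectrum(raw_spectrum(50, 1), 0.05, 100, c(100, 1000)),
               "empty")
})

test_that("white top-hat matches the brute-force morphology oracle", {
  expect_equal(tophat_baseline(as_binned(c(2, 2, 9, 2, 2)), 3)$intensity,
               c(0, 0, 7, 0, 0))
  expect_equal(tophat_baseline(as_binned(rep(4, 12)), 5)$intensity,
               rep(0, 12))
  # plateau wider than the element is removed entirely
  plateau <- c(0, 0, 6, 6, 6, 6, 6, 0, 0)
  expect_equal(tophat_baseline(as_binned(plateau), 3)$intensity,
               rep(0, 9))
  set.seed(4)
  for (i in 1:200) {
    x <- sample(0:9, sample(5:40, 1), replace = TRUE)
    w <- sample(c(3L, 5L, 7L, 9L), 1)
    expect_identical(tophat_baseline(as_binned(x), w)$intensity,
                     brute_tophat(x, w))
  }
  expect_error(tophat_baseline(as_binned(1:5), 4), "odd")
})

test_that("top-hat leaves narrow peaks unchanged (idempotence)", {
  set.seed(9)
  x <- numeric(60)
  x[c(10, 30, 50)] <- c(5, 8, 3)          # spikes narrower than the element
  once <- tophat_baseline(as_binned(x), 7)$intensity
  twice <- tophat_baseline(as_binned(once), 7)$intensity
  expect_identical(twice, once)
})

test_that("peak detection: strict local maxima with tie and SNR rules", {
  pk <- detect_peaks(as_binned(c(0, 1, 0, 3, 0)), peak_window = 1,
                     snr_threshold = 0)
  expect_equal(pk$bin, c(2L, 4L))
  expect_equal(pk$height, c(1, 3))
  expect_equal(nrow(detect_peaks(as_binned(rep(0, 50)), 3, 3)), 0)
  # plateau tie resolves to the lower index
  tie <- detect_peaks(as_binned(c(0, 5, 5, 0, 0)), 1, 0)
  expect_equal(tie$bin, 2L)
  # SNR threshold suppresses small bumps
  set.seed(12)
  y <- abs(rnorm(60))
  y[30] <- 50
  noisy <- detect_peaks(as_binned(y), 2, 10)
  expect_equal(noisy$bin, 30L)
})

test_that("planted high-SNR peaks are recovered", {
  rates <- vapply(1:5, function(s) {
    cfg <- desk_cohort_config(n_hc = 1, n_lbd = 0, n_luad = 0,
                              n_peaks = 60, n_discriminative = 0,
                              peak_height_meanlog2 = 9,
                              peak_height_sdlog2 = 0.5, seed = 100 + s)
    coh <- generate_cohort(cfg)
    pp <- preprocess_spectrum(synthesize_spectrum("S0001", coh$truth),
                              desk_preprocess_config())
    # score only isolated apexes: a base peak whose window is shared with
    # another rendered component (e.g. an adduct copy of a different peak)
    # is not a strict local maximum by construction
    comp <- sort(c(coh$truth$peak_mz, coh$truth$peak_mz + 21.9819,
                   coh$truth$peak_mz + 37.9559))
    isolated <- vapply(coh$truth$peak_mz, function(m)
      sum(abs(comp - m) < 1.6) == 1L, logical(1))   # 4x the rendered sd
    hit <- vapply(coh$truth$peak_mz[isolated], function(m)
      any(abs(pp$peaks$mz - m) <= 0.4), logical(1))
    mean(hit)
  }, numeric(1))
  expect_gte(mean(rates), 0.95)
})

test_that("feature matrix assembly honors prevalence and alignment", {
  pk <- function(bins, hts) data.frame(bin = bins, mz = bins - 0.5,
                                       height = hts)
  b1 <- as_binned(c(0, 5, 0, 2, 0))
  b2 <- as_binned(c(0, 4, 0, 0, 3))
  fm <- build_feature_matrix(list(a = pk(2L, 5), b = pk(2L, 4)),
                             list(a = b1, b = b2),
                             feature_prevalence = 0.5,
                             tic_normalize = FALSE)
  expect_equal(dim(fm$values), c(2L, 1L))
  expect_equal(as.vector(fm$values), c(5, 4))

  fm0 <- build_feature_matrix(list(a = pk(2L, 5), b = pk(5L, 3)),
                              list(a = b1, b = b2),
                              feature_prevalence = 1.0,
                              tic_normalize = FALSE)
  expect_equal(ncol(fm0$values), 0L)

  bad <- as_binned(c(0, 1, 2))
  expect_error(build_feature_matrix(list(a = pk(2L, 5), b = pk(2L, 4)),
                                    list(a = b1, b = bad)),
               "grids")
})

test_that("TIC normalization rescales rows by total corrected signal", {
  pk <- function(bins, hts) data.frame(bin = bins, mz = bins - 0.5,
                                       height = hts)
  b1 <- as_binned(c(0, 10, 0, 10, 0))    # TIC 20
  b2 <- as_binned(c(0, 5, 0, 5, 0))      # TIC 10
  fm <- build_feature_matrix(list(a = pk(c(2L, 4L), c(10, 10)),
                                  b = pk(c(2L, 4L), c(5, 5))),
                             list(a = b1, b = b2),
                             feature_prevalence = 0.5,
                             tic_normalize = TRUE)
  # median TIC = 15: row a scaled by 15/20, row b by 15/10 -> equal rows
  expect_equal(fm$values["a", ], fm$values["b", ])
  expect_equal(fm$tic, c(20, 10))
})

test_that("the preprocessing chain is bit-deterministic", {
  coh <- tiny_cohort(seed = 31)
  cfg <- desk_preprocess_config()
  sp <- synthesize_spectrum("S0002", coh$truth)
  a <- preprocess_spectrum(sp, cfg)
  b <- preprocess_spectrum(sp, cfg)
  expect_identical(a$binned$intensity, b$binned$intensity)
  expect_identical(a$peaks, b$peaks)
})

test_that("cohort-level features stay close to the planted panel", {
  # thinned panel: desk bins are coarse, so a crowded panel would merge
  # many adduct copies into shared local maxima
  cfg <- desk_cohort_config(n_hc = 4, n_lbd = 0, n_luad = 4,
                            n_peaks = 120, n_discriminative = 20,
                            seed = 17)
  coh <- generate_cohort(cfg)
  fm <- preprocess_cohort(coh$records, coh$truth, desk_preprocess_config())
  planted <- c(coh$truth$peak_mz,
               coh$truth$peak_mz + 21.9819,
               coh$truth$peak_mz + 37.9559)
  n_planted_bins <- length(unique(floor((planted - 100) / 0.2)))
  expect_gte(ncol(fm$values), 0.5 * n_planted_bins)
  expect_lte(ncol(fm$values), 2.0 * n_planted_bins)
  expect_true(all(fm$values >= 0))
})
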