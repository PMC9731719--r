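# Synthetic cohort generation: raw LDI-MS spectra with planted peaks and
# Na+/K+ adduct copies, plus subject metadata (diagnosis, stage, CEA,
# nodule descriptors, image-AI score, clinical covariates) with known ground
# truth, so every downstream stage is testable without patient data.

STAGES <- c("0", "I", "II", "III", "IV")

#' Configuration for the synthetic serum-fingerprint cohort
#'
#' Describes one simulated study: class sizes (healthy controls HC, lung
#' benign disease LBD, lung adenocarcinoma LUAD), the raw m/z grid, the
#' planted peak panel, the class signal carried by discriminative peaks, the
#' cation-adduct structure, baseline/noise, and the clinical covariate
#' distributions (CEA in ng/mL, image-AI score in [0,1], Mayo/VA covariates).
#'
#' Scale defaults mirror a realistic LDI-MS acquisition: ~125,000 raw points
#' over 100-1000 Da, ~300 resolvable metabolite peaks per serum sample of
#' which 40 carry disease signal, and Na+/K+ adducts at +21.9819/+37.9559 Da.
#' LUAD discriminative fold-changes grow with stage as
#' `1 + stage_gain * stage_index` (stage 0 -> index 0, ..., IV -> 4).
#'
#' @param n_hc,n_lbd,n_luad class sizes (non-negative integers).
#' @param stage_mix named proportions over stages 0,I,II,III,IV (sums to 1);
#'   applies to LUAD subjects only.
#' @param mass_range m/z window in Da, ascending length-2 vector.
#' @param n_points raw grid size (uniform in m/z; a documented
#'   simplification of time-uniform TOF grids).
#' @param n_peaks planted base peaks per sample (adduct copies are extra).
#' @param n_discriminative peaks carrying class signal (<= n_peaks).
#' @param effect_size mean |log2 fold-change| of discriminative peaks in
#'   LUAD versus controls at stage index 0.
#' @param prop_up fraction of discriminative peaks elevated (vs depressed)
#'   in LUAD.
#' @param stage_gain per-stage multiplicative gain on the fold-change.
#' @param peak_sigma Gaussian peak width (sd) in Da.
#' @param adduct_offsets named Da offsets of cation adduct copies.
#' @param adduct_ratio intensity of each adduct copy relative to its base.
#' @param peak_height_meanlog2,peak_height_sdlog2 log2-normal panel of base
#'   apex heights (arbitrary counts).
#' @param subject_sdlog2 per-subject biological/technical sd of log2 height.
#' @param baseline_amplitude,baseline_decay smooth baseline
#'   `A * exp(-(mz - low)/decay)` (counts, Da).
#' @param noise_sd additive Gaussian noise sd (counts).
#' @param cea_params per-class log-normal (meanlog, sdlog) of CEA; defaults
#'   give roughly 20% sensitivity at the clinical 5 ng/mL cutoff with ~95%
#'   specificity.
#' @param image_ai_params Beta(shape1, shape2) of the image-AI malignancy
#'   score for benign and malignant nodules.
#' @param covariate_signal if FALSE, the clinical covariates (age, smoking,
#'   nodule diameter, spiculation, lobe) are drawn from one shared
#'   distribution regardless of class, so the Mayo/VA models carry no
#'   signal; used for null-calibration worlds together with zero
#'   `effect_size` and class-identical `cea_params`/`image_ai_params`.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return a validated `cohort_config` list.
#' @export
#' @examples
#' cfg <- cohort_config(n_hc = 5, n_lbd = 2, n_luad = 5, n_points = 2000)
#' cohort <- generate_cohort(cfg)
#' nrow(cohort$records)
cohort_config <- function(n_hc = 150, n_lbd = 50, n_luad = 200,
                          stage_mix = c("0" = 0.10, I = 0.35, II = 0.27,
                                        III = 0.18, IV = 0.10),
                          mass_range = c(100, 1000),
                          n_points = 125000L,
                          n_peaks = 300L,
                          n_discriminative = 40L,
                          effect_size = 1.0,
                          prop_up = 0.5,
                          stage_gain = 0.15,
                          peak_sigma = 0.08,
                          adduct_offsets = c(Na = 21.9819, K = 37.9559),
                          adduct_ratio = c(Na = 0.5, K = 0.3),
                          peak_height_meanlog2 = 8,
                          peak_height_sdlog2 = 1.2,
                          subject_sdlog2 = 1.0,
                          baseline_amplitude = 200,
                          baseline_decay = 150,
                          noise_sd = 5,
                          cea_params = list(
                            hc   = c(meanlog = log(1.8), sdlog = 0.55),
                            lbd  = c(meanlog = log(2.0), sdlog = 0.60),
                            luad = c(meanlog = log(2.6), sdlog = 0.80)),
                          image_ai_params = list(
                            benign    = c(3, 8),
                            malignant = c(8, 3)),
                          covariate_signal = TRUE,
                          seed = 1L) {
  check_flag(covariate_signal, "covariate_signal")
  n_hc <- check_count(n_hc, "n_hc")
  n_lbd <- check_count(n_lbd, "n_lbd")
  n_luad <- check_count(n_luad, "n_luad")
  if (length(stage_mix) != 5L || is.null(names(stage_mix)) ||
      !identical(names(stage_mix), STAGES)) {
    stop_input("`stage_mix` must be named proportions over %s",
               paste(STAGES, collapse = ","))
  }
  if (any(stage_mix < 0) || abs(sum(stage_mix) - 1) > 1e-12) {
    stop_input("`stage_mix` must be non-negative and sum to 1 (got %.15f)",
               sum(stage_mix))
  }
  if (length(mass_range) != 2L || !all(is.finite(mass_range)) ||
      mass_range[1] >= mass_range[2]) {
    stop_input("`mass_range` must be an ascending pair of Da values")
  }
  n_points <- check_count(n_points, "n_points", lower = 10)
  n_peaks <- check_count(n_peaks, "n_peaks", lower = 1)
  n_discriminative <- check_count(n_discriminative, "n_discriminative")
  if (n_discriminative > n_peaks) {
    stop_input("`n_discriminative` (%d) exceeds `n_peaks` (%d)",
               n_discriminative, n_peaks)
  }
  check_number(effect_size, "effect_size", lower = 0)
  check_number(prop_up, "prop_up", lower = 0, upper = 1)
  check_number(stage_gain, "stage_gain", lower = 0)
  check_number(peak_sigma, "peak_sigma", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(baseline_amplitude, "baseline_amplitude", lower = 0)
  check_number(baseline_decay, "baseline_decay", lower = 0,
               strict_lower = TRUE)
  stopifnot(length(adduct_offsets) == length(adduct_ratio))
  cfg <- list(
    n_hc = n_hc, n_lbd = n_lbd, n_luad = n_luad,
    stage_mix = stage_mix, mass_range = as.double(mass_range),
    n_points = n_points, n_peaks = n_peaks,
    n_discriminative = n_discriminative,
    effect_size = effect_size, prop_up = prop_up, stage_gain = stage_gain,
    peak_sigma = peak_sigma,
    adduct_offsets = adduct_offsets, adduct_ratio = adduct_ratio,
    peak_height_meanlog2 = peak_height_meanlog2,
    peak_height_sdlog2 = peak_height_sdlog2,
    subject_sdlog2 = subject_sdlog2,
    baseline_amplitude = baseline_amplitude,
    baseline_decay = baseline_decay,
    noise_sd = noise_sd,
    cea_params = cea_params,
    image_ai_params = image_ai_params,
    covariate_signal = covariate_signal,
    seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

stage_index <- function(stage) {
  ifelse(stage %in% STAGES, match(stage, STAGES) - 1L, NA_integer_)
}

# Draw n sorted peak centers with a minimum spacing, by greedy thinning of an
# oversampled uniform draw (keeps the panel resolvable at the planted width).
draw_peak_centers <- function(n, lo, hi, min_gap) {
  if (n == 1L) return(stats::runif(1, lo, hi))
  for (attempt in 1:10) {
    cand <- sort(stats::runif((6L + 2L * attempt) * n, lo, hi))
    keep <- numeric(0)
    last <- -Inf
    for (x in cand) {
      if (x - last >= min_gap) {
        keep <- c(keep, x)
        last <- x
        if (length(keep) == n) break
      }
    }
    if (length(keep) == n) return(keep)
  }
  # dense panel: fall back to systematic placement with bounded jitter
  spacing <- (hi - lo) / (n - 1)
  if (spacing < min_gap) {
    stop_input("cannot place %d peaks with %.2f Da spacing in [%g, %g]",
               n, min_gap, lo, hi)
  }
  jit <- (spacing - min_gap) / 2
  sort(seq(lo, hi, length.out = n) +
         stats::runif(n, -jit, jit))
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws the shared planted-peak panel, per-subject peak heights (log2-normal
#' around per-class means, with LUAD discriminative peaks shifted by a
#' stage-scaled fold-change), CEA, nodule descriptors and clinical
#' covariates. LBD subjects carry benign nodules, LUAD subjects malignant
#' nodules, HC none; the image-AI score is defined only on the nodule subset.
#'
#' @param config a [cohort_config()].
#' @return list with `records` (one row per subject: subject_id,
#'   cohort_label, stage, cea, nodule/covariate columns, image_ai_score) and
#'   `truth` (peak panel m/z, discriminative indices/signs/fold-changes,
#'   per-class mean log2 heights, the per-subject log2 height table, and a
#'   config echo). The truth object is the immutable generating record.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop_input("`config` must come from cohort_config()")
  }
  n <- config$n_hc + config$n_lbd + config$n_luad
  if (n == 0L) stop_input("cohort is empty: all class counts are zero")
  with_seed(config$seed, {
    max_off <- max(config$adduct_offsets)
    centers <- draw_peak_centers(
      config$n_peaks,
      config$mass_range[1] + 5,
      config$mass_range[2] - max_off - 5,
      min_gap = max(1.2, 6 * config$peak_sigma))
    mu <- stats::rnorm(config$n_peaks, config$peak_height_meanlog2,
                       config$peak_height_sdlog2)
    disc_idx <- sort(sample.int(config$n_peaks, config$n_discriminative))
    disc_sign <- ifelse(
      stats::runif(config$n_discriminative) < config$prop_up, 1, -1)
    disc_lfc <- if (config$effect_size > 0) {
      abs(stats::rnorm(config$n_discriminative, config$effect_size,
                       0.25 * config$effect_size))
    } else {
      rep(0, config$n_discriminative)
    }
    delta <- numeric(config$n_peaks)
    delta[disc_idx] <- disc_sign * disc_lfc

    label <- factor(
      rep(c("HC", "LBD", "LUAD"), c(config$n_hc, config$n_lbd, config$n_luad)),
      levels = c("HC", "LBD", "LUAD"))
    stage <- rep("none", n)
    if (config$n_luad > 0) {
      stage[label == "LUAD"] <- sample(STAGES, config$n_luad, replace = TRUE,
                                       prob = config$stage_mix)
    }
    sidx <- stage_index(stage)
    stage_factor <- ifelse(is.na(sidx), 0, 1 + config$stage_gain * sidx)
    is_luad <- label == "LUAD"

    # log2 apex height of base peak j for subject i
    H <- matrix(mu, n, config$n_peaks, byrow = TRUE)
    H <- H + outer(ifelse(is_luad, stage_factor, 0), delta) +
      matrix(stats::rnorm(n * config$n_peaks, 0, config$subject_sdlog2),
             n, config$n_peaks)

    cea_key <- c(HC = "hc", LBD = "lbd", LUAD = "luad")[as.character(label)]
    cea <- vapply(cea_key, function(k) {
      p <- config$cea_params[[k]]
      stats::rlnorm(1, p[["meanlog"]], p[["sdlog"]])
    }, numeric(1), USE.NAMES = FALSE)

    nodule_present <- label %in% c("LBD", "LUAD")
    malignant <- ifelse(nodule_present, label == "LUAD", NA)
    cov_mal <- if (config$covariate_signal) is_luad else rep(FALSE, n)
    diameter <- rep(NA_real_, n)
    diameter[nodule_present & !cov_mal] <-
      pmin(30, pmax(2, stats::rlnorm(sum(nodule_present & !cov_mal),
                                     log(9), 0.50)))
    diameter[nodule_present & cov_mal] <-
      pmin(30, pmax(4, stats::rlnorm(sum(nodule_present & cov_mal),
                                     log(13), 0.45)))
    nodule_type <- rep(NA_character_, n)
    nodule_type[nodule_present] <- sample(
      c("solid", "part-solid", "pure GGN"), sum(nodule_present),
      replace = TRUE, prob = c(0.55, 0.25, 0.20))

    image_ai <- rep(NA_real_, n)
    ben <- which(nodule_present & !is_luad)
    mal <- which(nodule_present & is_luad)
    image_ai[ben] <- stats::rbeta(length(ben),
                                  config$image_ai_params$benign[1],
                                  config$image_ai_params$benign[2])
    image_ai[mal] <- stats::rbeta(length(mal),
                                  config$image_ai_params$malignant[1],
                                  config$image_ai_params$malignant[2])

    if (config$covariate_signal) {
      age_mean <- c(HC = 52, LBD = 56, LUAD = 63)[as.character(label)]
      age_sd <- c(HC = 12, LBD = 11, LUAD = 9)[as.character(label)]
    } else {
      age_mean <- rep(55, n)
      age_sd <- rep(11, n)
    }
    age <- round(pmin(88, pmax(25, stats::rnorm(n, age_mean, age_sd))))
    smoker <- stats::runif(n) < ifelse(cov_mal, 0.45, 0.35)
    current <- stats::runif(n) < 0.6
    years_quit <- ifelse(smoker & !current, round(stats::runif(n, 1, 20)), 0)
    cancer_hx <- stats::runif(n) < 0.04
    spic <- stats::runif(n) < ifelse(nodule_present,
                                     ifelse(cov_mal, 0.40, 0.10), 0)
    upper <- stats::runif(n) < ifelse(nodule_present,
                                      ifelse(cov_mal, 0.60, 0.45), 0.5)

    records <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      cohort_label = label,
      stage = stage,
      cea = cea,
      nodule_present = nodule_present,
      nodule_diameter = diameter,
      nodule_type = nodule_type,
      malignant = malignant,
      image_ai_score = image_ai,
      age = age,
      smoker_ever = smoker,
      years_quit = years_quit,
      extrathoracic_cancer_gt5y = cancer_hx,
      spiculation = spic,
      upper_lobe = upper,
      stringsAsFactors = FALSE)
    rownames(H) <- records$subject_id

    class_mean_log2 <- cbind(
      control = mu[disc_idx],
      luad = mu[disc_idx] + disc_sign * disc_lfc)
    truth <- list(
      peak_mz = centers,
      peak_meanlog2 = mu,
      disc_idx = disc_idx,
      disc_mz = centers[disc_idx],
      disc_sign = disc_sign,
      disc_lfc = disc_lfc,
      class_mean_log2 = class_mean_log2,
      heights_log2 = H,
      config = config)
    class(truth) <- "cohort_truth"
    list(records = records, truth = truth)
  })
}

#' Render one subject's raw spectrum
#'
#' Places each planted base peak as a narrow Gaussian bump at its panel m/z
#' with the subject's true apex height, adds the Na+/K+ adduct copies at
#' fixed offsets and relative intensities, a smooth exponentially decaying
#' baseline, and additive Gaussian noise; intensities are clipped at zero.
#'
#' @param subject a subject_id present in `truth`, or a single records row.
#' @param truth the `truth` component of [generate_cohort()].
#' @param seed integer seed for the noise stream; defaults to a child seed
#'   derived from the cohort seed and the subject index.
#' @return a `raw_spectrum` (fields `mz`, `intensity`, `subject_id`).
#' @export
synthesize_spectrum <- function(subject, truth, seed = NULL) {
  if (!inherits(truth, "cohort_truth")) {
    stop_input("`truth` must come from generate_cohort()")
  }
  id <- if (is.data.frame(subject)) subject$subject_id[1] else subject
  i <- match(id, rownames(truth$heights_log2))
  if (is.na(i)) stop_input("unknown subject `%s`", id)
  cfg <- truth$config
  if (is.null(seed)) seed <- child_seed(cfg$seed, i)
  mz <- seq(cfg$mass_range[1], cfg$mass_range[2], length.out = cfg$n_points)
  step <- mz[2] - mz[1]
  intensity <- cfg$baseline_amplitude *
    exp(-(mz - cfg$mass_range[1]) / cfg$baseline_decay)

  heights <- 2^truth$heights_log2[i, ]
  centers <- c(truth$peak_mz,
               unlist(lapply(cfg$adduct_offsets, function(o) truth$peak_mz + o),
                      use.names = FALSE))
  amps <- c(heights,
            unlist(lapply(cfg$adduct_ratio, function(r) heights * r),
                   use.names = FALSE))
  # render all Gaussian bumps at once: one index matrix of the +/- 4 sigma
  # windows, accumulated with rowsum (windows of different peaks may overlap)
  r <- as.integer(ceiling(4 * cfg$peak_sigma / step)) + 1L
  base_idx <- round((centers - cfg$mass_range[1]) / step) + 1
  idx <- outer((-r):r, base_idx, "+")
  ok <- idx >= 1L & idx <= cfg$n_points
  mzv <- cfg$mass_range[1] + (idx - 1) * step
  vals <- matrix(amps, 2L * r + 1L, length(centers), byrow = TRUE) *
    exp(-sweep(mzv, 2L, centers)^2 / (2 * cfg$peak_sigma^2))
  ivec <- idx[ok]
  acc <- rowsum(vals[ok], ivec, reorder = FALSE)
  ii <- ivec[!duplicated(ivec)]     # rowsum group order, kept as integers
  intensity[ii] <- intensity[ii] + acc[, 1]
  if (cfg$noise_sd > 0) {
    intensity <- with_seed(seed, {
      intensity + stats::rnorm(cfg$n_points, 0, cfg$noise_sd)
    })
  }
  raw_spectrum(mz, pmax(intensity, 0), subject_id = id)
}

#' Stratified train/test split of a cohort
#'
#' Randomly assigns subjects to training and test sets so that every stratum
#' is split within one subject of `train_fraction` (the study convention is
#' 8:2). Strata with fewer than 2 subjects are kept whole in training, with
#' a warning.
#'
#' @param records data frame with `subject_id` and the stratification columns.
#' @param train_fraction fraction assigned to training, in (0, 1).
#' @param stratify_on character vector of column names to stratify on.
#' @param seed integer seed.
#' @return list with `train` and `test` character vectors of subject ids
#'   (disjoint, exhaustive).
#' @export
split_cohort <- function(records, train_fraction = 0.8,
                         stratify_on = "cohort_label", seed = 1L) {
  check_number(train_fraction, "train_fraction", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  missing_cols <- setdiff(stratify_on, names(records))
  if (length(missing_cols)) {
    stop_input("stratification column(s) not found: %s",
               paste(missing_cols, collapse = ", "))
  }
  strat <- interaction(records[stratify_on], drop = TRUE)
  train <- character(0)
  with_seed(seed, {
    for (s in levels(strat)) {
      ids <- records$subject_id[strat == s]
      if (length(ids) < 2L) {
        warning(sprintf("stratum `%s` has %d subject(s); kept in training",
                        s, length(ids)), call. = FALSE)
        train <- c(train, ids)
        next
      }
      n_tr <- round(train_fraction * length(ids))
      n_tr <- min(max(n_tr, 1L), length(ids) - 1L)
      train <- c(train, sample(ids, n_tr))
    }
  })
  list(train = sort(train),
       test = sort(setdiff(records$subject_id, train)))
}
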