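# Spectrum preprocessing: raw spectrum -> smoothed -> binned -> white
# top-hat baseline corrected -> peak list -> aligned feature matrix (the
# serum metabolic fingerprint, SMF).

#' Construct a raw spectrum
#'
#' @param mz strictly ascending m/z vector (Da).
#' @param intensity non-negative intensities, same length.
#' @param subject_id optional sample identifier.
#' @return object of class `raw_spectrum`.
#' @export
raw_spectrum <- function(mz, intensity, subject_id = NA_character_) {
  if (length(mz) != length(intensity)) {
    stop_input("mz and intensity differ in length (%d vs %d)",
               length(mz), length(intensity))
  }
  if (length(mz) && any(diff(mz) <= 0)) {
    stop_input("mz must be strictly ascending")
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop_input("intensities must be finite and non-negative")
  }
  structure(list(mz = as.double(mz), intensity = as.double(intensity),
                 subject_id = subject_id),
            class = "raw_spectrum")
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf("<raw_spectrum> %s: %d points, m/z %.2f-%.2f Da\n",
              x$subject_id, length(x$mz), min(x$mz), max(x$mz)))
  invisible(x)
}

#' Preprocessing configuration
#'
#' Parameters of the four-step chain. `gaussian_sigma` is in raw-grid index
#' units (the scipy `gaussian_filter1d` convention); binning uses half-open
#' bins `[anchor + k*w, anchor + (k+1)*w)` whose value is the maximum raw
#' intensity in the bin; the top-hat structuring element is a flat segment of
#' `tophat_width` bins; peaks are strict local maxima over +/- `peak_window`
#' bins exceeding `snr_threshold` times a MAD-based noise scale.
#'
#' @param gaussian_sigma smoothing scale, raw-grid index units.
#' @param bin_width bin width in Da.
#' @param bin_anchor lower edge of bin 0, Da.
#' @param mass_range retained m/z window, Da.
#' @param tophat_width structuring element width in bins (odd, >= 3).
#' @param peak_window local-maxima half-width in bins.
#' @param snr_threshold minimum peak height in noise-SD units.
#' @param feature_prevalence minimum fraction of samples whose peak lists
#'   must hit a bin for it to become a feature.
#' @param tic_normalize divide each sample by its total ion count, then
#'   rescale by the cohort median TIC.
#' @param bin_agg `"max"` (default; preserves apex heights) or `"sum"`.
#' @return a validated `preprocess_config` list.
#' @export
preprocess_config <- function(gaussian_sigma = 1,
                              bin_width = 0.05,
                              bin_anchor = 100.0,
                              mass_range = c(100, 1000),
                              tophat_width = 201L,
                              peak_window = 5L,
                              snr_threshold = 3,
                              feature_prevalence = 0.05,
                              tic_normalize = TRUE,
                              bin_agg = c("max", "sum")) {
  check_number(gaussian_sigma, "gaussian_sigma", lower = 0,
               strict_lower = TRUE)
  check_number(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  tophat_width <- check_count(tophat_width, "tophat_width", lower = 3)
  if (tophat_width %% 2L == 0L) stop_input("`tophat_width` must be odd")
  peak_window <- check_count(peak_window, "peak_window", lower = 1)
  check_number(snr_threshold, "snr_threshold", lower = 0)
  check_number(feature_prevalence, "feature_prevalence", lower = 0, upper = 1)
  check_flag(tic_normalize, "tic_normalize")
  structure(list(gaussian_sigma = gaussian_sigma, bin_width = bin_width,
                 bin_anchor = bin_anchor, mass_range = as.double(mass_range),
                 tophat_width = tophat_width, peak_window = peak_window,
                 snr_threshold = snr_threshold,
                 feature_prevalence = feature_prevalence,
                 tic_normalize = tic_normalize,
                 bin_agg = match.arg(bin_agg)),
            class = "preprocess_config")
}

#' Gaussian smoothing of a raw spectrum
#'
#' Discrete Gaussian convolution with the kernel truncated at radius
#' `ceiling(4*sigma)` and renormalised to sum one; reflect boundary. Total
#' signal mass is preserved away from the boundary.
#'
#' @param spectrum a [raw_spectrum()].
#' @param sigma kernel scale in grid-index units (> 0).
#' @return smoothed `raw_spectrum` on the same grid.
#' @export
smooth_spectrum <- function(spectrum, sigma = 1) {
  check_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  r <- as.integer(ceiling(4 * sigma))
  kern <- stats::dnorm(-r:r, sd = sigma)
  kern <- kern / sum(kern)
  xp <- reflect_pad(spectrum$intensity, r)
  sm <- stats::filter(xp, kern, sides = 2)
  out <- as.double(sm[(r + 1L):(r + length(spectrum$intensity))])
  raw_spectrum(spectrum$mz, pmax(out, 0), spectrum$subject_id)
}

#' Down-sample a spectrum onto fixed-width m/z bins
#'
#' Half-open bins `[anchor + k*w, anchor + (k+1)*w)` covering `mass_range`;
#' each bin takes the maximum (or sum) of the raw intensities falling in it,
#' empty bins are zero. Bin count is `ceiling(span / w)`.
#'
#' @param spectrum a [raw_spectrum()].
#' @param bin_width bin width in Da.
#' @param bin_anchor lower edge of the first bin, Da.
#' @param mass_range retained window, Da.
#' @param agg `"max"` or `"sum"`.
#' @return a `binned_spectrum` (fields `bin_lower_edges`, `intensity`,
#'   `bin_width`, `subject_id`).
#' @export
bin_spectrum <- function(spectrum, bin_width = 0.05, bin_anchor = 100.0,
                         mass_range = c(100, 1000),
                         agg = c("max", "sum")) {
  agg <- match.arg(agg)
  check_number(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  keep <- spectrum$mz >= mass_range[1] & spectrum$mz <= mass_range[2]
  if (!any(keep)) stop_input("spectrum is empty within mass_range")
  mz <- spectrum$mz[keep]
  y <- spectrum$intensity[keep]
  span <- mass_range[2] - bin_anchor
  n_bins <- as.integer(ceiling(span / bin_width - 1e-9))
  idx <- floor((mz - bin_anchor) / bin_width + 1e-9)
  ok <- idx >= 0 & idx < n_bins
  idx <- as.integer(idx[ok])
  y <- y[ok]
  out <- numeric(n_bins)
  if (agg == "max") {
    # max per occupied bin: order by (bin, intensity); each bin's last
    # element after ordering is its maximum
    ord <- order(idx, y, method = "radix")
    gi <- idx[ord]
    yi <- y[ord]
    ends <- c(which(diff(gi) != 0L), length(gi))
    out[gi[ends] + 1L] <- yi[ends]
  } else {
    s <- rowsum(y, idx)
    out[as.integer(rownames(s)) + 1L] <- s[, 1]
  }
  structure(list(bin_lower_edges = bin_anchor + bin_width * (0:(n_bins - 1L)),
                 intensity = out, bin_width = bin_width,
                 subject_id = spectrum$subject_id),
            class = "binned_spectrum")
}

#' White top-hat baseline correction
#'
#' Subtracts the morphological opening (erosion followed by dilation with a
#' flat structuring element of `tophat_width` bins, reflect boundary) from
#' the binned spectrum. Broad baseline structures wider than the element are
#' removed entirely; narrow peaks pass through. The result is non-negative.
#'
#' @param binned a `binned_spectrum`.
#' @param tophat_width element width in bins (odd, >= 3).
#' @return baseline-corrected `binned_spectrum`.
#' @export
tophat_baseline <- function(binned, tophat_width = 201L) {
  tophat_width <- check_count(tophat_width, "tophat_width", lower = 3)
  if (tophat_width %% 2L == 0L) stop_input("`tophat_width` must be odd")
  r <- (tophat_width - 1L) %/% 2L
  opened <- running_extreme(running_extreme(binned$intensity, r, "min"),
                            r, "max")
  out <- binned
  out$intensity <- pmax(binned$intensity - opened, 0)
  out
}

#' Local-maxima peak detection
#'
#' Bin `i` is a peak iff its corrected intensity strictly exceeds every
#' other value within `+/- peak_window` bins (on a tie, the lower index is
#' kept) and exceeds `snr_threshold` times the noise scale, estimated as the
#' median absolute deviation of the corrected spectrum scaled to an SD
#' (constant 1.4826).
#'
#' @param corrected a baseline-corrected `binned_spectrum`.
#' @param peak_window half-width of the local-maxima window, bins.
#' @param snr_threshold minimum height in noise-SD units.
#' @return data frame with `bin` (1-based index), `mz` (bin center, Da) and
#'   `height` (> 0); zero rows when nothing qualifies.
#' @export
detect_peaks <- function(corrected, peak_window = 5L, snr_threshold = 3) {
  peak_window <- check_count(peak_window, "peak_window", lower = 1)
  check_number(snr_threshold, "snr_threshold", lower = 0)
  y <- corrected$intensity
  n <- length(y)
  noise <- stats::mad(y, constant = 1.4826)
  thr <- snr_threshold * noise
  rm_ <- running_extreme(y, peak_window, "max")
  cand <- which(y >= rm_ & y > thr & y > 0)
  keep <- logical(length(cand))
  last_bin <- -Inf
  last_val <- NA_real_
  for (k in seq_along(cand)) {
    i <- cand[k]
    w0 <- max(1L, i - peak_window)
    w1 <- min(n, i + peak_window)
    win <- y[w0:w1]
    ties <- sum(win == y[i])
    if (ties > 1L) {
      # plateau/tie: keep only the lowest index among the tied candidates
      if (i - last_bin <= peak_window && isTRUE(last_val == y[i])) next
    }
    keep[k] <- TRUE
    last_bin <- i
    last_val <- y[i]
  }
  idx <- cand[keep]
  data.frame(bin = idx,
             mz = corrected$bin_lower_edges[idx] + corrected$bin_width / 2,
             height = y[idx])
}

#' Assemble the aligned feature matrix (SMF)
#'
#' Features are the bins in which at least `feature_prevalence` of the
#' subjects host a detected peak. A subject's value in a feature bin is its
#' baseline-corrected intensity there if it has a peak in that bin, else 0.
#' With `tic_normalize`, each row is divided by the subject's total ion
#' count (sum of its corrected intensities) and rescaled by the cohort
#' median TIC.
#'
#' @param peaklists named list (by subject) of [detect_peaks()] results.
#' @param binned_spectra named list of corrected `binned_spectrum` objects
#'   on a shared bin grid.
#' @param feature_prevalence minimum hosting fraction in [0, 1].
#' @param tic_normalize flag.
#' @param feature_bins optional fixed bin indices (e.g. selected on the
#'   training split); overrides prevalence-based selection.
#' @param tic_reference optional reference TIC (e.g. the training-cohort
#'   median) used for rescaling instead of this cohort's own median.
#' @return a `feature_matrix`: list with `values` (subjects x features),
#'   `feature_mz` (bin centers, Da), `feature_bins`, `subject_ids`, `tic`.
#' @export
build_feature_matrix <- function(peaklists, binned_spectra,
                                 feature_prevalence = 0.05,
                                 tic_normalize = TRUE,
                                 feature_bins = NULL,
                                 tic_reference = NULL) {
  check_number(feature_prevalence, "feature_prevalence", lower = 0, upper = 1)
  ids <- names(peaklists)
  if (is.null(ids) || !identical(ids, names(binned_spectra))) {
    stop_input("peaklists and binned_spectra must be named identically")
  }
  edges <- binned_spectra[[1]]$bin_lower_edges
  w <- binned_spectra[[1]]$bin_width
  for (b in binned_spectra) {
    if (length(b$bin_lower_edges) != length(edges) ||
        abs(b$bin_lower_edges[1] - edges[1]) > 1e-9 ||
        abs(b$bin_width - w) > 1e-12) {
      stop_input("subjects are on different bin grids; align them first")
    }
  }
  n <- length(ids)
  n_bins <- length(edges)
  if (is.null(feature_bins)) {
    hits <- integer(n_bins)
    for (pl in peaklists) hits[pl$bin] <- hits[pl$bin] + 1L
    need <- max(1L, as.integer(ceiling(feature_prevalence * n - 1e-9)))
    fbins <- which(hits >= need)
  } else {
    fbins <- as.integer(feature_bins)
  }
  vals <- matrix(0, n, length(fbins),
                 dimnames = list(ids, sprintf("%.4f", edges[fbins] + w / 2)))
  tic <- numeric(n)
  for (i in seq_len(n)) {
    tic[i] <- sum(binned_spectra[[i]]$intensity)
    pl <- peaklists[[i]]
    m <- match(pl$bin, fbins)
    ok <- !is.na(m)
    vals[i, m[ok]] <- binned_spectra[[i]]$intensity[pl$bin[ok]]
  }
  if (tic_normalize && n > 0) {
    med <- tic_reference %||% stats::median(tic[tic > 0])
    scl <- ifelse(tic > 0, med / tic, 1)
    vals <- vals * scl
  }
  structure(list(values = vals, feature_mz = edges[fbins] + w / 2,
                 feature_bins = fbins, subject_ids = ids, tic = tic),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d subjects x %d features (m/z %.2f-%.2f)\n",
              nrow(x$values), ncol(x$values),
              if (length(x$feature_mz)) min(x$feature_mz) else NA,
              if (length(x$feature_mz)) max(x$feature_mz) else NA))
  invisible(x)
}

#' Run the full preprocessing chain on one spectrum
#'
#' smooth -> bin -> top-hat -> peak detection, under one
#' [preprocess_config()].
#'
#' @param spectrum a [raw_spectrum()].
#' @param config a [preprocess_config()].
#' @return list with `binned` (corrected `binned_spectrum`) and `peaks`.
#' @export
preprocess_spectrum <- function(spectrum, config = preprocess_config()) {
  sm <- smooth_spectrum(spectrum, config$gaussian_sigma)
  bn <- bin_spectrum(sm, config$bin_width, config$bin_anchor,
                     config$mass_range, agg = config$bin_agg)
  ct <- tophat_baseline(bn, config$tophat_width)
  pk <- detect_peaks(ct, config$peak_window, config$snr_threshold)
  list(binned = ct, peaks = pk)
}

#' Preprocess a whole synthetic cohort into a feature matrix
#'
#' Synthesizes each subject's raw spectrum from the ground truth, runs the
#' preprocessing chain, and assembles the aligned feature matrix. Raw
#' spectra are discarded as soon as each subject is processed, so memory
#' stays flat in cohort size.
#'
#' @param records,truth output of [generate_cohort()].
#' @param config a [preprocess_config()].
#' @param subjects optional subset of subject ids.
#' @return a `feature_matrix`.
#' @export
preprocess_cohort <- function(records, truth,
                              config = preprocess_config(),
                              subjects = NULL) {
  ids <- subjects %||% records$subject_id
  peaklists <- vector("list", length(ids))
  binned <- vector("list", length(ids))
  names(peaklists) <- names(binned) <- ids
  for (id in ids) {
    sp <- synthesize_spectrum(id, truth)
    pp <- preprocess_spectrum(sp, config)
    peaklists[[id]] <- pp$peaks
    binned[[id]] <- pp$binned
  }
  build_feature_matrix(peaklists, binned,
                       feature_prevalence = config$feature_prevalence,
                       tic_normalize = config$tic_normalize)
}
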