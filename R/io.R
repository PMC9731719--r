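# Formats: two-column CSV and minimal mzML spectra (64-bit float, no
# compression), feature-matrix CSV with a JSON sidecar, and JSON model
# checkpoints.

#' Read a raw spectrum from CSV or mzML
#'
#' CSV must have two numeric columns (m/z in Da, intensity in counts) with a
#' header. mzML support covers uncompressed 64-bit float arrays of the
#' first MS1 spectrum. Unsorted m/z values are sorted with a warning;
#' negative intensities are an error.
#'
#' @param path file path.
#' @param format "auto" (by extension), "csv" or "mzml".
#' @return a [raw_spectrum()].
#' @export
read_spectrum <- function(path, format = c("auto", "csv", "mzml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else
      "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path)
    if (ncol(df) < 2L) {
      stop_input("%s: expected two columns (mz, intensity)", path)
    }
    mz <- as.double(df[[1]])
    intensity <- as.double(df[[2]])
  } else {
    arr <- read_mzml_arrays(path)
    mz <- arr$mz
    intensity <- arr$intensity
  }
  if (any(!is.finite(mz)) || any(!is.finite(intensity))) {
    stop_input("%s: non-finite values", path)
  }
  if (any(intensity < 0)) {
    stop_input("%s: negative intensity at record %d", path,
               which(intensity < 0)[1])
  }
  if (is.unsorted(mz, strictly = TRUE)) {
    warning(sprintf("%s: m/z not strictly ascending; sorting", path),
            call. = FALSE)
    ord <- order(mz)
    mz <- mz[ord]
    intensity <- intensity[ord]
    keep <- !duplicated(mz)
    mz <- mz[keep]
    intensity <- intensity[keep]
  }
  raw_spectrum(mz, intensity,
               subject_id = sub("\\.[^.]+$", "", basename(path)))
}

#' Write a raw spectrum to CSV or mzML
#'
#' @param spectrum a [raw_spectrum()].
#' @param path destination (.csv or .mzML).
#' @param format "auto", "csv" or "mzml".
#' @return the path, invisibly.
#' @export
write_spectrum <- function(spectrum, path, format = c("auto", "csv",
                                                      "mzml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else
      "csv"
  }
  if (format == "csv") {
    utils::write.csv(data.frame(mz = spectrum$mz,
                                intensity = spectrum$intensity),
                     path, row.names = FALSE)
  } else {
    write_mzml(spectrum, path)
  }
  invisible(path)
}

b64_doubles <- function(x) {
  jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8L,
                                endian = "little"))
}

write_mzml <- function(spectrum, path) {
  n <- length(spectrum$mz)
  arr <- function(data, accession, name) {
    enc <- b64_doubles(data)
    paste0(
      '      <binaryDataArray encodedLength="', nchar(enc), '">\n',
      '        <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
      '        <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>\n',
      '        <cvParam cvRef="MS" accession="', accession, '" name="', name,
      '"/>\n',
      '        <binary>', enc, '</binary>\n',
      '      </binaryDataArray>\n')
  }
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<run id="', spectrum$subject_id %||% "sample", '">\n',
    '  <spectrumList count="1">\n',
    '  <spectrum index="0" id="scan=1" defaultArrayLength="', n, '">\n',
    '    <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>\n',
    '    <binaryDataArrayList count="2">\n',
    arr(spectrum$mz, "MS:1000514", "m/z array"),
    arr(spectrum$intensity, "MS:1000515", "intensity array"),
    '    </binaryDataArrayList>\n',
    '  </spectrum>\n',
    '  </spectrumList>\n',
    '</run>\n</mzML>\n')
  writeLines(xml, path, sep = "")
  invisible(path)
}

read_mzml_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  spec <- xml2::xml_find_first(doc, ".//spectrum")
  if (is.na(xml2::xml_attr(spec, "index")) && !length(spec)) {
    stop_input("%s: no spectrum element found", path)
  }
  arrays <- xml2::xml_find_all(spec, ".//binaryDataArray")
  out <- list()
  for (a in arrays) {
    names_cv <- xml2::xml_attr(xml2::xml_find_all(a, ".//cvParam"), "name")
    if (any(grepl("zlib", names_cv))) {
      stop_input("%s: compressed mzML arrays are not supported", path)
    }
    raw64 <- jsonlite::base64_dec(xml2::xml_text(
      xml2::xml_find_first(a, ".//binary")))
    vals <- readBin(raw64, "double", n = length(raw64) %/% 8L, size = 8L,
                    endian = "little")
    if (any(grepl("^m/z array$", names_cv))) out$mz <- vals
    if (any(grepl("^intensity array$", names_cv))) out$intensity <- vals
  }
  if (is.null(out$mz) || is.null(out$intensity)) {
    stop_input("%s: missing m/z or intensity array", path)
  }
  out
}

#' Write a feature matrix as CSV with a JSON sidecar
#'
#' CSV layout: `subject_id` column then one column per feature, header =
#' feature m/z. The sidecar (`<path>.json`) records the feature list and
#' provenance.
#'
#' @param fm a `feature_matrix`.
#' @param path CSV destination.
#' @param config optional [preprocess_config()] echoed into the sidecar.
#' @return the path, invisibly.
#' @export
write_feature_matrix <- function(fm, path, config = NULL) {
  df <- data.frame(subject_id = fm$subject_ids, fm$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- list(feature_mz = fm$feature_mz,
                  feature_bins = fm$feature_bins,
                  n_subjects = length(fm$subject_ids),
                  config = if (!is.null(config)) unclass(config))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path the CSV path.
#' @return a `feature_matrix` (TIC field unavailable from disk).
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$subject_id
  structure(list(values = vals,
                 feature_mz = as.double(colnames(vals)),
                 feature_bins = NULL,
                 subject_ids = df$subject_id,
                 tic = NULL),
            class = "feature_matrix")
}

#' Save / load a neural model checkpoint (portable JSON)
#'
#' Stores weights, configuration and standardization statistics with full
#' numeric precision; a loaded model predicts identically.
#'
#' @param net a trained `smf_net`.
#' @param path destination (.json).
#' @return the path, invisibly.
#' @export
save_network <- function(net, path) {
  ser <- list(
    cfg = unclass(net$cfg),
    W_in = net$params$W_in, b_in = net$params$b_in,
    blocks = lapply(net$params$blocks, function(bl)
      list(W = bl$W, b = bl$b)),
    W_out = as.vector(net$params$W_out), b_out = net$params$b_out,
    W_f = if (!is.null(net$params$W_f)) as.vector(net$params$W_f),
    b_f = net$params$b_f,
    feat_mean = net$feat_mean, feat_sd = net$feat_sd,
    cea_mean = net$cea_mean, cea_sd = net$cea_sd,
    loss_trace = net$loss_trace, trained = net$trained)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(net_config, s$cfg[c("input_dim", "n_blocks", "hidden_units",
                                     "dropout_rate", "leaky_slope",
                                     "use_fusion", "cea_transform")])
  h <- cfg$hidden_units
  params <- list(
    W_in = matrix(s$W_in, cfg$input_dim, h), b_in = as.double(s$b_in),
    blocks = lapply(seq_len(cfg$n_blocks), function(k)
      list(W = matrix(s$blocks$W[[k]], h, h), b = as.double(s$blocks$b[[k]]))),
    W_out = matrix(s$W_out, h, 1L), b_out = s$b_out)
  if (cfg$use_fusion) {
    params$W_f <- matrix(s$W_f, 2L, 1L)
    params$b_f <- s$b_f
  }
  structure(list(cfg = cfg, params = params,
                 feat_mean = as.double(s$feat_mean),
                 feat_sd = as.double(s$feat_sd),
                 cea_mean = s$cea_mean, cea_sd = s$cea_sd,
                 loss_trace = as.double(s$loss_trace),
                 trained = isTRUE(s$trained)),
            class = "smf_net")
}

#' Save / load a fusion forest (portable JSON, explicit trees)
#'
#' @param model a `fusion_model`.
#' @param path destination (.json).
#' @return the path, invisibly.
#' @export
save_fusion_model <- function(model, path) {
  ser <- unclass(model)
  # JSON has no Inf: encode unbounded depth as -1
  if (is.infinite(ser$max_depth)) ser$max_depth <- -1
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname save_fusion_model
#' @export
load_fusion_model <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = FALSE)
  s$trees <- lapply(s$trees, function(tr) lapply(tr, function(nd) {
    list(feature = if (is.null(nd$feature)) NA_integer_ else
      as.integer(nd$feature),
      threshold = if (is.null(nd$threshold)) NA_real_ else
        as.double(nd$threshold),
      left = if (is.null(nd$left)) NA_integer_ else as.integer(nd$left),
      right = if (is.null(nd$right)) NA_integer_ else as.integer(nd$right),
      prob = as.double(nd$prob), n = as.integer(nd$n))
  }))
  s$n_features <- as.integer(s$n_features)
  s$max_depth <- as.double(s$max_depth)
  if (!is.na(s$max_depth) && s$max_depth < 0) s$max_depth <- Inf
  s$feature_names <- unlist(s$feature_names) %||% NULL
  class(s) <- "fusion_model"
  s
}
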