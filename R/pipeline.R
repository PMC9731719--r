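# End-to-end pipeline driver: simulate -> preprocess -> split -> train
# Met-NN / MP-NN -> clinical baselines -> MPI-RF fusion -> evaluation
# report. Every stage runs off one master seed.

#' Desk-scale cohort configuration
#'
#' A scaled-down world for laptop-speed end-to-end runs: 5,000-point raw
#' grid and 0.4 Da peaks instead of the full-scale 125,000-point grid with
#' 0.08 Da peaks. All signal-structure parameters keep their full-scale
#' defaults; pass overrides through `...` (any [cohort_config()] argument).
#'
#' @param ... overrides forwarded to [cohort_config()].
#' @return a `cohort_config`.
#' @export
desk_cohort_config <- function(...) {
  args <- list(...)
  defaults <- list(n_points = 5000L, peak_sigma = 0.4)
  do.call(cohort_config, utils::modifyList(defaults, args))
}

#' Desk-scale preprocessing configuration
#'
#' Matches [desk_cohort_config()]: 0.2 Da bins, a 51-bin (~10 Da) top-hat
#' element and a +/-2 bin peak window.
#'
#' @param ... overrides forwarded to [preprocess_config()].
#' @return a `preprocess_config`.
#' @export
desk_preprocess_config <- function(...) {
  args <- list(...)
  defaults <- list(bin_width = 0.2, tophat_width = 51L, peak_window = 2L)
  do.call(preprocess_config, utils::modifyList(defaults, args))
}

#' Null-calibration cohort configuration
#'
#' The zero-signal world: no metabolic effect, class-identical CEA and
#' image-AI distributions, and class-independent clinical covariates, so
#' every diagnostic model should score at chance on a blind test.
#'
#' @param ... overrides forwarded to [desk_cohort_config()].
#' @return a `cohort_config`.
#' @export
null_cohort_config <- function(...) {
  args <- list(...)
  shared_cea <- c(meanlog = log(2), sdlog = 0.6)
  defaults <- list(
    effect_size = 0,
    cea_params = list(hc = shared_cea, lbd = shared_cea, luad = shared_cea),
    image_ai_params = list(benign = c(4, 4), malignant = c(4, 4)),
    covariate_signal = FALSE)
  do.call(desk_cohort_config, utils::modifyList(defaults, args))
}

#' Pipeline run configuration
#'
#' Bundles the per-stage configurations under one master seed. The default
#' is the desk-scale world (reduced spectra, reduced network width/epochs);
#' full published-scale settings are obtained by passing
#' `cohort = cohort_config(...)`, `prep = preprocess_config()`, `net =
#' list(n_blocks = 6, hidden_units = 1024, dropout_rate = 0.5)` and `train
#' = train_config()`.
#'
#' @param seed master seed; stage seeds are derived children.
#' @param cohort a [cohort_config()].
#' @param prep a [preprocess_config()].
#' @param net list of [net_config()] overrides shared by Met-NN and MP-NN
#'   (`input_dim` and `use_fusion` are set by the pipeline).
#' @param train a [train_config()].
#' @param grid a [fusion_grid()].
#' @param train_fraction train share of the split.
#' @param cea_cutoff CEA positivity cutoff, ng/mL.
#' @param n_perm permutations for the overfitting test.
#' @param out_dir optional output directory for the report bundle.
#' @return a `run_config`.
#' @export
run_config <- function(seed = 1L,
                       cohort = desk_cohort_config(),
                       prep = desk_preprocess_config(),
                       net = list(n_blocks = 2L, hidden_units = 64L,
                                  dropout_rate = 0.2),
                       train = train_config(learning_rate = 1e-3,
                                            epochs = 60L),
                       grid = fusion_grid(min_samples_leaf = c(2L, 5L),
                                          max_depth = c(3, 5),
                                          n_trees = 50L),
                       train_fraction = 0.8,
                       cea_cutoff = 5,
                       n_perm = 499L,
                       out_dir = NULL) {
  structure(list(seed = as.integer(seed), cohort = cohort, prep = prep,
                 net = net, train = train, grid = grid,
                 train_fraction = train_fraction, cea_cutoff = cea_cutoff,
                 n_perm = n_perm, out_dir = out_dir),
            class = "run_config")
}

summarize_split <- function(scores, labels, threshold) {
  r <- roc_auc(scores, labels)
  m <- threshold_metrics(scores, labels, threshold)
  list(auc = r$auc, ci = r$ci, threshold = threshold,
       sensitivity = m$sensitivity, specificity = m$specificity,
       ppv = m$ppv, npv = m$npv, accuracy = m$accuracy,
       youden_j = m$youden_j)
}

summarize_model <- function(s_tr, y_tr, s_te, y_te, threshold = NULL) {
  thr <- threshold %||% youden_threshold(s_tr, y_tr)$threshold
  list(train = summarize_split(s_tr, y_tr, thr),
       test = summarize_split(s_te, y_te, thr))
}

#' Run the full desk-scale pipeline
#'
#' Simulates a cohort, preprocesses every spectrum into the aligned
#' fingerprint matrix (feature bins and TIC reference chosen on the
#' training split only), trains Met-NN and MP-NN, computes the clinical
#' baselines, grid-searches and fits the MPI-RF fusion forest on the nodule
#' subset, and evaluates everything: AUC with DeLong CIs, Youden operating
#' points fixed on the training split, DeLong model comparisons, and a
#' label-permutation overfitting test.
#'
#' @param cfg a [run_config()].
#' @return a report list (class `smf_report`); if `cfg$out_dir` is set, a
#'   JSON report, per-subject score CSV, and metadata CSV are written there.
#' @export
run_pipeline <- function(cfg = run_config()) {
  if (!inherits(cfg, "run_config")) stop_input("`cfg` must be a run_config")
  cohort_cfg <- cfg$cohort
  cohort_cfg$seed <- child_seed(cfg$seed, 1L)
  cohort <- generate_cohort(cohort_cfg)
  records <- add_clinical_scores(cohort$records, cfg$cea_cutoff)
  split <- split_cohort(records, cfg$train_fraction,
                        stratify_on = "cohort_label",
                        seed = child_seed(cfg$seed, 2L))

  ids <- records$subject_id
  peaklists <- vector("list", length(ids))
  binned <- vector("list", length(ids))
  names(peaklists) <- names(binned) <- ids
  for (id in ids) {
    pp <- preprocess_spectrum(synthesize_spectrum(id, cohort$truth),
                              cfg$prep)
    peaklists[[id]] <- pp$peaks
    binned[[id]] <- pp$binned
  }
  fm_train <- build_feature_matrix(
    peaklists[split$train], binned[split$train],
    feature_prevalence = cfg$prep$feature_prevalence,
    tic_normalize = cfg$prep$tic_normalize)
  if (!length(fm_train$feature_bins)) {
    stop_input("preprocessing produced no features on the training split")
  }
  tic_ref <- stats::median(fm_train$tic[fm_train$tic > 0])
  fm_all <- build_feature_matrix(
    peaklists, binned,
    tic_normalize = cfg$prep$tic_normalize,
    feature_bins = fm_train$feature_bins,
    tic_reference = tic_ref)

  y_diag <- as.integer(records$cohort_label == "LUAD")
  names(y_diag) <- ids
  tr <- split$train
  te <- split$test
  X <- fm_all$values

  net_args <- utils::modifyList(
    list(n_blocks = 2L, hidden_units = 64L, dropout_rate = 0.2), cfg$net)
  make_net <- function(use_fusion, seed_off) {
    build_network(do.call(net_config, c(
      list(input_dim = ncol(X), use_fusion = use_fusion), net_args)),
      seed = child_seed(cfg$seed, seed_off))
  }
  tc <- cfg$train
  tc$seed <- child_seed(cfg$seed, 4L)
  met <- train_network(make_net(FALSE, 3L), X[tr, , drop = FALSE],
                       y_diag[tr], tc = tc)
  cea <- records$cea
  names(cea) <- ids
  tc$seed <- child_seed(cfg$seed, 5L)
  mp <- train_network(make_net(TRUE, 6L), X[tr, , drop = FALSE],
                      y_diag[tr], cea = cea[tr], tc = tc)
  s_met <- predict(met, X)
  s_mp <- predict(mp, X, cea = cea)

  # --- nodule subset: tri-modal fusion -------------------------------
  nod <- records$subject_id[records$nodule_present]
  nod_tr <- intersect(tr, nod)
  nod_te <- intersect(te, nod)
  y_nod <- as.integer(records$malignant[match(nod, records$subject_id)])
  names(y_nod) <- nod
  img <- records$image_ai_score
  names(img) <- ids
  fus_X <- cbind(mp_nn_score = s_mp[nod], image_ai_score = img[nod])
  rownames(fus_X) <- nod
  grid <- cfg$grid
  grid$seed <- child_seed(cfg$seed, 7L)
  gs <- grid_search_cv(fus_X[nod_tr, , drop = FALSE], y_nod[nod_tr], grid)
  mpi <- fit_final(fus_X[nod_tr, , drop = FALSE], y_nod[nod_tr],
                   min_samples_leaf = gs$best$min_samples_leaf,
                   max_depth = gs$best$max_depth,
                   n_trees = gs$best$n_trees,
                   seed = child_seed(cfg$seed, 8L))
  s_mpi <- predict_fusion(mpi, fus_X)
  names(s_mpi) <- nod

  # --- evaluation -----------------------------------------------------
  diag_models <- list(
    CEA = summarize_model(cea[tr], y_diag[tr], cea[te], y_diag[te],
                          threshold = cfg$cea_cutoff),
    `Met-NN` = summarize_model(s_met[tr], y_diag[tr], s_met[te], y_diag[te]),
    `MP-NN` = summarize_model(s_mp[tr], y_diag[tr], s_mp[te], y_diag[te]))
  mayo <- records$mayo_prob
  va <- records$va_prob
  names(mayo) <- names(va) <- ids
  nod_models <- list(
    `Met-NN` = summarize_model(s_met[nod_tr], y_nod[nod_tr],
                               s_met[nod_te], y_nod[nod_te]),
    `MP-NN` = summarize_model(s_mp[nod_tr], y_nod[nod_tr],
                              s_mp[nod_te], y_nod[nod_te]),
    `Image-AI` = summarize_model(img[nod_tr], y_nod[nod_tr],
                                 img[nod_te], y_nod[nod_te]),
    Mayo = summarize_model(mayo[nod_tr], y_nod[nod_tr],
                           mayo[nod_te], y_nod[nod_te]),
    VA = summarize_model(va[nod_tr], y_nod[nod_tr],
                         va[nod_te], y_nod[nod_te]),
    `MPI-RF` = summarize_model(s_mpi[nod_tr], y_nod[nod_tr],
                               s_mpi[nod_te], y_nod[nod_te]))
  delong <- list(
    mp_vs_met_diag_test = delong_compare(s_mp[te], s_met[te], y_diag[te]),
    mp_vs_cea_diag_test = delong_compare(s_mp[te], cea[te], y_diag[te]),
    mpi_vs_mp_nodule_test = delong_compare(s_mpi[nod_te], s_mp[nod_te],
                                           y_nod[nod_te]),
    mpi_vs_image_nodule_test = delong_compare(s_mpi[nod_te], img[nod_te],
                                              y_nod[nod_te]))
  perm <- permutation_auc_test(s_mp[te], y_diag[te], n_perm = cfg$n_perm,
                               seed = child_seed(cfg$seed, 9L))

  report <- structure(list(
    seed = cfg$seed,
    n_subjects = length(ids),
    n_features = ncol(X),
    split = split,
    diagnosis = diag_models,
    nodule = nod_models,
    fusion_hyperparameters = gs$best,
    delong = delong,
    permutation = list(auc = perm$auc, p = perm$p),
    scores = data.frame(subject_id = ids,
                        label = as.character(records$cohort_label),
                        split = ifelse(ids %in% tr, "train", "test"),
                        met_nn = as.vector(s_met),
                        mp_nn = as.vector(s_mp),
                        cea = as.vector(cea),
                        mayo = as.vector(mayo),
                        va = as.vector(va),
                        image_ai = as.vector(img),
                        mpi_rf = as.vector(s_mpi[match(ids, nod)]))),
    class = "smf_report")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      report[setdiff(names(report), c("scores", "split"))],
      file.path(cfg$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
    utils::write.csv(report$scores, file.path(cfg$out_dir, "scores.csv"),
                     row.names = FALSE)
    utils::write.csv(records, file.path(cfg$out_dir, "metadata.csv"),
                     row.names = FALSE)
  }
  report
}

#' @export
print.smf_report <- function(x, ...) {
  cat(sprintf("<smf_report> seed %d: %d subjects, %d features\n",
              x$seed, x$n_subjects, x$n_features))
  cat("Blind-test AUCs (diagnosis):",
      paste(sprintf("%s %.3f", names(x$diagnosis),
                    vapply(x$diagnosis, function(m) m$test$auc, 1)),
            collapse = ", "), "\n")
  cat("Blind-test AUCs (nodule):",
      paste(sprintf("%s %.3f", names(x$nodule),
                    vapply(x$nodule, function(m) m$test$auc, 1)),
            collapse = ", "), "\n")
  invisible(x)
}
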