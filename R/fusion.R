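# MPI-RF: the tri-modal fusion stage. A random forest (bootstrap-sampled,
# feature-subsampled, Gini-split decision trees) consumes the MP-NN score
# and the image-AI score per subject; hyperparameters are chosen by
# stratified k-fold grid search on mean out-of-fold AUC. Trees are stored
# as explicit node tables, so models serialize to JSON and predictions are
# exactly reproducible.

#' Hyperparameter grid for the fusion forest
#'
#' @param min_samples_leaf candidate minimum leaf sizes.
#' @param max_depth candidate maximum tree depths (`Inf` = unbounded).
#' @param n_trees candidate forest sizes.
#' @param cv_folds stratified folds (study convention: 10).
#' @param seed integer seed driving fold assignment and tree growth.
#' @return a validated `fusion_grid`.
#' @export
fusion_grid <- function(min_samples_leaf = c(1L, 2L, 5L, 10L),
                        max_depth = c(2, 3, 5, Inf),
                        n_trees = c(100L, 300L, 500L),
                        cv_folds = 10L, seed = 1L) {
  stopifnot(length(min_samples_leaf) >= 1, length(max_depth) >= 1,
            length(n_trees) >= 1)
  cv_folds <- check_count(cv_folds, "cv_folds", lower = 2)
  structure(list(min_samples_leaf = as.integer(min_samples_leaf),
                 max_depth = as.double(max_depth),
                 n_trees = as.integer(n_trees),
                 cv_folds = cv_folds, seed = as.integer(seed)),
            class = "fusion_grid")
}

# Best Gini split over a feature subset; returns NULL if no valid split.
best_split <- function(X, y, idx, feats, min_leaf) {
  n <- length(idx)
  best <- NULL
  for (f in feats) {
    xv <- X[idx, f]
    ord <- order(xv)
    xs <- xv[ord]
    ys <- y[idx][ord]
    n1 <- cumsum(ys)
    i <- seq_len(n - 1L)
    valid <- i >= min_leaf & (n - i) >= min_leaf & xs[i] < xs[i + 1L]
    if (!any(valid)) next
    i <- i[valid]
    nl <- i
    nr <- n - i
    p1l <- n1[i] / nl
    p1r <- (n1[n] - n1[i]) / nr
    gini <- (nl * 2 * p1l * (1 - p1l) + nr * 2 * p1r * (1 - p1r)) / n
    k <- which.min(gini)
    if (is.null(best) || gini[k] < best$gini - 1e-15) {
      best <- list(feature = f, threshold = (xs[i[k]] + xs[i[k] + 1L]) / 2,
                   gini = gini[k])
    }
  }
  best
}

# Grow one tree on bootstrap rows `rows`; nodes accumulated in a list:
# each node has feature (NA = leaf), threshold, left, right, prob, n.
grow_tree <- function(X, y, rows, max_depth, min_leaf, mtry) {
  nodes <- list()
  new_node <- function() {
    nodes[[length(nodes) + 1L]] <<- list(feature = NA_integer_,
                                         threshold = NA_real_,
                                         left = NA_integer_,
                                         right = NA_integer_,
                                         prob = NA_real_, n = 0L)
    length(nodes)
  }
  p <- ncol(X)
  build <- function(idx, depth) {
    id <- new_node()
    prob <- mean(y[idx])
    nodes[[id]]$prob <<- prob
    nodes[[id]]$n <<- length(idx)
    if (depth >= max_depth || length(idx) < 2L * min_leaf ||
        prob == 0 || prob == 1) {
      return(id)
    }
    feats <- if (mtry >= p) seq_len(p) else sort(sample.int(p, mtry))
    sp <- best_split(X, y, idx, feats, min_leaf)
    if (is.null(sp)) return(id)
    nodes[[id]]$feature <<- sp$feature
    nodes[[id]]$threshold <<- sp$threshold
    go_left <- X[idx, sp$feature] <= sp$threshold
    nodes[[id]]$left <<- build(idx[go_left], depth + 1L)
    nodes[[id]]$right <<- build(idx[!go_left], depth + 1L)
    id
  }
  build(rows, 0L)
  nodes
}

tree_predict <- function(nodes, X) {
  out <- numeric(nrow(X))
  recurse <- function(id, rows) {
    nd <- nodes[[id]]
    if (is.na(nd$feature)) {
      out[rows] <<- nd$prob
      return(invisible())
    }
    go_left <- X[rows, nd$feature] <= nd$threshold
    if (any(go_left)) recurse(nd$left, rows[go_left])
    if (any(!go_left)) recurse(nd$right, rows[!go_left])
  }
  if (nrow(X)) recurse(1L, seq_len(nrow(X)))
  out
}

as_feature_mat <- function(features) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop_input("fusion features must be finite")
  X
}

#' Fit the fusion random forest with fixed hyperparameters
#'
#' Each tree is grown on a bootstrap sample with `floor(sqrt(p))` features
#' tried per split (Gini criterion); the forest probability is the mean of
#' per-tree leaf class-1 frequencies. Fully deterministic under `seed`.
#'
#' @param features numeric matrix/data frame, one row per subject;
#'   canonical layout is `(mp_nn_score, image_ai_score)`.
#' @param labels binary labels (1 = malignant).
#' @param min_samples_leaf minimum samples per leaf.
#' @param max_depth maximum depth (`Inf` = unbounded).
#' @param n_trees number of trees.
#' @param seed integer seed.
#' @return a `fusion_model`.
#' @export
fit_final <- function(features, labels, min_samples_leaf = 1L,
                      max_depth = Inf, n_trees = 300L, seed = 1L) {
  X <- as_feature_mat(features)
  y <- as_binary_labels(labels)
  if (nrow(X) != length(y)) stop_input("features/labels size mismatch")
  min_samples_leaf <- check_count(min_samples_leaf, "min_samples_leaf",
                                  lower = 1)
  n_trees <- check_count(n_trees, "n_trees", lower = 1)
  mtry <- max(1L, floor(sqrt(ncol(X))))
  trees <- with_seed(seed, {
    lapply(seq_len(n_trees), function(t) {
      rows <- sample.int(nrow(X), nrow(X), replace = TRUE)
      grow_tree(X, y, rows, max_depth, min_samples_leaf, mtry)
    })
  })
  structure(list(trees = trees, n_features = ncol(X),
                 feature_names = colnames(X),
                 min_samples_leaf = min_samples_leaf,
                 max_depth = max_depth, n_trees = n_trees,
                 mtry = mtry, seed = as.integer(seed)),
            class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf(
    "<fusion_model> %d trees (depth <= %s, leaf >= %d) on %d feature(s)\n",
    x$n_trees, format(x$max_depth), x$min_samples_leaf, x$n_features))
  invisible(x)
}

#' Predict fusion probabilities
#'
#' @param model a [fit_final()] forest.
#' @param features matrix with the training column layout.
#' @return probability per subject in [0, 1] (mean of per-tree leaf
#'   class frequencies).
#' @export
predict_fusion <- function(model, features) {
  X <- as_feature_mat(features)
  if (ncol(X) != model$n_features) {
    stop_input("expected %d feature column(s), got %d",
               model$n_features, ncol(X))
  }
  votes <- vapply(model$trees, function(tr) tree_predict(tr, X),
                  numeric(nrow(X)))
  if (nrow(X) == 1L) votes <- matrix(votes, nrow = 1L)
  p <- rowMeans(votes)
  names(p) <- rownames(X)
  p
}

#' Grid-searched cross-validated hyperparameter selection
#'
#' Stratified k-fold CV over every grid point; the selection metric is the
#' mean out-of-fold AUC, with ties broken toward parsimony (fewer trees,
#' then shallower depth, then larger leaf).
#'
#' @param features,labels as in [fit_final()].
#' @param grid a [fusion_grid()].
#' @return list: `best` (chosen hyperparameters), `cv_table` (one row per
#'   grid point with mean and per-fold AUC), `folds` (fold id per subject).
#' @export
grid_search_cv <- function(features, labels, grid = fusion_grid()) {
  if (!inherits(grid, "fusion_grid")) {
    stop_input("`grid` must come from fusion_grid()")
  }
  X <- as_feature_mat(features)
  y <- as_binary_labels(labels)
  folds <- stratified_folds(y, grid$cv_folds, seed = grid$seed)
  combos <- expand.grid(min_samples_leaf = grid$min_samples_leaf,
                        max_depth = grid$max_depth,
                        n_trees = grid$n_trees,
                        KEEP.OUT.ATTRS = FALSE)
  fold_auc <- matrix(NA_real_, nrow(combos), grid$cv_folds)
  for (ci in seq_len(nrow(combos))) {
    for (k in seq_len(grid$cv_folds)) {
      tr <- folds != k
      model <- fit_final(X[tr, , drop = FALSE], y[tr],
                         min_samples_leaf = combos$min_samples_leaf[ci],
                         max_depth = combos$max_depth[ci],
                         n_trees = combos$n_trees[ci],
                         seed = child_seed(grid$seed, ci * 1000L + k))
      oof <- predict_fusion(model, X[!tr, , drop = FALSE])
      yk <- y[!tr]
      if (length(unique(yk)) == 2L) {
        fold_auc[ci, k] <- roc_auc(oof, yk)$auc
      }
    }
  }
  mean_auc <- rowMeans(fold_auc, na.rm = TRUE)
  ord <- order(-mean_auc, combos$n_trees, combos$max_depth,
               -combos$min_samples_leaf)
  best <- combos[ord[1], ]
  list(best = list(min_samples_leaf = best$min_samples_leaf,
                   max_depth = best$max_depth,
                   n_trees = best$n_trees),
       cv_table = cbind(combos, mean_auc = mean_auc, fold_auc),
       folds = folds)
}
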