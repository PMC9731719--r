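# Met-NN / MP-NN: residual fully-connected classifiers on metabolic
# fingerprints, optionally fused with the CEA tumor marker. Implemented as
# plain matrix algebra with hand-derived backpropagation and the Adam
# update rule, so training is exactly reproducible under a seed.
#
# Architecture: affine input projection to `hidden_units` (the first skip
# connection is undefined when input_dim != hidden, so a linear projection
# precedes the stack), then `n_blocks` residual feature-extraction blocks
#   h <- h + LeakyReLU(Dropout(h %*% W + b))
# (fully connected -> dropout -> LeakyReLU, plus the identity skip), then an
# affine map to one logit squashed to the metabolite score in (0,1). With
# `use_fusion`, a final affine layer maps (metabolite score, transformed
# CEA) to the fused probability; Met-NN and MP-NN share the topology but
# are trained as separate models (MP-NN end to end).

#' Network architecture configuration
#'
#' Defaults follow the published architecture: six residual feature
#' extraction blocks of 1024 hidden units with dropout and LeakyReLU.
#' Dropout rate, leaky slope and batch size are implementation defaults
#' (0.5, 0.01, 64).
#'
#' @param input_dim number of fingerprint features.
#' @param n_blocks residual blocks (>= 1).
#' @param hidden_units width of the hidden layers.
#' @param dropout_rate dropout probability in [0, 1).
#' @param leaky_slope negative-part slope of LeakyReLU.
#' @param use_fusion TRUE for MP-NN (fingerprints + CEA), FALSE for Met-NN.
#' @param cea_transform "log1p_standardize" (default), "standardize", or
#'   "none".
#' @return a validated `net_config`.
#' @export
net_config <- function(input_dim, n_blocks = 6L, hidden_units = 1024L,
                       dropout_rate = 0.5, leaky_slope = 0.01,
                       use_fusion = FALSE,
                       cea_transform = c("log1p_standardize", "standardize",
                                         "none")) {
  input_dim <- check_count(input_dim, "input_dim", lower = 1)
  n_blocks <- check_count(n_blocks, "n_blocks", lower = 1)
  hidden_units <- check_count(hidden_units, "hidden_units", lower = 1)
  check_number(dropout_rate, "dropout_rate", lower = 0, upper = 1,
               strict_upper = TRUE)
  check_number(leaky_slope, "leaky_slope", lower = 0)
  check_flag(use_fusion, "use_fusion")
  structure(list(input_dim = input_dim, n_blocks = n_blocks,
                 hidden_units = hidden_units, dropout_rate = dropout_rate,
                 leaky_slope = leaky_slope, use_fusion = use_fusion,
                 cea_transform = match.arg(cea_transform)),
            class = "net_config")
}

#' Training configuration
#'
#' Adam with the published settings: learning rate 1e-4, beta1 0.9, beta2
#' 0.999, binary cross-entropy loss, a fixed number of epochs (1000 at full
#' scale; reduce via `epochs` for desk-scale runs).
#'
#' @param learning_rate Adam step size (> 0).
#' @param beta1,beta2 Adam moment decays in (0, 1).
#' @param epochs training epochs (>= 1).
#' @param batch_size minibatch size.
#' @param seed seed for initialization, shuffling and dropout streams.
#' @return a validated `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         epochs = 1000L, batch_size = 64L, seed = 1L) {
  check_number(learning_rate, "learning_rate", lower = 0,
               strict_lower = TRUE)
  check_number(beta1, "beta1", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(beta2, "beta2", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  epochs <- check_count(epochs, "epochs", lower = 1)
  batch_size <- check_count(batch_size, "batch_size", lower = 1)
  structure(list(learning_rate = learning_rate, beta1 = beta1,
                 beta2 = beta2, epochs = epochs, batch_size = batch_size,
                 seed = as.integer(seed)),
            class = "train_config")
}

init_params <- function(cfg, seed) {
  with_seed(seed, {
    d <- cfg$input_dim
    h <- cfg$hidden_units
    he <- function(fan_in, nr, nc) {
      matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
    }
    p <- list(W_in = he(d, d, h), b_in = numeric(h),
              blocks = lapply(seq_len(cfg$n_blocks), function(k) {
                list(W = he(h, h, h), b = numeric(h))
              }),
              W_out = he(h, h, 1L), b_out = 0)
    if (cfg$use_fusion) {
      # identity-leaning start: fused logit begins close to the met score
      p$W_f <- matrix(c(1, 0) + 0.1 * stats::rnorm(2), 2, 1)
      p$b_f <- -0.5
    }
    p
  })
}

#' Build an untrained network
#'
#' Seeded parameter initialization (He-scaled Gaussians); two builds with
#' the same seed are identical.
#'
#' @param cfg a [net_config()].
#' @param seed integer seed.
#' @return an `smf_net` (untrained: standardization statistics unset).
#' @export
build_network <- function(cfg, seed = 1L) {
  if (!inherits(cfg, "net_config")) stop_input("`cfg` must be a net_config")
  structure(list(cfg = cfg, params = init_params(cfg, seed),
                 feat_mean = NULL, feat_sd = NULL,
                 cea_mean = NULL, cea_sd = NULL,
                 loss_trace = numeric(0), trained = FALSE),
            class = "smf_net")
}

#' @export
print.smf_net <- function(x, ...) {
  cat(sprintf("<smf_net> %s: %d features -> %d x %d residual blocks%s%s\n",
              if (x$cfg$use_fusion) "MP-NN" else "Met-NN",
              x$cfg$input_dim, x$cfg$n_blocks, x$cfg$hidden_units,
              if (x$cfg$use_fusion) " + CEA fusion" else "",
              if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

transform_cea <- function(cea, kind, center = NULL, scale = NULL) {
  v <- switch(kind,
              log1p_standardize = log1p(cea),
              standardize = cea,
              none = cea)
  if (kind == "none") return(list(v = v, center = 0, scale = 1))
  center <- center %||% mean(v)
  scale <- scale %||% stats::sd(v)
  if (!is.finite(scale) || scale == 0) scale <- 1
  list(v = (v - center) / scale, center = center, scale = scale)
}

# Forward pass. X: standardized n x d matrix; cea_t: standardized vector or
# NULL; masks: list of dropout masks per block (NULL = inference).
net_forward <- function(params, cfg, X, cea_t = NULL, masks = NULL) {
  H <- sweep(X %*% params$W_in, 2L, -params$b_in)
  cache <- list(H = list(H))
  A_list <- vector("list", cfg$n_blocks)
  for (k in seq_len(cfg$n_blocks)) {
    A <- sweep(H %*% params$blocks[[k]]$W, 2L, -params$blocks[[k]]$b)
    D <- if (is.null(masks)) A else A * masks[[k]]
    Z <- D * ((D > 0) + cfg$leaky_slope * (D <= 0))
    H <- H + Z
    A_list[[k]] <- D
    cache$H[[k + 1L]] <- H
  }
  s_logit <- as.vector(H %*% params$W_out) + params$b_out
  met <- sigmoid(s_logit)
  if (cfg$use_fusion) {
    if (is.null(cea_t)) stop_input("MP-NN requires a CEA value per subject")
    f_logit <- as.vector(cbind(met, cea_t) %*% params$W_f) + params$b_f
    prob <- sigmoid(f_logit)
  } else {
    prob <- met
  }
  list(prob = prob, met = met, s_logit = s_logit, A = A_list, cache = cache)
}

# Backward pass of mean binary cross-entropy; returns gradients shaped like
# params. fw is the net_forward() output for the same (X, cea_t, masks).
net_backward <- function(params, cfg, X, cea_t, y, fw, masks = NULL) {
  n <- nrow(X)
  g <- list(blocks = vector("list", cfg$n_blocks))
  if (cfg$use_fusion) {
    dfl <- (fw$prob - y) / n
    Fmat <- cbind(fw$met, cea_t)
    g$W_f <- crossprod(Fmat, dfl)
    g$b_f <- sum(dfl)
    dmet <- dfl * params$W_f[1, 1]
    dsl <- dmet * fw$met * (1 - fw$met)
  } else {
    dsl <- (fw$prob - y) / n
  }
  H_last <- fw$cache$H[[cfg$n_blocks + 1L]]
  g$W_out <- crossprod(H_last, dsl)
  g$b_out <- sum(dsl)
  dH <- matrix(dsl, ncol = 1L) %*% t(params$W_out)
  for (k in rev(seq_len(cfg$n_blocks))) {
    D <- fw$A[[k]]
    dD <- dH * ((D > 0) + cfg$leaky_slope * (D <= 0))
    dA <- if (is.null(masks)) dD else dD * masks[[k]]
    H_prev <- fw$cache$H[[k]]
    g$blocks[[k]] <- list(W = crossprod(H_prev, dA), b = colSums(dA))
    dH <- dH + dA %*% t(params$blocks[[k]]$W)
  }
  g$W_in <- crossprod(X, dH)
  g$b_in <- colSums(dH)
  g
}

flatten_params <- function(p) {
  out <- c(as.vector(p$W_in), p$b_in)
  for (bl in p$blocks) out <- c(out, as.vector(bl$W), bl$b)
  out <- c(out, as.vector(p$W_out), p$b_out)
  if (!is.null(p$W_f)) out <- c(out, as.vector(p$W_f), p$b_f)
  out
}

bce_loss <- function(prob, y, eps = 1e-12) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

adam_step <- function(state, params, grads, tc, t) {
  lr_t <- tc$learning_rate * sqrt(1 - tc$beta2^t) / (1 - tc$beta1^t)
  upd <- function(th, g, m, v) {
    m <- tc$beta1 * m + (1 - tc$beta1) * g
    v <- tc$beta2 * v + (1 - tc$beta2) * g * g
    th <- th - lr_t * m / (sqrt(v) + 1e-8)
    list(th = th, m = m, v = v)
  }
  # flat traversal over the named leaves
  leaves <- c("W_in", "b_in", "W_out", "b_out",
              if (!is.null(params$W_f)) c("W_f", "b_f"))
  for (nm in leaves) {
    r <- upd(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]])
    params[[nm]] <- r$th; state$m[[nm]] <- r$m; state$v[[nm]] <- r$v
  }
  for (k in seq_along(params$blocks)) {
    for (nm in c("W", "b")) {
      r <- upd(params$blocks[[k]][[nm]], grads$blocks[[k]][[nm]],
               state$m$blocks[[k]][[nm]], state$v$blocks[[k]][[nm]])
      params$blocks[[k]][[nm]] <- r$th
      state$m$blocks[[k]][[nm]] <- r$m
      state$v$blocks[[k]][[nm]] <- r$v
    }
  }
  list(params = params, state = state)
}

zero_like <- function(p) {
  z <- list(W_in = p$W_in * 0, b_in = p$b_in * 0,
            blocks = lapply(p$blocks, function(bl)
              list(W = bl$W * 0, b = bl$b * 0)),
            W_out = p$W_out * 0, b_out = 0)
  if (!is.null(p$W_f)) { z$W_f <- p$W_f * 0; z$b_f <- 0 }
  z
}

#' Train a Met-NN / MP-NN classifier
#'
#' Minimizes mean binary cross-entropy with Adam over seeded minibatches;
#' feature columns are z-scored and CEA is log1p-transformed and z-scored
#' on the training data only (statistics are stored in the returned model).
#' Dropout and shuffling streams are derived from `tc$seed`, so training is
#' fully deterministic.
#'
#' @param net an untrained [build_network()] model (its initial weights are
#'   kept, so build and train seeds are independent).
#' @param features numeric matrix (subjects x features) or a
#'   `feature_matrix`.
#' @param labels binary labels (1 = LUAD / malignant).
#' @param cea CEA per subject in ng/mL (required for MP-NN).
#' @param tc a [train_config()].
#' @return the trained `smf_net`, with `loss_trace` (per-epoch mean BCE).
#' @export
train_network <- function(net, features, labels, cea = NULL,
                          tc = train_config()) {
  if (!inherits(net, "smf_net")) stop_input("`net` must be an smf_net")
  X <- if (inherits(features, "feature_matrix")) features$values else
    as.matrix(features)
  y <- as_binary_labels(labels)
  if (nrow(X) != length(y)) stop_input("features/labels size mismatch")
  cfg <- net$cfg
  if (ncol(X) != cfg$input_dim) {
    stop_input("expected %d features, got %d", cfg$input_dim, ncol(X))
  }
  net$feat_mean <- colMeans(X)
  net$feat_sd <- apply(X, 2L, stats::sd)
  net$feat_sd[!is.finite(net$feat_sd) | net$feat_sd == 0] <- 1
  Xs <- sweep(sweep(X, 2L, net$feat_mean), 2L, net$feat_sd, "/")
  cea_t <- NULL
  if (cfg$use_fusion) {
    if (is.null(cea)) stop_input("MP-NN training requires `cea`")
    tr <- transform_cea(cea, cfg$cea_transform)
    net$cea_mean <- tr$center
    net$cea_sd <- tr$scale
    cea_t <- tr$v
  }
  n <- nrow(Xs)
  params <- net$params
  state <- list(m = zero_like(params), v = zero_like(params))
  trace <- numeric(tc$epochs)
  t_step <- 0L
  with_seed(tc$seed, {
    for (ep in seq_len(tc$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      n_batches <- ceiling(n / tc$batch_size)
      for (b in seq_len(n_batches)) {
        idx <- ord[((b - 1L) * tc$batch_size + 1L):min(b * tc$batch_size, n)]
        Xb <- Xs[idx, , drop = FALSE]
        yb <- y[idx]
        cb <- if (is.null(cea_t)) NULL else cea_t[idx]
        masks <- if (cfg$dropout_rate > 0) {
          lapply(seq_len(cfg$n_blocks), function(k) {
            matrix(stats::rbinom(length(idx) * cfg$hidden_units, 1L,
                                 1 - cfg$dropout_rate) /
                     (1 - cfg$dropout_rate),
                   length(idx), cfg$hidden_units)
          })
        } else NULL
        fw <- net_forward(params, cfg, Xb, cb, masks)
        loss <- bce_loss(fw$prob, yb)
        if (!is.finite(loss)) {
          stop_input("training diverged (non-finite loss at epoch %d)", ep)
        }
        ep_loss <- ep_loss + loss * length(idx)
        g <- net_backward(params, cfg, Xb, cb, yb, fw, masks)
        t_step <- t_step + 1L
        st <- adam_step(state, params, g, tc, t_step)
        params <- st$params
        state <- st$state
      }
      trace[ep] <- ep_loss / n
    }
  })
  net$params <- params
  net$loss_trace <- trace
  net$trained <- TRUE
  net
}

#' Score subjects with a trained network
#'
#' Applies the stored feature standardization and CEA transform, disables
#' dropout, and returns deterministic scores in (0, 1).
#'
#' @param object a trained `smf_net`.
#' @param features matrix or `feature_matrix` with the training columns.
#' @param cea CEA per subject (MP-NN only).
#' @param ... unused.
#' @return numeric scores, named by subject when available.
#' @export
predict.smf_net <- function(object, features, cea = NULL, ...) {
  X <- if (inherits(features, "feature_matrix")) features$values else
    as.matrix(features)
  if (ncol(X) != object$cfg$input_dim) {
    stop_input("expected %d features, got %d", object$cfg$input_dim, ncol(X))
  }
  if (is.null(object$feat_mean)) stop_input("network is untrained")
  Xs <- sweep(sweep(X, 2L, object$feat_mean), 2L, object$feat_sd, "/")
  cea_t <- NULL
  if (object$cfg$use_fusion) {
    if (is.null(cea)) stop_input("MP-NN prediction requires `cea`")
    cea_t <- transform_cea(cea, object$cfg$cea_transform,
                           object$cea_mean, object$cea_sd)$v
  }
  p <- net_forward(object$params, object$cfg, Xs, cea_t, masks = NULL)$prob
  names(p) <- rownames(X)
  p
}
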