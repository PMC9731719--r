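loss_of <- function(net, X, cea, y) {
  fw <- smfdx:::net_forward(net$params, net$cfg, X, cea, masks = NULL)
  smfdx:::bce_loss(fw$prob, y)
}

test_that("network construction is seeded and architecturally sound", {
  a <- small_net(10, seed = 3)
  b <- small_net(10, seed = 3)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, small_net(10, seed = 4)$params))
  expect_length(a$params$blocks, 2L)
  expect_equal(dim(a$params$blocks[[1]]$W), c(16L, 16L))
  # published-scale topology is representable
  big <- net_config(input_dim = 2316, n_blocks = 6, hidden_units = 1024,
                    dropout_rate = 0.5, use_fusion = TRUE)
  expect_equal(big$n_blocks, 6L)
  expect_equal(big$hidden_units, 1024L)
  expect_error(net_config(input_dim = 0), "input_dim")
  expect_error(net_config(input_dim = 5, dropout_rate = 1), "dropout_rate")
})

test_that("zeroed final layer yields exactly 0.5; outputs stay in (0,1)", {
  net <- small_net(6)
  net$params$W_out[] <- 0
  net$params$b_out <- 0
  X <- matrix(rnorm(30), 5, 6)
  fw <- smfdx:::net_forward(net$params, net$cfg, X)
  expect_equal(fw$prob, rep(0.5, 5))
  set.seed(2)
  X2 <- matrix(rnorm(600), 100, 6)
  p <- smfdx:::net_forward(small_net(6)$params, small_net(6)$cfg, X2)$prob
  expect_true(all(p > 0 & p < 1))
})

test_that("analytic gradients match central differences (micro-network)", {
  set.seed(5)
  n <- 12
  X <- matrix(rnorm(n * 5), n, 5)
  y <- rep(c(0, 1), 6)
  cea <- runif(n, -1, 1)
  for (fusion in c(FALSE, TRUE)) {
    net <- build_network(net_config(5, n_blocks = 2, hidden_units = 7,
                                    dropout_rate = 0, use_fusion = fusion),
                         seed = 9)
    cc <- if (fusion) cea else NULL
    fw <- smfdx:::net_forward(net$params, net$cfg, X, cc)
    g <- smfdx:::net_backward(net$params, net$cfg, X, cc, y, fw)
    eps <- 1e-5
    check_coord <- function(getp, setp, ganal) {
      base <- getp(net$params)
      for (trial in 1:4) {
        i <- sample(length(base), 1)
        pp <- net$params; pp <- setp(pp, replace(base, i, base[i] + eps))
        pm <- net$params; pm <- setp(pm, replace(base, i, base[i] - eps))
        np <- net; np$params <- pp
        nm <- net; nm$params <- pm
        num <- (loss_of(np, X, cc, y) - loss_of(nm, X, cc, y)) / (2 * eps)
        expect_lt(abs(num - ganal[i]) / max(abs(num), abs(ganal[i]), 1e-8),
                  1e-4)
      }
    }
    check_coord(function(p) p$W_in,
                function(p, v) { p$W_in[] <- v; p }, as.vector(g$W_in))
    check_coord(function(p) p$blocks[[1]]$W,
                function(p, v) { p$blocks[[1]]$W[] <- v; p },
                as.vector(g$blocks[[1]]$W))
    check_coord(function(p) p$blocks[[2]]$b,
                function(p, v) { p$blocks[[2]]$b <- v; p },
                g$blocks[[2]]$b)
    check_coord(function(p) p$W_out,
                function(p, v) { p$W_out[] <- v; p }, as.vector(g$W_out))
    if (fusion) {
      check_coord(function(p) p$W_f,
                  function(p, v) { p$W_f[] <- v; p }, as.vector(g$W_f))
    }
  }
})

test_that("training separates a linearly separable toy and reduces loss", {
  toy <- toy_features(n = 100, p = 50, informative = 2, delta = 2)
  net <- build_network(net_config(50, n_blocks = 2, hidden_units = 32,
                                  dropout_rate = 0), seed = 1)
  tc <- train_config(learning_rate = 1e-3, epochs = 100, batch_size = 32,
                     seed = 2)
  fit <- train_network(net, toy$X, toy$y, tc = tc)
  expect_gte(roc_auc(predict(fit, toy$X), toy$y)$auc, 0.99)
  expect_lte(fit$loss_trace[50], fit$loss_trace[1])
  expect_length(fit$loss_trace, 100)
})

test_that("training is deterministic under its seed, including dropout", {
  toy <- toy_features(n = 60, p = 20)
  mk <- function() {
    net <- build_network(net_config(20, n_blocks = 2, hidden_units = 16,
                                    dropout_rate = 0.3), seed = 5)
    train_network(net, toy$X, toy$y,
                  tc = train_config(learning_rate = 1e-3, epochs = 10,
                                    batch_size = 16, seed = 11))
  }
  a <- mk()
  b <- mk()
  expect_identical(a$params, b$params)
  expect_identical(predict(a, toy$X), predict(b, toy$X))
})

test_that("training-input validation catches the documented errors", {
  toy <- toy_features(n = 20, p = 8)
  net <- small_net(8)
  expect_error(train_network(net, toy$X, rep(1, 20)), "both classes")
  expect_error(train_network(net, toy$X[, 1:5], toy$y), "features")
  expect_error(predict(small_net(8), toy$X), "untrained")
  fit <- train_network(small_net(8), toy$X, toy$y,
                       tc = train_config(epochs = 2, seed = 1))
  expect_error(predict(fit, toy$X[, 1:5]), "expected 8 features, got 5")
})

test_that("permuted labels give chance-level blind-test AUC", {
  toy <- toy_features(n = 120, p = 30, informative = 3, delta = 1.5)
  aucs <- vapply(1:5, function(s) {
    set.seed(900 + s)
    yp <- sample(toy$y)
    tr <- seq_len(80)
    te <- 81:120
    net <- build_network(net_config(30, n_blocks = 2, hidden_units = 16,
                                    dropout_rate = 0.2), seed = s)
    fit <- train_network(net, toy$X[tr, ], yp[tr],
                         tc = train_config(learning_rate = 1e-3,
                                           epochs = 30, batch_size = 32,
                                           seed = s))
    roc_auc(predict(fit, toy$X[te, ]), yp[te])$auc
  }, numeric(1))
  expect_true(all(aucs > 0.25 & aucs < 0.75))
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})

test_that("MP-NN fusion: CEA ablation identity and monotonicity", {
  toy <- toy_features(n = 80, p = 10)
  set.seed(3)
  cea <- rlnorm(80, log(2 + 3 * toy$y), 0.4)
  net <- build_network(net_config(10, n_blocks = 1, hidden_units = 8,
                                  dropout_rate = 0, use_fusion = TRUE),
                       seed = 2)
  fit <- train_network(net, toy$X, toy$y, cea = cea,
                       tc = train_config(learning_rate = 1e-3, epochs = 30,
                                         seed = 4))
  # zero CEA fusion weight: score is a logistic map of the met score alone
  abl <- fit
  abl$params$W_f[2, 1] <- 0
  s <- predict(abl, toy$X, cea = cea)
  fw <- smfdx:::net_forward(abl$params, abl$cfg,
                            sweep(sweep(toy$X, 2, abl$feat_mean), 2,
                                  abl$feat_sd, "/"),
                            cea_t = rep(0, nrow(toy$X)))
  expect_equal(s, stats::setNames(
    smfdx:::sigmoid(abl$params$W_f[1, 1] * fw$met + abl$params$b_f),
    names(s)), tolerance = 1e-12)
  # positive CEA weight: raising CEA never lowers the score
  pos <- fit
  pos$params$W_f[2, 1] <- abs(pos$params$W_f[2, 1]) + 0.1
  cea_grid <- seq(0.5, 40, length.out = 15)
  one_row <- toy$X[1, , drop = FALSE][rep(1, 15), ]
  sc <- predict(pos, one_row, cea = cea_grid)
  expect_true(all(diff(sc) >= -1e-12))
})

test_that("MP-NN beats Met-NN when CEA carries independent signal", {
  wins <- vapply(1:8, function(s) {
    toy <- toy_features(n = 150, p = 25, informative = 4, delta = 0.5,
                        seed = 300 + s)
    set.seed(300 + s)
    cea <- rlnorm(150, log(2) + 1.2 * toy$y, 0.6)
    tr <- seq_len(100)
    te <- 101:150
    tc <- train_config(learning_rate = 1e-3, epochs = 40, batch_size = 32,
                       seed = s)
    met <- train_network(
      build_network(net_config(25, n_blocks = 2, hidden_units = 16,
                               dropout_rate = 0.2), seed = s),
      toy$X[tr, ], toy$y[tr], tc = tc)
    mp <- train_network(
      build_network(net_config(25, n_blocks = 2, hidden_units = 16,
                               dropout_rate = 0.2, use_fusion = TRUE),
                    seed = s),
      toy$X[tr, ], toy$y[tr], cea = cea[tr], tc = tc)
    roc_auc(predict(mp, toy$X[te, ], cea = cea[te]), toy$y[te])$auc >=
      roc_auc(predict(met, toy$X[te, ]), toy$y[te])$auc
  }, logical(1))
  expect_gte(mean(wins), 0.75)
})

test_that("checkpoints round-trip with identical predictions", {
  toy <- toy_features(n = 40, p = 12)
  set.seed(8)
  cea <- rlnorm(40, log(3), 0.5)
  fit <- train_network(
    build_network(net_config(12, n_blocks = 2, hidden_units = 8,
                             dropout_rate = 0.1, use_fusion = TRUE),
                  seed = 3),
    toy$X, toy$y, cea = cea,
    tc = train_config(epochs = 5, seed = 6))
  path <- tempfile(fileext = ".json")
  save_network(fit, path)
  back <- load_network(path)
  expect_equal(predict(back, toy$X, cea = cea),
               predict(fit, toy$X, cea = cea), tolerance = 1e-12)
})
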