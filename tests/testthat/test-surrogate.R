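# a linear synthetic regression problem: fields = scores %*% B + noise
linear_problem <- function(n = 120L, k = 4L, N = 60L, noise = 0, seed = 1L) {
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * k), n, k)
    B <- matrix(stats::rnorm(k * N, sd = 2), k, N)
    F_all <- X %*% B + matrix(stats::rnorm(n * N, sd = noise), n, N)
    list(X = X, F_all = F_all)
  })
}

test_that("net_config validates its fields", {
  expect_error(net_config(n_hidden_layers = 0), ">= 1")
  expect_error(net_config(learning_rate = 0), "positive")
  cfg <- net_config()
  expect_identical(cfg$batch_size, 32L)
  expect_identical(cfg$epochs, 50L)
})

test_that("training learns a linear map to under 1% of the field range", {
  pb <- linear_problem()
  tr <- 1:100
  te <- 101:120
  basis <- fit_pca(pb$F_all[tr, ], var_target = 1)
  cfg <- net_config(n_hidden_layers = 1L, neurons_per_layer = 96L,
                    learning_rate = 5e-3, batch_size = 20L, epochs = 250L,
                    rng_seed = 2L)
  m <- train_surrogate(pb$X[tr, ], pb$F_all[tr, ], basis, cfg,
                       validation = list(scores = pb$X[te, ],
                                         fields = pb$F_all[te, ]))
  rng <- max(pb$F_all) - min(pb$F_all)
  expect_lt(utils::tail(m$history$val_loss, 1L) / rng, 0.01)
  # training loss decreases overall
  expect_lt(utils::tail(m$history$train_loss, 1L), m$history$train_loss[1L])
})

test_that("training is deterministic and diverging runs abort", {
  pb <- linear_problem(n = 80L)
  basis <- fit_pca(pb$F_all, var_target = 0.99)
  cfg <- net_config(epochs = 5L, batch_size = 16L, rng_seed = 9L)
  h1 <- train_surrogate(pb$X, pb$F_all, basis, cfg)$history
  h2 <- train_surrogate(pb$X, pb$F_all, basis, cfg)$history
  expect_identical(h1, h2)

  cfg_bad <- net_config(n_hidden_layers = 3L, epochs = 5L,
                        batch_size = 16L, learning_rate = 1e150,
                        rng_seed = 9L)
  expect_error(train_surrogate(pb$X, pb$F_all, basis, cfg_bad), "diverged")
  expect_error(train_surrogate(pb$X[1:20, ], pb$F_all[1:20, ], basis,
                               net_config(batch_size = 32L)),
               "2 batches")
})

test_that("prediction applies the frozen inverse-PCA stage", {
  pb <- linear_problem(n = 80L)
  basis <- fit_pca(pb$F_all, var_target = 0.99)
  cfg <- net_config(epochs = 3L, batch_size = 16L)
  m <- train_surrogate(pb$X, pb$F_all, basis, cfg)

  # output length equals the node count
  single <- predict(m, pb$X[1L, ])
  expect_length(single, ncol(pb$F_all))

  # zero-weight network predicts the basis column mean
  m0 <- m
  m0$weights <- lapply(m0$weights, function(w) w * 0)
  m0$biases <- lapply(m0$biases, function(b) b * 0)
  expect_equal(as.numeric(predict(m0, pb$X[1L, ])), basis$column_mean,
               tolerance = 1e-12)

  # batch prediction equals row-wise single predictions
  batch <- predict(m, pb$X[1:5, ])
  for (i in 1:5) expect_equal(batch[i, ], predict(m, pb$X[i, ]))
  expect_error(predict(m, pb$X[, 1:2]), "dimension mismatch")
})

test_that("full-field MAE with an identity basis equals direct score MAE", {
  pb <- linear_problem(n = 60L, N = 8L)
  # identity basis: components = I, mean 0, sd 1 -> reconstruction is the
  # identity, so the full-field loss must equal the raw regression MAE
  id_basis <- fit_pca(rbind(diag(8L) * 2, -diag(8L) * 2,
                            matrix(0, 2L, 8L)), fixed_k = 8L)
  id_basis$components <- diag(8L)
  id_basis$column_mean <- rep(0, 8L)
  id_basis$column_sd <- rep(1, 8L)
  cfg <- net_config(epochs = 4L, batch_size = 12L, rng_seed = 3L)
  m <- train_surrogate(pb$X, pb$F_all, id_basis, cfg)
  pred_scores <- predict(m, pb$X, type = "scores")
  pred_fields <- predict(m, pb$X, type = "field")
  expect_equal(pred_scores, pred_fields)
  expect_equal(mean(abs(pred_fields - pb$F_all)),
               utils::tail(m$history$train_loss, 1L), tolerance = 1e-12)
})

test_that("cross-validation balances folds and averages fold losses", {
  pb <- linear_problem(n = 10L, k = 2L, N = 6L)
  cfg <- net_config(epochs = 2L, batch_size = 2L, rng_seed = 5L)
  cv <- cross_validate(pb$X, pb$F_all, cfg, n_folds = 5L, var_target = 0.9)
  folds <- attr(cv, "fold_losses")
  expect_length(folds, 5L)
  expect_equal(as.numeric(cv), mean(folds), tolerance = 1e-12)
  expect_error(cross_validate(pb$X[1:3, ], pb$F_all[1:3, ], cfg,
                              n_folds = 5L),
               "n_folds")

  # constant targets are perfectly learnable
  Fc <- matrix(5, 40L, 6L) + matrix(stats::rnorm(240, sd = 1e-9), 40L)
  Xc <- with_seed(3, matrix(stats::rnorm(80), 40L, 2L))
  cvc <- cross_validate(Xc, Fc,
                        net_config(epochs = 80L, batch_size = 8L,
                                   learning_rate = 5e-3),
                        n_folds = 4L, var_target = 0.5)
  # targets have magnitude 5; "approximately zero" here means < 0.1% of it
  expect_lt(as.numeric(cvc), 5e-3)
})

test_that("hyperparameter search returns the argmin and reproduces itself", {
  pb <- linear_problem(n = 40L, k = 2L, N = 10L)
  space <- list(layers = c(1, 2), neurons = c(8, 32), lr = c(1e-3, 1e-2))
  one <- tune_hyperparameters(pb$X, pb$F_all, space, n_trials = 1L,
                              seed = 2L, n_folds = 4L, var_target = 0.9,
                              batch_size = 8L, epochs = 2L)
  expect_s3_class(one, "net_config")
  expect_identical(nrow(attr(one, "trials")), 1L)

  t5a <- tune_hyperparameters(pb$X, pb$F_all, space, n_trials = 5L,
                              seed = 2L, n_folds = 4L, var_target = 0.9,
                              batch_size = 8L, epochs = 2L)
  t5b <- tune_hyperparameters(pb$X, pb$F_all, space, n_trials = 5L,
                              seed = 2L, n_folds = 4L, var_target = 0.9,
                              batch_size = 8L, epochs = 2L)
  expect_identical(attr(t5a, "trials"), attr(t5b, "trials"))
  trials <- attr(t5a, "trials")
  expect_lte(min(trials$cv_loss), stats::median(trials$cv_loss))
  best <- trials[which.min(trials$cv_loss), ]
  expect_identical(t5a$neurons_per_layer, as.integer(best$neurons))

  tpe <- tune_hyperparameters(pb$X, pb$F_all, space, n_trials = 7L,
                              strategy = "tpe", seed = 3L, n_folds = 4L,
                              var_target = 0.9, batch_size = 8L,
                              epochs = 2L)
  expect_identical(nrow(attr(tpe, "trials")), 7L)
  expect_error(tune_hyperparameters(pb$X, pb$F_all, list(), n_trials = 1L),
               "search space")
})

test_that("prediction is Lipschitz in the input for fixed weights", {
  pb <- linear_problem(n = 80L)
  basis <- fit_pca(pb$F_all, var_target = 0.99)
  m <- train_surrogate(pb$X, pb$F_all, basis,
                       net_config(epochs = 5L, batch_size = 16L))
  # finite-difference bound: ||f(x+h) - f(x)|| <= L ||h|| with L from the
  # product of layer operator norms and the basis scaling
  Lw <- prod(vapply(m$weights, function(w) norm(w, "2"), numeric(1))) *
    norm(diag(m$basis$column_sd) %*% t(m$basis$components), "2")
  x <- pb$X[1L, ]
  for (i in 1:5) {
    h <- with_seed(i, stats::rnorm(length(x), sd = 0.1))
    num <- sqrt(sum((predict(m, x + h) - predict(m, x))^2))
    expect_lte(num, Lw * sqrt(sum(h^2)) * (1 + 1e-10))
  }
})
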