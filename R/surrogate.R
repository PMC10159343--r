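#' Network training configuration
#'
#' Batch size 32 and 50 epochs are the tuning-stage settings; the final
#' training protocol uses more epochs (configurable; paper-scale is 1000).
#'
#' @param n_hidden_layers number of hidden ReLU layers (>= 1).
#' @param neurons_per_layer width of each hidden layer (>= 1).
#' @param learning_rate initial Adam learning rate (> 0).
#' @param batch_size minibatch size (default 32).
#' @param epochs training epochs (default 50).
#' @param rng_seed seed for weight init and batch shuffling.
#' @return An object of class `net_config`.
#' @export
net_config <- function(n_hidden_layers = 2L, neurons_per_layer = 64L,
                       learning_rate = 1e-3, batch_size = 32L,
                       epochs = 50L, rng_seed = 1L) {
  if (n_hidden_layers < 1L || neurons_per_layer < 1L || batch_size < 1L ||
      epochs < 1L) {
    stop("all counts must be >= 1")
  }
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(n_hidden_layers = as.integer(n_hidden_layers),
                 neurons_per_layer = as.integer(neurons_per_layer),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 rng_seed = as.integer(rng_seed)),
            class = "net_config")
}

# Glorot-uniform initialisation of a dense ReLU network
mlp_init <- function(d_in, d_out, cfg) {
  dims <- c(d_in, rep(cfg$neurons_per_layer, cfg$n_hidden_layers), d_out)
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    lim <- sqrt(6 / (dims[l] + dims[l + 1L]))
    W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1L], -lim, lim),
                     dims[l], dims[l + 1L])
    b[[l]] <- rep(0, dims[l + 1L])
  }
  list(W = W, b = b)
}

# forward pass caching activations; hidden layers ReLU, output linear
mlp_forward <- function(par, X) {
  L <- length(par$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% par$W[[l]], 2L, par$b[[l]], `+`)
    A[[l + 1L]] <- if (l < L) pmax(Z, 0) else Z
  }
  A
}

# backprop of dL/d(output scores) through the network
mlp_backward <- function(par, A, dS) {
  L <- length(par$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- dS
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(par$W[[l]])) * (A[[l]] > 0)
    }
  }
  list(W = gW, b = gb)
}

# full-field MAE of predictions reconstructed through the frozen basis
full_field_mae <- function(par, basis, X, F_true) {
  A <- mlp_forward(par, X)
  S_hat <- A[[length(A)]]
  F_hat <- pca_reconstruct(basis, S_hat)
  mean(abs(F_hat - F_true))
}

#' Train a surrogate network
#'
#' Fits a dense ReLU network mapping shape PCA scores to field PCA scores,
#' with a frozen (non-trainable) inverse-PCA reconstruction stage appended so
#' the mean-absolute-error loss is computed on the entire flow field rather
#' than on the score vector — this weights every mode by the variance it
#' explains. Optimised with Adam; deterministic for a fixed
#' `cfg$rng_seed`.
#'
#' @param shape_scores n x k_s matrix of shape mode weights.
#' @param field_matrix n x N matrix of ground-truth fields (the basis must
#'   have been fit on training rows only).
#' @param field_basis the field-space [fit_pca()] basis (frozen).
#' @param cfg a [net_config()].
#' @param validation optional list with `scores` and `fields` for per-epoch
#'   validation loss.
#' @return An object of class `surrogate_model` with the weights, the frozen
#'   basis and a `history` tibble (epoch, train_loss, val_loss).
#' @export
train_surrogate <- function(shape_scores, field_matrix, field_basis, cfg,
                            validation = NULL) {
  X <- as.matrix(shape_scores)
  F_true <- as.matrix(field_matrix)
  n <- nrow(X)
  if (nrow(F_true) != n) stop("shape scores and fields disagree on n")
  if (n < 2L * cfg$batch_size) {
    stop("need at least 2 batches of training subjects")
  }
  k_f <- nrow(field_basis$components)
  N <- ncol(field_basis$components)
  if (ncol(F_true) != N) stop("field matrix does not match the basis")
  sdv <- field_basis$column_sd
  Ct <- t(field_basis$components)

  with_seed(cfg$rng_seed, {
    par <- mlp_init(ncol(X), k_f, cfg)
    adam <- list(
      mW = lapply(par$W, function(w) w * 0),
      vW = lapply(par$W, function(w) w * 0),
      mb = lapply(par$b, function(bb) bb * 0),
      vb = lapply(par$b, function(bb) bb * 0))
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_step <- 0L
    hist_train <- hist_val <- rep(NA_real_, cfg$epochs)
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      for (s0 in starts) {
        rows <- ord[s0:min(s0 + cfg$batch_size - 1L, n)]
        Xb <- X[rows, , drop = FALSE]
        Fb <- F_true[rows, , drop = FALSE]
        A <- mlp_forward(par, Xb)
        S_hat <- A[[length(A)]]
        F_hat <- pca_reconstruct(field_basis, S_hat)
        resid <- F_hat - Fb
        if (anyNA(resid) || any(!is.finite(resid))) {
          stop(sprintf("training diverged (non-finite loss) at epoch %d",
                       epoch))
        }
        dF <- sign(resid) / length(resid)
        dS <- sweep(dF, 2L, sdv, `*`) %*% Ct
        g <- mlp_backward(par, A, dS)
        t_step <- t_step + 1L
        for (l in seq_along(par$W)) {
          adam$mW[[l]] <- beta1 * adam$mW[[l]] + (1 - beta1) * g$W[[l]]
          adam$vW[[l]] <- beta2 * adam$vW[[l]] + (1 - beta2) * g$W[[l]]^2
          adam$mb[[l]] <- beta1 * adam$mb[[l]] + (1 - beta1) * g$b[[l]]
          adam$vb[[l]] <- beta2 * adam$vb[[l]] + (1 - beta2) * g$b[[l]]^2
          mhW <- adam$mW[[l]] / (1 - beta1^t_step)
          vhW <- adam$vW[[l]] / (1 - beta2^t_step)
          mhb <- adam$mb[[l]] / (1 - beta1^t_step)
          vhb <- adam$vb[[l]] / (1 - beta2^t_step)
          par$W[[l]] <- par$W[[l]] - cfg$learning_rate * mhW /
            (sqrt(vhW) + eps)
          par$b[[l]] <- par$b[[l]] - cfg$learning_rate * mhb /
            (sqrt(vhb) + eps)
        }
      }
      hist_train[epoch] <- full_field_mae(par, field_basis, X, F_true)
      if (!is.null(validation)) {
        hist_val[epoch] <- full_field_mae(par, field_basis,
                                          as.matrix(validation$scores),
                                          as.matrix(validation$fields))
      }
    }
    structure(list(
      weights = par$W, biases = par$b, basis = field_basis, config = cfg,
      input_dim = ncol(X), output_dim = k_f,
      history = tibble::tibble(epoch = seq_len(cfg$epochs),
                               train_loss = hist_train,
                               val_loss = hist_val)
    ), class = "surrogate_model")
  })
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf(
    "surrogate_model: %d -> %s -> %d modes -> %d nodes (final loss %.4g)\n",
    x$input_dim,
    paste(rep(x$config$neurons_per_layer, x$config$n_hidden_layers),
          collapse = "-"),
    x$output_dim, ncol(x$basis$components),
    utils::tail(x$history$train_loss, 1L)))
  invisible(x)
}

#' Predict full flow fields from shape scores
#'
#' Forward pass through the trained network followed by the frozen
#' inverse-PCA reconstruction.
#'
#' @param object a [train_surrogate()] model.
#' @param shape_scores length-k_s vector or m x k_s matrix.
#' @param type `"field"` (default, length-N reconstruction) or `"scores"`
#'   (raw network output).
#' @param ... unused.
#' @return A vector (single subject) or matrix (row per subject).
#' @export
predict.surrogate_model <- function(object, shape_scores,
                                    type = c("field", "scores"), ...) {
  type <- match.arg(type)
  X <- row_matrix(shape_scores, object$input_dim)
  A <- mlp_forward(list(W = object$weights, b = object$biases), X)
  S_hat <- A[[length(A)]]
  out <- if (type == "scores") S_hat else pca_reconstruct(object$basis, S_hat)
  if (is.null(dim(shape_scores))) out[1L, ] else out
}

#' K-fold cross-validation of a surrogate configuration
#'
#' Deterministic seeded fold assignment with floor-balanced folds (sizes
#' differ by at most one). For every fold the field basis is refit on the
#' training rows only, the network trained, and the full-field MAE measured
#' on the held-out fold; the mean of the fold losses is returned.
#'
#' @param shape_scores n x k_s matrix.
#' @param field_matrix n x N matrix.
#' @param cfg a [net_config()].
#' @param n_folds number of folds (default 5).
#' @param var_target,fixed_k mode rule for the per-fold field basis.
#' @return Mean validation loss (attribute `fold_losses` has the per-fold
#'   values).
#' @export
cross_validate <- function(shape_scores, field_matrix, cfg, n_folds = 5L,
                           var_target = 0.99, fixed_k = NULL) {
  X <- as.matrix(shape_scores)
  F_true <- as.matrix(field_matrix)
  n <- nrow(X)
  if (n < n_folds) stop("need at least n_folds subjects")
  fold <- with_seed(cfg$rng_seed, {
    sample(rep_len(seq_len(n_folds), n))
  })
  losses <- vapply(seq_len(n_folds), function(f) {
    tr <- fold != f
    basis <- fit_pca(F_true[tr, , drop = FALSE], var_target = var_target,
                     fixed_k = fixed_k)
    model <- train_surrogate(X[tr, , drop = FALSE],
                             F_true[tr, , drop = FALSE], basis, cfg)
    full_field_mae(list(W = model$weights, b = model$biases), basis,
                   X[!tr, , drop = FALSE], F_true[!tr, , drop = FALSE])
  }, numeric(1))
  out <- mean(losses)
  attr(out, "fold_losses") <- losses
  out
}

#' Hyperparameter search over network configurations
#'
#' Evaluates candidate configurations (hidden layers, width, learning rate)
#' by [cross_validate()] and returns the argmin. Candidates are drawn either
#' uniformly at random (reference strategy) or by a light tree-structured
#' Parzen estimator: after a random start-up phase, candidates are sampled
#' from a kernel density over the best-quartile trials and ranked by the
#' good/bad density ratio.
#'
#' @param shape_scores,field_matrix training data.
#' @param search_space list with ranges `layers = c(lo, hi)`,
#'   `neurons = c(lo, hi)` (log-spaced), `lr = c(lo, hi)` (log-uniform).
#' @param n_trials number of configurations to evaluate (>= 1).
#' @param strategy `"random"` (default) or `"tpe"`.
#' @param seed RNG seed for the trial sequence.
#' @param n_folds folds for the inner cross-validation.
#' @param var_target,fixed_k field-basis mode rule.
#' @param batch_size,epochs,... fixed settings forwarded to [net_config()].
#' @return The best [net_config()]; attribute `trials` is the tibble of all
#'   evaluated configurations and their CV losses.
#' @export
tune_hyperparameters <- function(shape_scores, field_matrix,
                                 search_space = list(layers = c(1, 4),
                                                     neurons = c(16, 256),
                                                     lr = c(1e-4, 1e-2)),
                                 n_trials = 20L,
                                 strategy = c("random", "tpe"),
                                 seed = 1L, n_folds = 5L,
                                 var_target = 0.99, fixed_k = NULL,
                                 batch_size = 32L, epochs = 50L) {
  strategy <- match.arg(strategy)
  if (n_trials < 1L) stop("n_trials must be >= 1")
  if (!all(c("layers", "neurons", "lr") %in% names(search_space))) {
    stop("search space must give layers, neurons and lr ranges")
  }
  n_startup <- min(n_trials, 5L)
  trials <- tibble::tibble(trial = integer(), layers = integer(),
                           neurons = integer(), lr = numeric(),
                           cv_loss = numeric())
  draw_random <- function() {
    layer_choices <- seq(search_space$layers[1L], search_space$layers[2L])
    list(layers = layer_choices[sample.int(length(layer_choices), 1L)],
         neurons = round(exp(stats::runif(1, log(search_space$neurons[1L]),
                                          log(search_space$neurons[2L])))),
         lr = exp(stats::runif(1, log(search_space$lr[1L]),
                               log(search_space$lr[2L]))))
  }
  draw_tpe <- function(done) {
    gamma_n <- max(1L, floor(0.25 * nrow(done)))
    good <- done[order(done$cv_loss), ][seq_len(gamma_n), ]
    bad <- done[order(done$cv_loss), ][-seq_len(gamma_n), ]
    cand <- lapply(seq_len(16L), function(i) {
      g <- good[sample.int(nrow(good), 1L), ]
      list(layers = min(max(g$layers + sample(-1:1, 1L),
                            search_space$layers[1L]),
                        search_space$layers[2L]),
           neurons = min(max(round(g$neurons *
                                     exp(stats::rnorm(1, 0, 0.25))),
                             search_space$neurons[1L]),
                         search_space$neurons[2L]),
           lr = min(max(g$lr * exp(stats::rnorm(1, 0, 0.5)),
                        search_space$lr[1L]), search_space$lr[2L]))
    })
    dens <- function(set, c_) {
      if (!nrow(set)) return(1e-12)
      mean(stats::dnorm(log(c_$lr), log(set$lr), 0.5)) *
        mean(stats::dnorm(log(c_$neurons), log(set$neurons), 0.35)) *
        mean(stats::dnorm(c_$layers, set$layers, 0.75))
    }
    score <- vapply(cand, function(c_) dens(good, c_) /
                      max(dens(bad, c_), 1e-12), numeric(1))
    cand[[which.max(score)]]
  }
  with_seed(seed, {
    for (tr in seq_len(n_trials)) {
      c_ <- if (strategy == "tpe" && tr > n_startup) draw_tpe(trials)
            else draw_random()
      cfg <- net_config(n_hidden_layers = c_$layers,
                        neurons_per_layer = c_$neurons,
                        learning_rate = c_$lr, batch_size = batch_size,
                        epochs = epochs, rng_seed = seed)
      loss <- cross_validate(shape_scores, field_matrix, cfg,
                             n_folds = n_folds, var_target = var_target,
                             fixed_k = fixed_k)
      trials <- rbind(trials,
                      tibble::tibble(trial = tr, layers = c_$layers,
                                     neurons = c_$neurons, lr = c_$lr,
                                     cv_loss = as.numeric(loss)))
    }
  })
  best <- trials[which.min(trials$cv_loss), ]
  out <- net_config(n_hidden_layers = best$layers,
                    neurons_per_layer = best$neurons,
                    learning_rate = best$lr, batch_size = batch_size,
                    epochs = epochs, rng_seed = seed)
  attr(out, "trials") <- trials
  out
}
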