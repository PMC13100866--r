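#' Selector-network configuration
#'
#' Architecture and training hyperparameters for the network that maps a
#' noisy decay directly to a regularization weight, trained against bilevel
#' oracle labels with the L1 loss (robust to the heavy right tail of the
#' oracle distribution, which spans several orders of magnitude). The
#' default is a four-layer 1-D convolutional feature extractor over the
#' echo dimension followed by a dense head with a softplus (nonnegative)
#' scalar output; predictions are on the raw lambda scale to match the L1
#' training objective (a log-scale variant is available but off by default).
#'
#' @param n_conv_layers Number of conv layers (default 4).
#' @param channels Output channels per conv layer (recycled to
#'   `n_conv_layers`).
#' @param kernel Odd conv kernel width.
#' @param pool_after Indices of conv layers followed by average pooling
#'   (factor 2); pooling bounds the flattened width, the main overfitting
#'   lever at desk-scale training sizes.
#' @param hidden Width of the dense layer after flattening.
#' @param activation Activation for conv and dense layers.
#' @param epochs,batch_size,lr Training hyperparameters.
#' @param weight_decay Decoupled L2 weight decay.
#' @param early_stopping Keep the best-validation-epoch weights.
#' @param seed Seed controlling initialization and shuffling.
#' @param log_scale Train/predict on `log10(lambda)` instead of raw lambda.
#' @param val_fraction Held-out fraction used for the skill check (and for
#'   early stopping).
#' @return A `lambda_net_config` list.
#' @export
lambda_net_config <- function(n_conv_layers = 4L, channels = c(8, 8, 16, 16),
                              kernel = 5L, pool_after = c(1L, 2L),
                              hidden = 32L, activation = "relu",
                              epochs = 120L, batch_size = 64L, lr = 1e-3,
                              weight_decay = 1e-4, early_stopping = TRUE,
                              seed = 1L, log_scale = FALSE,
                              val_fraction = 0.15) {
  channels <- rep_len(channels, n_conv_layers)
  structure(list(n_conv_layers = as.integer(n_conv_layers), channels = channels,
                 kernel = as.integer(kernel),
                 pool_after = as.integer(pool_after),
                 hidden = as.integer(hidden),
                 activation = activation, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay,
                 early_stopping = isTRUE(early_stopping),
                 seed = as.integer(seed), log_scale = isTRUE(log_scale),
                 val_fraction = val_fraction),
            class = "lambda_net_config")
}

#' Compute and attach bilevel oracle labels to a dataset
#'
#' Runs [lambda_oracle()] for every signal (an expensive sweep; labels are
#' computed once and carried with the dataset).
#'
#' @param dataset A `signal_dataset`.
#' @param control A [fit_control()].
#' @param progress Print a dot every `progress` signals (0 = silent).
#' @return The dataset with fields `oracle_lambda` (numeric vector) and
#'   `oracle_fits` (list of `fit_result` at the oracle lambda).
#' @export
attach_oracle_labels <- function(dataset, control = fit_control(dataset$schedule),
                                 progress = 0L) {
  n <- nrow(dataset$signals)
  lam <- numeric(n)
  fits <- vector("list", n)
  for (i in seq_len(n)) {
    sel <- lambda_oracle(dataset$signals[i, ], dataset$params[i, ], control)
    lam[i] <- sel$lambda
    fits[[i]] <- sel$fit
    if (progress > 0L && i %% progress == 0L) cat(".")
  }
  if (progress > 0L) cat("\n")
  dataset$oracle_lambda <- lam
  dataset$oracle_fits <- fits
  dataset
}

#' Train the lambda-selector network
#'
#' Fits the surrogate map from noisy signal to oracle regularization weight
#' by minimizing the mean absolute error against precomputed oracle labels.
#' A held-out split is scored against the best constant predictor (the label
#' median, which is L1-optimal among constants); a selector that cannot beat
#' that baseline has learned nothing signal-dependent and is rejected.
#'
#' @param train A `signal_dataset` with `oracle_lambda` labels (see
#'   [attach_oracle_labels()]), or a list with `signals` and
#'   `oracle_lambda`.
#' @param config A [lambda_net_config()].
#' @param reject_if_no_skill Error when the held-out L1 does not beat the
#'   median baseline (default TRUE).
#' @return A `lambda_selector`: list with the trained network, config,
#'   training history, `val_l1`, `baseline_l1` and `skillful` flag.
#' @export
train_lambda_net <- function(train, config = lambda_net_config(),
                             reject_if_no_skill = TRUE) {
  X <- train$signals
  y <- train$oracle_lambda
  if (is.null(y)) stop("training dataset has no oracle_lambda labels")
  if (is.null(X) || nrow(X) == 0L) stop("empty training dataset")
  if (anyNA(y) || anyNA(X)) stop("NA in training data")
  Y <- matrix(if (config$log_scale) log10(y) else y, ncol = 1L)
  n <- nrow(X)
  set.seed(config$seed)
  n_val <- max(2L, round(config$val_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  layers <- list()
  for (i in seq_len(config$n_conv_layers)) {
    layers <- c(layers, list(layer_conv1d(config$channels[i], config$kernel,
                                          config$activation)))
    if (i %in% config$pool_after) layers <- c(layers, list(layer_avgpool1d(2L)))
  }
  layers <- c(layers,
              list(layer_flatten(),
                   layer_dense(config$hidden, config$activation),
                   layer_dense(1L, "linear")),
              if (!config$log_scale) list(layer_nonneg_head()))
  net <- build_network(c(ncol(X), 1L), layers, seed = config$seed)
  net <- nn_train(net, X[tr_idx, , drop = FALSE], Y[tr_idx, , drop = FALSE],
                  loss = loss_l1(), epochs = config$epochs,
                  batch_size = config$batch_size, lr = config$lr,
                  weight_decay = config$weight_decay,
                  early_stopping = config$early_stopping, seed = config$seed,
                  X_val = X[val_idx, , drop = FALSE],
                  Y_val = Y[val_idx, , drop = FALSE])
  pred_val <- nn_forward(net, X[val_idx, , drop = FALSE])$out[, 1L]
  if (config$log_scale) pred_val <- 10^pred_val
  val_l1 <- mean(abs(pred_val - y[val_idx]))
  baseline_l1 <- mean(abs(stats::median(y[tr_idx]) - y[val_idx]))
  skillful <- val_l1 < baseline_l1
  if (reject_if_no_skill && !skillful)
    stop(sprintf(
      "selector rejected: held-out L1 %.4g does not beat median baseline %.4g",
      val_l1, baseline_l1))
  structure(list(net = net, config = config, history = net$history,
                 n_echoes = ncol(X), val_l1 = val_l1,
                 baseline_l1 = baseline_l1, skillful = skillful),
            class = "lambda_selector")
}

#' @export
print.lambda_selector <- function(x, ...) {
  cat(sprintf("<lambda_selector> %d conv layers, held-out L1 = %.4g (median baseline %.4g)\n",
              x$config$n_conv_layers, x$val_l1, x$baseline_l1))
  invisible(x)
}

#' Predict the regularization weight with a trained selector
#'
#' A single forward pass per signal; unlike the oracle and GCV selectors no
#' grid search is needed at inference time.
#'
#' @param selector A `lambda_selector` from [train_lambda_net()].
#' @param s A `decay_signal`, a numeric signal vector, or a matrix with one
#'   signal per row.
#' @return For a single signal, a `lambda_selection` with
#'   `method = "network"`; for a matrix, a numeric vector of lambdas.
#' @export
predict_lambda <- function(selector, s) {
  stopifnot(inherits(selector, "lambda_selector"))
  batch <- is.matrix(s)
  X <- if (batch) s else matrix(signal_values(s), nrow = 1L)
  if (ncol(X) != selector$n_echoes)
    stop(sprintf("signal length %d does not match the %d echoes seen in training",
                 ncol(X), selector$n_echoes))
  lam <- nn_forward(selector$net, X)$out[, 1L]
  if (selector$config$log_scale) lam <- 10^lam
  if (batch) return(lam)
  new_lambda_selection(lam, "network", objective_value = NA_real_)
}
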