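#' Build the concatenated ILR input for one signal
#'
#' Input layer regularization feeds the parameter-estimation network the
#' noisy signal concatenated with a clean curve synthesized from its
#' regularized fit: \eqn{x = [s;\ G(p^*_{\lambda(s)}(s))]}. The first half
#' is the measurement untouched; the second half is a forward-model
#' evaluation, hence monotone and noiseless.
#'
#' @param s A `decay_signal` or numeric signal vector.
#' @param selection A `lambda_selection` for this signal (oracle, GCV or
#'   network); its cached inner fit is reused when it matches.
#' @param control A [fit_control()].
#' @return A `concat_input`: list with `values` (length 2N), `lambda_used`,
#'   `method` (the selection provenance tag).
#' @export
build_concat_input <- function(s, selection, control = fit_control()) {
  v <- signal_values(s)
  fit <- selection$fit
  if (is.null(fit) || !identical(fit$lambda, selection$lambda)) {
    fit <- tr_nlls_fit(v, selection$lambda, control)
  }
  if (!fit$converged) {
    # retry with a larger iteration budget before declaring failure; a
    # maxed-out solve with a finite objective still defines the curve
    control_retry <- control
    control_retry$maxiter <- 4L * control$maxiter
    fit2 <- tr_nlls_fit(v, selection$lambda, control_retry)
    if (fit2$objective <= fit$objective) fit <- fit2
  }
  if (!is.finite(fit$objective))
    stop(sprintf("inner fit at lambda = %g failed (objective %.4g)",
                 selection$lambda, fit$objective))
  reg <- biexp_curve(fit$params, control$schedule$times)
  structure(list(values = c(v, reg), lambda_used = selection$lambda,
                 method = selection$method),
            class = "concat_input")
}

#' Duplicated-input variant for the no-ILR reference network
#'
#' Concatenates the noisy signal with itself, giving the (ND, ND) network
#' an input of the same length as the ILR networks so that input size is
#' not a confounder in comparisons.
#'
#' @inheritParams build_concat_input
#' @return A `concat_input` with `method = "duplicate"`.
#' @export
duplicate_input <- function(s) {
  v <- signal_values(s)
  structure(list(values = c(v, v), lambda_used = NA_real_,
                 method = "duplicate"),
            class = "concat_input")
}

#' B-weighted squared-error loss between parameter batches
#'
#' Mean over the batch of \eqn{(\hat p - p)^\top B (\hat p - p)} with B the
#' diagonal scale matrix equalizing the fraction and relaxation-time scales.
#' With B the identity this is 3x the plain MSE.
#'
#' @param pred,true Matrices with rows `(c1, T2_1, T2_2)` (or single
#'   triples).
#' @param B Length-3 positive diagonal, default `c(100, 1, 1)`.
#' @return Scalar loss.
#' @export
weighted_param_loss <- function(pred, true, B = c(100, 1, 1)) {
  if (is.null(dim(pred))) pred <- matrix(pred, nrow = 1L)
  if (is.null(dim(true))) true <- matrix(true, nrow = 1L)
  if (!all(dim(pred) == dim(true)))
    stop("prediction and truth batches have mismatched shapes")
  D <- pred - true
  mean(D^2 %*% B)
}

#' Combined weighted-MSE + Wasserstein-1 loss between parameter batches
#'
#' The benchmark loss of the model-informed estimator: adds to
#' [weighted_param_loss()] a distributional term, `weight` times the sum
#' over the three parameters of the 1-D Wasserstein-1 distance between the
#' batch-empirical distributions of predictions and truths. The W1 term is
#' invariant under permutations of the batch.
#'
#' @inheritParams weighted_param_loss
#' @param weight Mixing coefficient on the W1 term.
#' @return Scalar loss.
#' @export
mi_ml_loss <- function(pred, true, weight = 1, B = c(100, 1, 1)) {
  if (is.null(dim(pred))) pred <- matrix(pred, nrow = 1L)
  if (is.null(dim(true))) true <- matrix(true, nrow = 1L)
  if (!all(dim(pred) == dim(true)))
    stop("prediction and truth batches have mismatched shapes")
  if (nrow(pred) < 2L)
    stop("mi_ml_loss needs a batch of at least 2 (distributional term)")
  w1 <- sum(vapply(seq_len(ncol(pred)),
                   function(j) wasserstein1_1d(pred[, j], true[, j]),
                   numeric(1L)))
  weighted_param_loss(pred, true, B) + weight * w1
}

#' Parameter-estimation network configuration
#'
#' @param hidden Hidden layer widths (default four layers of 256).
#' @param activation Hidden activation.
#' @param loss `"weighted_mse"` (the B-weighted loss) or `"mi_ml"`.
#' @param mi_ml_weight Mixing coefficient for the `"mi_ml"` loss.
#' @param B Length-3 diagonal of the loss scale matrix.
#' @param t2_scale Softplus output scale for the relaxation times (ms).
#' @param epochs,batch_size,lr,lr_decay Training hyperparameters.
#' @param seed Seed controlling initialization and shuffling.
#' @return A `pe_net_config` list.
#' @export
pe_net_config <- function(hidden = c(256, 256, 256, 256), activation = "relu",
                          loss = c("weighted_mse", "mi_ml"), mi_ml_weight = 1,
                          B = c(100, 1, 1), t2_scale = 100,
                          epochs = 200L, batch_size = 64L, lr = 1e-3,
                          lr_decay = 1, seed = 1L) {
  loss <- match.arg(loss)
  structure(list(hidden = hidden, activation = activation, loss = loss,
                 mi_ml_weight = mi_ml_weight, B = as.numeric(B),
                 t2_scale = t2_scale, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_decay = lr_decay, seed = as.integer(seed)),
            class = "pe_net_config")
}

concat_matrix <- function(inputs) {
  if (is.matrix(inputs)) return(inputs)
  if (inherits(inputs, "concat_input")) return(matrix(inputs$values, nrow = 1L))
  do.call(rbind, lapply(inputs, function(x) x$values))
}

#' Train a parameter-estimation network on concatenated inputs
#'
#' Fully connected network from the length-2N concatenated input to the
#' constrained parameter triple (sigmoid fraction, softplus relaxation
#' times), trained with the B-weighted MSE loss or the MSE+W1 combination.
#' The input variant ((ND, ND) duplication or (ND, Reg) with a given
#' lambda-selection method) is recorded and enforced at prediction time.
#'
#' @param inputs A matrix with one length-2N concatenated input per row, or
#'   a list of `concat_input` objects.
#' @param params Matrix of generating parameter triples (rows aligned with
#'   `inputs`), in canonical order.
#' @param config A [pe_net_config()].
#' @param variant Input variant tag: `"ndnd"`, `"ndreg_gcv"`,
#'   `"ndreg_network"`, or `"ndreg_oracle"`.
#' @param X_val,P_val Optional held-out inputs/params scored each epoch.
#' @return A `pe_estimator`: trained network plus config, variant and
#'   training history.
#' @export
train_pe_network <- function(inputs, params, config = pe_net_config(),
                             variant = c("ndnd", "ndreg_gcv", "ndreg_network",
                                         "ndreg_oracle"),
                             X_val = NULL, P_val = NULL) {
  variant <- match.arg(variant)
  X <- concat_matrix(inputs)
  P <- as.matrix(params)
  if (nrow(X) == 0L) stop("empty training set")
  if (nrow(X) != nrow(P)) stop("inputs and params are not index-aligned")
  loss <- if (config$loss == "mi_ml") {
    loss_mi_ml(config$B, config$mi_ml_weight)
  } else {
    loss_weighted_mse(config$B)
  }
  layers <- c(lapply(config$hidden, function(h) layer_dense(h, config$activation)),
              list(layer_dense(3L, "linear"), layer_pe_head(config$t2_scale)))
  net <- build_network(ncol(X), layers, seed = config$seed)
  net <- nn_train(net, X, P, loss = loss, epochs = config$epochs,
                  batch_size = config$batch_size, lr = config$lr,
                  lr_decay = config$lr_decay, seed = config$seed,
                  X_val = if (is.null(X_val)) NULL else concat_matrix(X_val),
                  Y_val = if (is.null(P_val)) NULL else as.matrix(P_val))
  structure(list(net = net, config = config, variant = variant,
                 input_width = ncol(X), history = net$history),
            class = "pe_estimator")
}

#' @export
print.pe_estimator <- function(x, ...) {
  cat(sprintf("<pe_estimator> variant %s, input width %d, %d hidden layers\n",
              x$variant, x$input_width, length(x$config$hidden)))
  invisible(x)
}

variant_of_method <- function(method) {
  switch(method,
         duplicate = "ndnd",
         gcv = "ndreg_gcv",
         network = "ndreg_network",
         oracle = "ndreg_oracle",
         stop("unknown concat method: ", method))
}

#' Estimate the parameter triple with a trained network
#'
#' @param estimator A `pe_estimator`.
#' @param x A `concat_input` (variant checked against the estimator), a
#'   numeric length-2N vector, or a matrix of such rows.
#' @return For a single input, a [biexp_params()] triple (canonical order);
#'   for a matrix, an n x 3 matrix of canonical triples.
#' @export
estimate_params <- function(estimator, x) {
  stopifnot(inherits(estimator, "pe_estimator"))
  if (inherits(x, "concat_input")) {
    if (!identical(variant_of_method(x$method), estimator$variant))
      stop(sprintf("input variant %s does not match estimator variant %s",
                   variant_of_method(x$method), estimator$variant))
    x <- matrix(x$values, nrow = 1L)
    single <- TRUE
  } else if (is.null(dim(x))) {
    x <- matrix(x, nrow = 1L)
    single <- TRUE
  } else single <- FALSE
  if (ncol(x) != estimator$input_width)
    stop(sprintf("input width %d does not match estimator width %d",
                 ncol(x), estimator$input_width))
  P <- nn_forward(estimator$net, x)$out
  colnames(P) <- c("c1", "T2_1", "T2_2")
  swap <- P[, "T2_1"] > P[, "T2_2"]
  if (any(swap)) {
    tmp <- P[swap, "T2_1"]
    P[swap, "T2_1"] <- P[swap, "T2_2"]
    P[swap, "T2_2"] <- tmp
    P[swap, "c1"] <- 1 - P[swap, "c1"]
  }
  if (single) biexp_params(P[1L, 1L], P[1L, 2L], P[1L, 3L]) else P
}

#' Build ILR (or duplicated) inputs for every signal of a dataset
#'
#' The batch workhorse behind training and benchmarking: selects lambda per
#' signal by the requested method, runs the regularized fit, and stacks the
#' concatenated inputs.
#'
#' @param dataset A `signal_dataset`.
#' @param method `"ndnd"` (duplication, no fits), `"gcv"`, `"network"`, or
#'   `"oracle"` (training data only; uses the stored labels when present).
#' @param control A [fit_control()].
#' @param selector A `lambda_selector`, required for `method = "network"`.
#' @param lambdas Optional precomputed per-signal lambdas overriding the
#'   selection step (fits still run at these values).
#' @param progress Print a dot every `progress` signals (0 = silent).
#' @return List with `X` (n x 2N matrix), `lambdas`, `variant`.
#' @export
build_ilr_inputs <- function(dataset, method = c("ndnd", "gcv", "network", "oracle"),
                             control = fit_control(dataset$schedule),
                             selector = NULL, lambdas = NULL, progress = 0L) {
  method <- match.arg(method)
  S <- dataset$signals
  n <- nrow(S)
  if (method == "ndnd") {
    return(list(X = cbind(S, S), lambdas = rep(NA_real_, n), variant = "ndnd"))
  }
  if (method == "network" && is.null(lambdas)) {
    if (is.null(selector))
      stop("method = 'network' needs a trained selector or precomputed lambdas")
    lambdas <- predict_lambda(selector, S)
  }
  if (method == "oracle" && is.null(lambdas)) lambdas <- dataset$oracle_lambda
  X <- matrix(0, n, 2L * ncol(S))
  lam_out <- numeric(n)
  for (i in seq_len(n)) {
    sel <- if (!is.null(lambdas)) {
      fit <- if (method == "oracle" && !is.null(dataset$oracle_fits))
        dataset$oracle_fits[[i]] else NULL
      new_lambda_selection(lambdas[i],
                           method = if (method == "network") "network" else method,
                           objective_value = NA_real_, fit = fit)
    } else if (method == "gcv") {
      lambda_gcv(S[i, ], control)
    } else {
      lambda_oracle(S[i, ], dataset$params[i, ], control)
    }
    ci <- build_concat_input(S[i, ], sel, control)
    X[i, ] <- ci$values
    lam_out[i] <- sel$lambda
    if (progress > 0L && i %% progress == 0L) cat(".")
  }
  if (progress > 0L) cat("\n")
  list(X = X, lambdas = lam_out, variant = variant_of_method(
    if (method == "network") "network" else method))
}
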