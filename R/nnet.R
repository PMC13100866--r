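#' @name nnet_engine
#' @title Compact feed-forward network engine
#'
#' @description
#' A small, fully deterministic neural-network engine used by the two
#' learned components of the pipeline: the scalar selector network mapping a
#' noisy decay to a regularization weight, and the parameter-estimation
#' networks mapping concatenated inputs to the biexponential triple. It
#' supports dense and 1-D convolutional layers, ReLU/tanh activations,
#' range-constraining output heads (sigmoid for the fraction, scaled
#' softplus for relaxation times and for the nonnegative scalar weight),
#' mini-batch Adam, and three losses: mean absolute error, B-weighted mean
#' squared error, and the weighted-MSE + Wasserstein-1 combination. All
#' randomness (initialization, shuffling) is driven by explicit seeds.
#' @keywords internal
NULL

softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))
sigmoid <- function(z) 1 / (1 + exp(-z))

activate <- function(z, act) {
  switch(act,
         relu = pmax(z, 0),
         tanh = tanh(z),
         linear = z,
         stop("unknown activation: ", act))
}

activate_grad <- function(z, act) {
  switch(act,
         relu = (z > 0) * 1,
         tanh = 1 - tanh(z)^2,
         linear = array(1, dim(z)) )
}

#' Dense layer spec
#' @param units Output width.
#' @param activation One of "relu", "tanh", "linear".
#' @return Layer spec for [build_network()].
#' @export
layer_dense <- function(units, activation = "relu") {
  list(type = "dense", units = as.integer(units), activation = activation)
}

#' 1-D convolution layer spec (stride 1, zero "same" padding, odd kernel)
#' @param filters Output channels.
#' @param kernel Odd kernel width.
#' @param activation One of "relu", "tanh", "linear".
#' @return Layer spec for [build_network()].
#' @export
layer_conv1d <- function(filters, kernel = 5L, activation = "relu") {
  if (kernel %% 2L == 0L) stop("kernel width must be odd")
  list(type = "conv1d", filters = as.integer(filters),
       kernel = as.integer(kernel), activation = activation)
}

#' Flatten a (length x channels) sequence into a feature vector
#' @return Layer spec for [build_network()].
#' @export
layer_flatten <- function() list(type = "flatten")

#' Non-overlapping average pooling along the sequence axis
#' @param factor Pooling window (must divide the current length).
#' @return Layer spec for [build_network()].
#' @export
layer_avgpool1d <- function(factor = 2L) {
  list(type = "avgpool1d", factor = as.integer(factor))
}

#' Output head constraining the parameter triple to the feasible set
#'
#' Maps 3 raw outputs to `(sigmoid, floor + scale * softplus,
#' floor + scale * softplus)` so that estimates satisfy `0 <= c1 <= 1` and
#' `T2 > 0` without post-hoc clipping.
#' @param t2_scale Softplus scale for the relaxation-time outputs (ms).
#' @param t2_floor Additive floor keeping T2 strictly positive.
#' @return Layer spec for [build_network()].
#' @export
layer_pe_head <- function(t2_scale = 100, t2_floor = 1e-3) {
  list(type = "pe_head", t2_scale = t2_scale, t2_floor = t2_floor)
}

#' Nonnegative scalar output head (softplus)
#' @return Layer spec for [build_network()].
#' @export
layer_nonneg_head <- function() list(type = "nonneg_head")

init_matrix <- function(nin, nout, act) {
  sd <- if (identical(act, "relu")) sqrt(2 / nin) else sqrt(1 / nin)
  matrix(stats::rnorm(nin * nout, 0, sd), nin, nout)
}

#' Assemble a network from layer specs
#'
#' @param input Either an integer feature width (dense input) or
#'   `c(length, channels)` for a sequence input feeding conv layers.
#' @param layers List of layer specs ([layer_dense()], [layer_conv1d()],
#'   [layer_flatten()], [layer_pe_head()], [layer_nonneg_head()]).
#' @param seed Seed for weight initialization.
#' @return An object of class `ff_network`.
#' @export
build_network <- function(input, layers, seed = 1L) {
  set.seed(seed)
  if (length(input) == 1L) {
    mode <- "matrix"; width <- as.integer(input); L <- NA_integer_; C <- NA_integer_
  } else {
    mode <- "seq"; L <- as.integer(input[1L]); C <- as.integer(input[2L]); width <- NA_integer_
  }
  built <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    sp <- layers[[i]]
    if (sp$type == "dense") {
      if (mode != "matrix") stop("dense layer needs flattened input")
      sp$W <- init_matrix(width, sp$units, sp$activation)
      sp$b <- numeric(sp$units)
      width <- sp$units
    } else if (sp$type == "conv1d") {
      if (mode != "seq") stop("conv1d layer needs a sequence input")
      fan_in <- C * sp$kernel
      sd <- if (identical(sp$activation, "relu")) sqrt(2 / fan_in) else sqrt(1 / fan_in)
      sp$W <- lapply(seq_len(sp$kernel), function(j)
        matrix(stats::rnorm(C * sp$filters, 0, sd), C, sp$filters))
      sp$b <- numeric(sp$filters)
      C <- sp$filters
    } else if (sp$type == "avgpool1d") {
      if (mode != "seq") stop("avgpool1d needs a sequence input")
      if (L %% sp$factor != 0L) stop("pooling factor must divide the length")
      L <- L %/% sp$factor
    } else if (sp$type == "flatten") {
      if (mode != "seq") stop("flatten needs a sequence input")
      mode <- "matrix"; width <- L * C
    } else if (sp$type %in% c("pe_head", "nonneg_head")) {
      if (mode != "matrix") stop("output head needs flattened input")
      need <- if (sp$type == "pe_head") 3L else 1L
      if (width != need)
        stop(sprintf("%s expects %d inputs, got %d", sp$type, need, width))
    } else stop("unknown layer type: ", sp$type)
    built[[i]] <- sp
  }
  structure(list(layers = built, input = input,
                 out_width = if (is.na(width)) L * C else width),
            class = "ff_network")
}

# Sequence activations are stored as a (batch*L) x channels matrix in
# column-major (batch fastest) order, so a shift along the echo axis is a
# contiguous row offset of batch rows and each kernel tap is one BLAS
# product.
conv1d_forward <- function(X, sp, batch, L) {
  c_out <- sp$filters
  k <- sp$kernel; pad <- (k - 1L) %/% 2L
  Z <- matrix(sp$b, batch * L, c_out, byrow = TRUE)
  for (j in seq_len(k)) {
    shift <- j - 1L - pad
    y1 <- max(1L, 1L - shift); y2 <- min(L, L - shift)
    if (y1 > y2) next
    ry <- ((y1 - 1L) * batch + 1L):(y2 * batch)
    Z[ry, ] <- Z[ry, ] + X[ry + shift * batch, , drop = FALSE] %*% sp$W[[j]]
  }
  Z
}

conv1d_backward <- function(X, dZ, sp, batch, L) {
  c_in <- ncol(X); c_out <- sp$filters
  k <- sp$kernel; pad <- (k - 1L) %/% 2L
  dX <- matrix(0, batch * L, c_in)
  dW <- vector("list", k)
  for (j in seq_len(k)) {
    shift <- j - 1L - pad
    y1 <- max(1L, 1L - shift); y2 <- min(L, L - shift)
    if (y1 > y2) { dW[[j]] <- matrix(0, c_in, c_out); next }
    ry <- ((y1 - 1L) * batch + 1L):(y2 * batch)
    rx <- ry + shift * batch
    G <- dZ[ry, , drop = FALSE]
    dW[[j]] <- crossprod(X[rx, , drop = FALSE], G)
    dX[rx, ] <- dX[rx, ] + G %*% t(sp$W[[j]])
  }
  list(dX = dX, dW = dW, db = colSums(dZ))
}

# forward pass; returns output and per-layer caches for backprop
nn_forward <- function(net, X, keep_cache = FALSE) {
  batch <- nrow(X)
  seq_mode <- length(net$input) > 1L
  cur_L <- if (seq_mode) net$input[1L] else NA_integer_
  if (seq_mode) {
    # (batch, L*C) -> (batch*L, C), batch fastest
    dim(X) <- NULL
    X <- matrix(X, batch * cur_L)
  }
  caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  A <- X
  for (i in seq_along(net$layers)) {
    sp <- net$layers[[i]]
    if (sp$type == "dense") {
      Z <- sweep(A %*% sp$W, 2L, sp$b, "+")
      out <- activate(Z, sp$activation)
      if (keep_cache) caches[[i]] <- list(A = A, Z = Z)
    } else if (sp$type == "conv1d") {
      Z <- conv1d_forward(A, sp, batch, cur_L)
      out <- activate(Z, sp$activation)
      if (keep_cache) caches[[i]] <- list(A = A, Z = Z, L = cur_L)
    } else if (sp$type == "avgpool1d") {
      f <- sp$factor
      # (batch*L, C) -> (batch, f, L/f, C) average over the window axis
      out <- A
      dim(out) <- c(batch, f, cur_L %/% f, ncol(A))
      out <- colMeans(aperm(out, c(2L, 1L, 3L, 4L)))
      dim(out) <- c(batch * (cur_L %/% f), ncol(A))
      if (keep_cache) caches[[i]] <- list(L = cur_L, C = ncol(A))
      cur_L <- cur_L %/% f
    } else if (sp$type == "flatten") {
      out <- A
      dim(out) <- c(batch, cur_L * ncol(A))
      if (keep_cache) caches[[i]] <- list(ncol_in = ncol(A), L = cur_L)
    } else if (sp$type == "pe_head") {
      s1 <- sigmoid(A[, 1L])
      out <- cbind(s1,
                   sp$t2_floor + sp$t2_scale * softplus(A[, 2L]),
                   sp$t2_floor + sp$t2_scale * softplus(A[, 3L]))
      colnames(out) <- c("c1", "T2_1", "T2_2")
      if (keep_cache) caches[[i]] <- list(A = A)
    } else if (sp$type == "nonneg_head") {
      out <- matrix(softplus(A[, 1L]), ncol = 1L)
      if (keep_cache) caches[[i]] <- list(A = A)
    }
    A <- out
  }
  list(out = A, caches = caches)
}

# backward pass from output gradient; returns gradients per layer
nn_backward <- function(net, fwd, dOut) {
  n <- length(net$layers)
  batch <- nrow(dOut)
  grads <- vector("list", n)
  G <- dOut
  for (i in rev(seq_len(n))) {
    sp <- net$layers[[i]]
    cache <- fwd$caches[[i]]
    if (sp$type == "dense") {
      dZ <- G * activate_grad(cache$Z, sp$activation)
      grads[[i]] <- list(dW = crossprod(cache$A, dZ), db = colSums(dZ))
      G <- dZ %*% t(sp$W)
    } else if (sp$type == "conv1d") {
      dZ <- G * activate_grad(cache$Z, sp$activation)
      bk <- conv1d_backward(cache$A, dZ, sp, batch, cache$L)
      grads[[i]] <- list(dW = bk$dW, db = bk$db)
      G <- bk$dX
    } else if (sp$type == "avgpool1d") {
      f <- sp$factor
      Lp <- cache$L %/% f
      dA <- array(0, c(f, batch, Lp, cache$C))
      G_arr <- G / f
      dim(G_arr) <- c(batch, Lp, cache$C)
      for (w in seq_len(f)) dA[w, , , ] <- G_arr
      dA <- aperm(dA, c(2L, 1L, 3L, 4L))
      dim(dA) <- c(batch * cache$L, cache$C)
      G <- dA
    } else if (sp$type == "flatten") {
      dim(G) <- NULL
      G <- matrix(G, batch * cache$L, cache$ncol_in)
    } else if (sp$type == "pe_head") {
      A <- cache$A
      d1 <- sigmoid(A[, 1L]); d1 <- d1 * (1 - d1)
      d2 <- sp$t2_scale * sigmoid(A[, 2L])
      d3 <- sp$t2_scale * sigmoid(A[, 3L])
      G <- cbind(G[, 1L] * d1, G[, 2L] * d2, G[, 3L] * d3)
    } else if (sp$type == "nonneg_head") {
      G <- matrix(G[, 1L] * sigmoid(cache$A[, 1L]), ncol = 1L)
    }
  }
  grads
}

#' Predict with a feed-forward network
#' @param net An `ff_network`.
#' @param X Input matrix (rows are samples).
#' @return Output matrix.
#' @export
nn_predict <- function(net, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  nn_forward(net, X)$out
}

## ---- losses -------------------------------------------------------------

#' Mean absolute error loss (scalar targets)
#' @return A loss object for [nn_train()].
#' @export
loss_l1 <- function() {
  list(name = "l1",
       value = function(pred, true) mean(abs(pred - true)),
       grad = function(pred, true) sign(pred - true) / length(pred))
}

#' B-weighted mean squared error loss on the parameter triple
#'
#' Mean over the batch of \eqn{(\hat p - p)^\top B (\hat p - p)} with B the
#' diagonal scale matrix; B = identity reduces it to (3x) plain MSE.
#' @param B Length-3 positive diagonal (default `c(100, 1, 1)`).
#' @return A loss object for [nn_train()].
#' @export
loss_weighted_mse <- function(B = c(100, 1, 1)) {
  list(name = "weighted_mse",
       value = function(pred, true) weighted_param_loss(pred, true, B),
       grad = function(pred, true) {
         sweep(2 * (pred - true), 2L, B, "*") / nrow(pred)
       })
}

#' Combined weighted-MSE + Wasserstein-1 loss
#'
#' The benchmark loss of the model-informed estimator: the B-weighted MSE
#' plus `weight` times the sum over the three parameters of the 1-D
#' Wasserstein-1 distance between the batch-empirical distributions of
#' predictions and truths.
#' @param B Length-3 positive diagonal.
#' @param weight Mixing coefficient on the distributional term.
#' @return A loss object for [nn_train()].
#' @export
loss_mi_ml <- function(B = c(100, 1, 1), weight = 1) {
  list(name = "mi_ml",
       value = function(pred, true) mi_ml_loss(pred, true, weight = weight, B = B),
       grad = function(pred, true) {
         n <- nrow(pred)
         G <- sweep(2 * (pred - true), 2L, B, "*") / n
         for (j in seq_len(ncol(pred))) {
           op <- order(pred[, j]); ot <- order(true[, j])
           gj <- numeric(n)
           gj[op] <- sign(pred[op, j] - true[ot, j]) / n
           G[, j] <- G[, j] + weight * gj
         }
         G
       })
}

## ---- training -----------------------------------------------------------

adam_init <- function(net) {
  lapply(net$layers, function(sp) {
    if (sp$type == "dense") {
      list(mW = sp$W * 0, vW = sp$W * 0, mb = sp$b * 0, vb = sp$b * 0)
    } else if (sp$type == "conv1d") {
      list(mW = lapply(sp$W, function(w) w * 0), vW = lapply(sp$W, function(w) w * 0),
           mb = sp$b * 0, vb = sp$b * 0)
    } else NULL
  })
}

adam_update <- function(x, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, weight_decay = 0) {
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  # decoupled weight decay (AdamW)
  list(x = x - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * x),
       state = state)
}

#' Train a feed-forward network with mini-batch Adam
#'
#' @param net An `ff_network` from [build_network()].
#' @param X Input matrix (samples x features).
#' @param Y Target matrix (samples x outputs).
#' @param loss A loss object ([loss_l1()], [loss_weighted_mse()],
#'   [loss_mi_ml()]).
#' @param epochs Number of passes over the data.
#' @param batch_size Mini-batch size.
#' @param lr Adam learning rate.
#' @param lr_decay Per-epoch multiplicative learning-rate decay (1 = none).
#' @param weight_decay Decoupled L2 weight decay coefficient (0 = none).
#' @param early_stopping Keep the weights of the best validation epoch
#'   (requires `X_val`).
#' @param seed Seed for shuffling (weights were seeded at build time).
#' @param X_val,Y_val Optional held-out set evaluated each epoch.
#' @param verbose Print a line every `verbose` epochs (0 = silent).
#' @return The trained network, with a `history` data.frame attached
#'   (`epoch`, `train_loss`, `val_loss`).
#' @export
nn_train <- function(net, X, Y, loss, epochs = 100L, batch_size = 64L,
                     lr = 1e-3, lr_decay = 1, weight_decay = 0,
                     early_stopping = FALSE, seed = 1L,
                     X_val = NULL, Y_val = NULL, verbose = 0L) {
  n <- nrow(X)
  if (n == 0L) stop("empty training set")
  if (nrow(Y) != n) stop("X and Y row mismatch")
  set.seed(seed)
  states <- adam_init(net)
  t_step <- 0L
  best_val <- Inf
  best_layers <- NULL
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  for (ep in seq_len(epochs)) {
    lr_ep <- lr * lr_decay^(ep - 1L)
    idx <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      batch <- idx[start:min(start + batch_size - 1L, n)]
      if (loss$name == "mi_ml" && length(batch) < 2L) next
      Xb <- X[batch, , drop = FALSE]
      Yb <- Y[batch, , drop = FALSE]
      fwd <- nn_forward(net, Xb, keep_cache = TRUE)
      lv <- loss$value(fwd$out, Yb)
      if (!is.finite(lv)) stop("non-finite training loss (diverged)")
      grads <- nn_backward(net, fwd, loss$grad(fwd$out, Yb))
      t_step <- t_step + 1L
      for (i in seq_along(net$layers)) {
        sp <- net$layers[[i]]
        if (is.null(grads[[i]]) || is.null(states[[i]])) next
        if (sp$type == "dense") {
          up <- adam_update(sp$W, grads[[i]]$dW,
                            list(m = states[[i]]$mW, v = states[[i]]$vW),
                            lr_ep, t_step, weight_decay = weight_decay)
          sp$W <- up$x; states[[i]]$mW <- up$state$m; states[[i]]$vW <- up$state$v
          up <- adam_update(sp$b, grads[[i]]$db,
                            list(m = states[[i]]$mb, v = states[[i]]$vb), lr_ep, t_step)
          sp$b <- up$x; states[[i]]$mb <- up$state$m; states[[i]]$vb <- up$state$v
        } else if (sp$type == "conv1d") {
          for (j in seq_along(sp$W)) {
            up <- adam_update(sp$W[[j]], grads[[i]]$dW[[j]],
                              list(m = states[[i]]$mW[[j]], v = states[[i]]$vW[[j]]),
                              lr_ep, t_step, weight_decay = weight_decay)
            sp$W[[j]] <- up$x
            states[[i]]$mW[[j]] <- up$state$m; states[[i]]$vW[[j]] <- up$state$v
          }
          up <- adam_update(sp$b, grads[[i]]$db,
                            list(m = states[[i]]$mb, v = states[[i]]$vb), lr_ep, t_step)
          sp$b <- up$x; states[[i]]$mb <- up$state$m; states[[i]]$vb <- up$state$v
        }
        net$layers[[i]] <- sp
      }
      ep_loss <- ep_loss + lv; nb <- nb + 1L
    }
    vl <- NA_real_
    if (!is.null(X_val)) {
      vl <- loss$value(nn_forward(net, X_val)$out, Y_val)
      if (early_stopping && vl < best_val) {
        best_val <- vl
        best_layers <- net$layers
      }
    }
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                         val_loss = vl))
    if (verbose > 0L && ep %% verbose == 0L)
      message(sprintf("epoch %d: train %.5g val %.5g", ep, ep_loss / nb, vl))
  }
  if (early_stopping && !is.null(best_layers)) net$layers <- best_layers
  net$history <- history
  net
}
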