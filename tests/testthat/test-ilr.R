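test_that("concatenated inputs have the right structure", {
  ctl <- fit_control()
  p <- c(c1 = 0.3, T2_1 = 25, T2_2 = 150)
  s <- forward_model(p, ctl$schedule)
  sel <- new_sel <- lambda_oracle(s, p, ctl)
  x <- build_concat_input(s, sel, ctl)
  expect_length(x$values, 2L * ctl$schedule$n)
  expect_identical(x$values[1:64], s$values)
  reg <- x$values[65:128]
  expect_true(all(diff(reg) <= 0))  # clean forward-model half

  # a clean signal refit at negligible lambda reproduces itself
  tiny <- ilrmwf:::new_lambda_selection(1e-7, "oracle", NA_real_)
  x2 <- build_concat_input(s, tiny, ctl)
  expect_lt(max(abs(x2$values[65:128] - s$values)), 1e-3)
})

test_that("the duplicated variant copies the noisy signal verbatim", {
  d <- generate_dataset(1, noise = noise_spec(snr = 5), seed = 3)
  x <- duplicate_input(d$signals[1, ])
  expect_identical(x$values, c(d$signals[1, ], d$signals[1, ]))
  expect_identical(x$method, "duplicate")
})

test_that("weighted parameter loss matches its closed forms", {
  expect_identical(weighted_param_loss(c(0.3, 20, 80), c(0.3, 20, 80)), 0)
  expect_equal(weighted_param_loss(c(1, 20, 80), c(0, 20, 80)), 100)
  expect_equal(weighted_param_loss(c(0.3, 20, 82), c(0.3, 20, 80)), 4)
  # B = identity reduces to the summed plain MSE
  pred <- cbind(runif(6), runif(6, 10, 60), runif(6, 60, 300))
  true <- cbind(runif(6), runif(6, 10, 60), runif(6, 60, 300))
  expect_equal(weighted_param_loss(pred, true, B = c(1, 1, 1)),
               mean(rowSums((pred - true)^2)))
  expect_error(weighted_param_loss(pred, true[1:3, ]), "mismatch")
})

test_that("the combined MSE + W1 loss has the advertised structure", {
  set.seed(8)
  true <- cbind(runif(8), runif(8, 10, 60), runif(8, 60, 300))
  expect_equal(mi_ml_loss(true, true), 0)
  # permuting the batch zeroes the W1 term but not the MSE term
  perm <- true[sample(8), ]
  expect_equal(mi_ml_loss(perm, true, weight = 5),
               weighted_param_loss(perm, true))
  expect_gt(mi_ml_loss(perm, true, weight = 5), 0)
  # two-sample batches: W1 term is the sorted mean absolute difference
  a <- cbind(c(0, 1), c(10, 20), c(100, 200))
  b <- cbind(c(1, 2), c(20, 40), c(100, 150))
  w1 <- mean(abs(sort(a[, 1]) - sort(b[, 1]))) +
    mean(abs(sort(a[, 2]) - sort(b[, 2]))) +
    mean(abs(sort(a[, 3]) - sort(b[, 3])))
  expect_equal(mi_ml_loss(a, b, weight = 1),
               weighted_param_loss(a, b) + w1)
  expect_error(mi_ml_loss(a[1, , drop = FALSE], b[1, , drop = FALSE]),
               "at least 2")
})

test_that("a small parameter network memorizes a tiny training set", {
  set.seed(10)
  d <- generate_dataset(10, noise = noise_spec(snr = 50), seed = 44)
  X <- cbind(d$signals, d$signals)
  est <- train_pe_network(X, d$params,
                          pe_net_config(hidden = c(128, 128), epochs = 10000,
                                        batch_size = 10, lr = 2e-3,
                                        lr_decay = 0.9998, seed = 5),
                          variant = "ndnd")
  final <- weighted_param_loss(estimate_params(est, X), d$params)
  expect_lt(final, 1e-3)
})

test_that("training is reproducible and beats an untrained network", {
  fx <- labelled_ensemble()
  d <- fx$dataset
  X <- cbind(d$signals, d$signals)
  cfg <- pe_net_config(hidden = c(64, 64), epochs = 120, seed = 7)
  m1 <- train_pe_network(X, d$params, cfg, "ndnd")
  m2 <- train_pe_network(X, d$params, cfg, "ndnd")
  expect_identical(estimate_params(m1, X), estimate_params(m2, X))

  untrained <- ilrmwf:::build_network(
    ncol(X), c(lapply(cfg$hidden, function(h) layer_dense(h, "relu")),
               list(layer_dense(3, "linear"), layer_pe_head(100))), seed = 7)
  r_trained <- rmse(estimate_params(m1, X)[, "c1"], d$params[, "c1"])
  r_raw <- rmse(ilrmwf:::nn_forward(untrained, X)$out[, 1], d$params[, "c1"])
  expect_lt(r_trained, r_raw)
})

test_that("estimates respect the feasible set and the variant contract", {
  d <- generate_dataset(30, noise = noise_spec(snr = 5), seed = 50)
  X <- cbind(d$signals, d$signals)
  est <- train_pe_network(X, d$params,
                          pe_net_config(hidden = 16, epochs = 3, seed = 2),
                          variant = "ndnd")
  P <- estimate_params(est, X)
  expect_true(all(P[, "c1"] >= 0 & P[, "c1"] <= 1))
  expect_true(all(P[, "T2_1"] > 0 & P[, "T2_1"] <= P[, "T2_2"]))
  # batch equals single
  one <- estimate_params(est, X[4, ])
  expect_equal(unclass(one), P[4, ], tolerance = 1e-12)
  # feeding an ILR-tagged input to a duplicated-input model errors
  sel <- ilrmwf:::new_lambda_selection(1e-3, "gcv", NA_real_)
  xg <- build_concat_input(d$signals[1, ], sel, fit_control())
  expect_error(estimate_params(est, xg), "variant")
})

test_that("batch ILR input construction matches the single-signal path", {
  fx <- labelled_ensemble()
  d <- fx$dataset
  ctl <- fx$control
  inp <- build_ilr_inputs(d, "oracle", ctl)
  expect_identical(dim(inp$X), c(nrow(d$signals), 128L))
  i <- 7L
  sel <- ilrmwf:::new_lambda_selection(d$oracle_lambda[i], "oracle", NA_real_)
  xi <- build_concat_input(d$signals[i, ], sel, ctl)
  expect_equal(inp$X[i, ], xi$values, tolerance = 1e-8)
  expect_identical(inp$variant, "ndreg_oracle")
  # first halves are always the untouched noisy signals
  expect_identical(inp$X[, 1:64], d$signals)
})
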