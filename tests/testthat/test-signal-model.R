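test_that("forward model matches hand-evaluated values and boundary cases", {
  sch <- echo_schedule(times = c(0, 20, 40, 60))
  s <- forward_model(biexp_params(0.5, 20, 80), sch)
  expect_identical(s$values[1], 1)
  expect_equal(s$values[2], 0.5 * exp(-1) + 0.5 * exp(-0.25))

  # c1 = 0 collapses to the slow monoexponential
  s0 <- forward_model(biexp_params(0, 20, 80), sch)
  expect_equal(s0$values, exp(-sch$times / 80))

  expect_true(s$clean)
  expect_s3_class(s, "decay_signal")
})

test_that("forward model is positive and nonincreasing for feasible params", {
  sch <- echo_schedule()
  P <- random_params(20, seed = 4)
  for (i in seq_len(nrow(P))) {
    v <- forward_model(biexp_params(P[i, 1], P[i, 2], P[i, 3]), sch)$values
    expect_true(all(v > 0))
    expect_true(all(diff(v) <= 0))
  }
})

test_that("invalid parameters are rejected with the violated bound named", {
  expect_error(biexp_params(-0.1, 20, 80), "c1")
  expect_error(biexp_params(1.2, 20, 80), "c1")
  expect_error(biexp_params(0.5, 0, 80), "T2_1")
  expect_error(biexp_params(0.5, 20, -3), "T2_2")
  expect_error(forward_model(c(2, 20, 80), echo_schedule()), "c1")
})

test_that("canonical ordering swaps labels and remaps the fraction", {
  p <- biexp_params(0.8, 80, 20)
  expect_equal(unclass(p), c(c1 = 0.2, T2_1 = 20, T2_2 = 80))
  # the two labelings describe the same curve
  sch <- echo_schedule()
  expect_equal(forward_model(p, sch)$values,
               forward_model(biexp_params(0.2, 20, 80), sch)$values)
})

test_that("echo schedule invariants are enforced", {
  expect_error(echo_schedule(times = c(1, 2, 3, 4)), "must be 0")
  expect_error(echo_schedule(times = c(0, 2, 2, 4)), "increasing")
  expect_error(echo_schedule(times = c(0, 1)), "at least 4")
  expect_identical(echo_schedule()$n, 64L)
})

test_that("analytic Jacobian matches central finite differences", {
  sch <- echo_schedule()
  P <- random_params(100, seed = 9)
  h <- 1e-6
  worst <- 0
  for (i in seq_len(nrow(P))) {
    p <- P[i, ]
    p[1] <- min(max(p[1], 0.05), 0.95)  # keep the c1 stencil feasible
    J <- forward_jacobian(p, sch)
    for (k in 1:3) {
      hp <- h * max(1, abs(p[k]))
      pp <- p; pp[k] <- pp[k] + hp
      pm <- p; pm[k] <- pm[k] - hp
      fd <- (forward_model(pp, sch)$values - forward_model(pm, sch)$values) / (2 * hp)
      worst <- max(worst, max(abs(J[, k] - fd)) / max(abs(J[, k])))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("Jacobian boundary rows and columns vanish where the model is flat", {
  sch <- echo_schedule()
  J <- forward_jacobian(biexp_params(0.5, 20, 80), sch)
  expect_equal(unname(J[1, ]), c(0, 0, 0))  # t = 0
  J1 <- forward_jacobian(biexp_params(1, 20, 80), sch)
  expect_equal(unname(J1[, "T2_2"]), rep(0, sch$n))
})

test_that("Rician noise is the identity at sigma = 0 and reproducible", {
  sch <- echo_schedule()
  s <- forward_model(biexp_params(0.3, 20, 120), sch)
  expect_identical(add_rician_noise(s, noise_spec(sigma = 0))$values, s$values)
  a <- add_rician_noise(s, noise_spec(snr = 10), seed = 5)
  b <- add_rician_noise(s, noise_spec(snr = 10), seed = 5)
  expect_identical(a$values, b$values)
  expect_true(all(a$values >= 0))
  expect_false(a$clean)
  expect_error(noise_spec(sigma = -1), "nonnegative")
})

test_that("Rician magnitude of a zero signal has the Rayleigh mean", {
  n <- 1e5
  sch <- echo_schedule(times = seq(0, n - 1))
  zero <- decay_signal(rep(0, n), sch, clean = TRUE)
  sigma <- 0.3
  out <- add_rician_noise(zero, noise_spec(sigma = sigma), seed = 8)$values
  want <- sigma * sqrt(pi / 2)
  se <- sigma * sqrt(2 - pi / 2) / sqrt(n)
  expect_lt(abs(mean(out) - want), 3 * se)
})

test_that("magnitude noise biases the first echo upward at low SNR", {
  d <- generate_dataset(500, noise = noise_spec(snr = 5), seed = 31)
  # clean value is exactly 1 at t = 0; Rician mean ~ 1 + sigma^2/2
  expect_gt(mean(d$signals[, 1]), 1)
})

test_that("parameter sampling respects ranges, ordering, and the LLN", {
  expect_identical(nrow(sample_parameters(0)), 0L)
  P <- sample_parameters(5, prior_config(c(0.3, 0.3), c(20, 20), c(90, 90)),
                         seed = 1)
  expect_true(all(P[, "c1"] == 0.3 & P[, "T2_1"] == 20 & P[, "T2_2"] == 90))
  expect_error(prior_config(T2_1_range = c(50, 20)), "invalid range")
  expect_error(prior_config(T2_1_range = c(-5, 20)), "positive")

  P2 <- sample_parameters(1e4, prior_config(c1_range = c(0, 1),
                                            T2_1_range = c(10, 100),
                                            T2_2_range = c(10, 100)),
                          seed = 12)
  expect_true(all(P2[, "T2_1"] <= P2[, "T2_2"]))
  # LLN on the pre-ordering c1 mean: ordering remaps c1 -> 1 - c1 only when
  # T2s swap, which is mean-preserving for a symmetric c1 range
  expect_lt(abs(mean(P2[, "c1"]) - 0.5), 3 * (1 / sqrt(12)) / 100)
})

test_that("dataset generation is aligned, reproducible, and substream-stable", {
  d0 <- generate_dataset(3, noise = noise_spec(sigma = 0), seed = 2)
  for (i in 1:3) {
    expect_equal(d0$signals[i, ],
                 forward_model(d0$params[i, ], d0$schedule)$values)
  }
  d1 <- generate_dataset(6, noise = noise_spec(snr = 50), seed = 7)
  d2 <- generate_dataset(6, noise = noise_spec(snr = 50), seed = 7)
  expect_identical(d1$signals, d2$signals)
  # per-signal substreams: a shorter dataset reproduces the leading rows
  d3 <- generate_dataset(3, noise = noise_spec(snr = 50), seed = 7)
  expect_identical(d3$signals, d1$signals[1:3, ])
})

test_that("dataset CSV round trip preserves signals and metadata", {
  d <- generate_dataset(4, noise = noise_spec(snr = 50), seed = 3)
  path <- file.path(tempdir(), "ds.csv")
  write_dataset_csv(d, path)
  d2 <- read_dataset_csv(path)
  expect_equal(d2$signals, d$signals)
  expect_equal(d2$params, d$params, ignore_attr = TRUE)
  expect_equal(d2$schedule$times, d$schedule$times)
  expect_equal(d2$noise$sigma, d$noise$sigma)
  unlink(c(path, paste0(path, ".json")))
})
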