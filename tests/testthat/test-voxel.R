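test_that("monoexponential fits recover clean curves exactly", {
  sch <- echo_schedule()
  v <- 2.5 * exp(-sch$times / 70)
  fit <- fit_monoexponential(v, sch)
  expect_lt(fit$rss, 1e-10)
  expect_equal(fit$amplitude, 2.5, tolerance = 1e-6)
  expect_equal(fit$T2, 70, tolerance = 1e-6)
  expect_identical(fit$k, 2L)

  # a well-separated biexponential cannot be fit by one exponential
  vb <- biexp_params(0.5, 15, 250)
  vb <- forward_model(vb, sch)$values
  expect_gt(fit_monoexponential(vb, sch)$rss, 1e-3)
})

test_that("monoexponential fit matches a 2-D grid oracle on noisy input", {
  sch <- echo_schedule()
  set.seed(12)
  v <- abs(1.3 * exp(-sch$times / 90) + rnorm(sch$n, 0, 0.05))
  fit <- fit_monoexponential(v, sch)
  amps <- seq(0.5, 2.5, length.out = 60)
  t2s <- exp(seq(log(5), log(500), length.out = 60))
  E <- exp(-outer(sch$times, t2s, "/"))
  gmin <- min(vapply(seq_along(t2s), function(j) {
    min(colSums((outer(E[, j], amps) - v)^2))
  }, numeric(1)))
  expect_lte(fit$rss, gmin + 1e-6)
})

test_that("AIC scores follow the least-squares closed form", {
  expect_equal(aic_score(1, 64, 4) - aic_score(1, 64, 2), 4)
  expect_equal(aic_score(0.5, 64, 2) - aic_score(1, 64, 2), -64 * log(2))
  expect_identical(aic_score(0, 64, 2), -Inf)
  expect_error(aic_score(1, 3, 4), "n_obs")
  expect_error(aic_score(-1, 64, 2), "RSS")
  # AICc penalizes the larger model more at small n
  d4 <- aic_score(1, 10, 4, correction = TRUE) - aic_score(1, 10, 4)
  d2 <- aic_score(1, 10, 2, correction = TRUE) - aic_score(1, 10, 2)
  expect_gt(d4, d2)
})

test_that("mono-truth voxels are overwhelmingly classified monoexponential", {
  sch <- echo_schedule()
  set.seed(33)
  n_vox <- 200
  correct <- 0
  for (i in seq_len(n_vox)) {
    t2 <- runif(1, 50, 150)
    g <- exp(-sch$times / t2)
    v <- sqrt((g + rnorm(sch$n, 0, 0.04))^2 + rnorm(sch$n, 0, 0.04)^2)
    fm <- fit_monoexponential(v, sch, offset = TRUE)
    fb <- ilrmwf:::fit_biexp_free_amp(v, sch, offset = TRUE)
    if (aic_score(fm$rss, sch$n, fm$k) <= aic_score(fb$rss, sch$n, fb$k)) {
      correct <- correct + 1
    }
  }
  expect_gte(correct / n_vox, 0.9)
})

test_that("the phantom class map recovers the biexponential disk", {
  ph <- voxel_phantom(H = 16, W = 16, radius = 5,
                      p_bi = biexp_params(0.35, 15, 250),
                      T2_mono = 90, noise = noise_spec(sigma = 0.01),
                      seed = 21)
  cm <- classify_voxels(ph$image)
  acc <- mean((cm$labels == "biexponential") == ph$disk)
  expect_gte(acc, 0.95)
  expect_identical(dim(cm$labels), dim(ph$truth))

  # masked-out voxels are excluded wholesale
  img2 <- voxel_image(ph$image$data, ph$image$schedule,
                      mask = matrix(FALSE, 16, 16))
  cm2 <- classify_voxels(img2)
  expect_true(all(cm2$labels == "excluded"))
  expect_true(all(is.na(cm2$snr)))
})

test_that("voxel SNR estimates are calibrated and scale-invariant", {
  sch <- echo_schedule()
  # noiseless: zero residual yields the +Inf sentinel
  v <- exp(-sch$times / 80)
  fm <- fit_monoexponential(v, sch)
  expect_identical(estimate_voxel_snr(v, fm), Inf)

  set.seed(44)
  snrs <- replicate(200, {
    t2 <- runif(1, 60, 150)
    g <- exp(-sch$times / t2)
    v <- sqrt((g + rnorm(sch$n, 0, 0.2))^2 + rnorm(sch$n, 0, 0.2)^2)
    # offset fit, as used by the classifier: the noise floor is model, not
    # residual, at this noise level
    estimate_voxel_snr(v, fit_monoexponential(v, sch, offset = TRUE))
  })
  expect_lt(abs(median(snrs) - 5) / 5, 0.2)

  # rescaling the signal leaves the estimate unchanged
  set.seed(45)
  v <- sqrt((exp(-sch$times / 100) + rnorm(sch$n, 0, 0.05))^2 +
              rnorm(sch$n, 0, 0.05)^2)
  s1 <- estimate_voxel_snr(v, fit_monoexponential(v, sch))
  s2 <- estimate_voxel_snr(7 * v, fit_monoexponential(7 * v, sch))
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("the MWF map recovers a constant-fraction phantom", {
  ph <- voxel_phantom(H = 12, W = 12, radius = 4,
                      p_bi = biexp_params(0.2, 15, 250),
                      T2_mono = 90, noise = noise_spec(sigma = 0.01),
                      seed = 31)
  cm <- classify_voxels(ph$image)
  map <- estimate_mwf_map(ph$image, cm, estimator = "nlls")
  expect_identical(dim(map$c1), dim(ph$disk))
  inside <- map$c1[ph$disk & cm$labels == "biexponential"]
  expect_gt(length(inside), 10)
  expect_lt(abs(mean(inside, na.rm = TRUE) - 0.2), 0.05)
  # mono background carries the sentinel
  expect_true(all(is.na(map$c1[cm$labels == "monoexponential"])))
})

test_that("voxelwise results equal the signal-level pipeline (no coupling)", {
  ph <- voxel_phantom(H = 6, W = 6, radius = 2,
                      p_bi = biexp_params(0.3, 20, 200),
                      noise = noise_spec(sigma = 0.02), seed = 8)
  cm <- classify_voxels(ph$image)
  map <- estimate_mwf_map(ph$image, cm, estimator = "nlls")
  idx <- which(cm$labels == "biexponential", arr.ind = TRUE)
  i <- idx[1, 1]; j <- idx[1, 2]
  v <- ph$image$data[i, j, ]
  fit <- nlls_fit(v / v[1], fit_control(ph$image$schedule))
  expect_equal(map$c1[i, j], canonicalize_params(fit$params)[["c1"]],
               tolerance = 1e-10)
})
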