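#' Voxel-grid image of decay signals
#'
#' @param data H x W x N numeric array of magnitudes (N echoes per voxel).
#' @param schedule The [echo_schedule()] (N must match).
#' @param mask H x W logical matrix; masked-out voxels are excluded from all
#'   statistics (default all TRUE).
#' @return Object of class `voxel_image`.
#' @export
voxel_image <- function(data, schedule, mask = NULL) {
  d <- dim(data)
  if (length(d) != 3L) stop("data must be an H x W x N array")
  if (d[3L] != schedule$n) stop("third dimension must match the echo schedule")
  if (is.null(mask)) mask <- matrix(TRUE, d[1L], d[2L])
  if (!all(dim(mask) == d[1:2])) stop("mask shape must match the image")
  structure(list(data = data, schedule = schedule, mask = mask),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_image> %d x %d voxels, N = %d echoes, %d in mask\n",
              d[1L], d[2L], d[3L], sum(x$mask)))
  invisible(x)
}

#' Monoexponential least-squares fit
#'
#' Fits \eqn{a e^{-t/T_2}} with \eqn{a \ge 0}, \eqn{T_2 > 0} by bounded
#' Levenberg-Marquardt, initialized from a log-linear regression on the
#' early decay plus fallback starts. With `offset = TRUE` a nonnegative
#' constant \eqn{b} is added to the model (3 free parameters), absorbing
#' the Rician noise floor that magnitude data exhibit where the signal has
#' decayed away; the voxel classifier uses the offset variant so that the
#' floor cannot masquerade as a second exponential component.
#'
#' @param s A `decay_signal` or numeric signal vector.
#' @param schedule An [echo_schedule()] (taken from `s` when it is a
#'   `decay_signal`).
#' @param t2_floor,t2_cap Bounds on T2.
#' @param offset Include a nonnegative constant baseline term.
#' @return List with `amplitude`, `T2`, `offset`, `rss`, `fitted`,
#'   `converged`, and `k` (2, or 3 with offset) free parameters.
#' @export
fit_monoexponential <- function(s, schedule = NULL, t2_floor = 1e-3,
                                t2_cap = 2000, offset = FALSE) {
  if (inherits(s, "decay_signal") && is.null(schedule)) schedule <- s$schedule
  if (is.null(schedule)) stop("schedule required")
  v <- signal_values(s)
  t <- schedule$times
  pos <- v > 0
  start_t2 <- 50
  if (sum(pos) >= 3L) {
    cf <- stats::coef(stats::lm(log(v[pos]) ~ t[pos]))
    if (is.finite(cf[2L]) && cf[2L] < 0) start_t2 <- min(max(-1 / cf[2L], 1), t2_cap)
  }
  b0 <- if (offset) stats::median(utils::tail(v, max(4L, length(v) %/% 8L))) else 0
  starts <- rbind(c(max(v[1L] - b0, 1e-3), start_t2),
                  c(max(v[1L] - b0, 1e-3), 20),
                  c(max(mean(v), 1e-3), 200))
  k_free <- if (offset) 3L else 2L
  best <- NULL
  conv <- FALSE
  for (k in seq_len(nrow(starts))) {
    par0 <- c(a = starts[k, 1L], T2 = starts[k, 2L])
    if (offset) par0 <- c(par0, b = b0)
    fit <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(par = par0,
                         lower = c(0, t2_floor, 0)[seq_len(k_free)],
                         upper = c(Inf, t2_cap, Inf)[seq_len(k_free)],
                         fn = function(p) {
                           p[[1L]] * exp(-t / p[[2L]]) +
                             (if (offset) p[[3L]] else 0) - v
                         },
                         control = minpack.lm::nls.lm.control(maxiter = 100))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (fit$info %in% 1:4) conv <- TRUE
    if (is.null(best) || rss < best$rss) {
      best <- list(amplitude = fit$par[["a"]], T2 = fit$par[["T2"]],
                   offset = if (offset) fit$par[["b"]] else 0, rss = rss)
    }
  }
  if (is.null(best))
    return(list(amplitude = NA_real_, T2 = NA_real_, offset = NA_real_,
                rss = NA_real_, fitted = rep(NA_real_, length(v)),
                converged = FALSE, k = k_free))
  c(best, list(fitted = best$amplitude * exp(-t / best$T2) + best$offset,
               converged = conv, k = k_free))
}

# free-amplitude biexponential fit for voxel classification of
# non-normalized magnitudes: a (c1 e^-t/T21 + (1-c1) e^-t/T22) [+ b].
# The optional nonnegative offset absorbs the Rician noise floor.
fit_biexp_free_amp <- function(v, schedule, control = fit_control(schedule),
                               offset = FALSE) {
  t <- schedule$times
  b0 <- if (offset) stats::median(utils::tail(v, max(4L, length(v) %/% 8L))) else 0
  a0 <- max(v[1L] - b0, 1e-3)
  starts <- unname(cbind(a0, fit_starts(control)))
  k_free <- if (offset) 5L else 4L
  lower <- c(0, 0, control$t2_floor, control$t2_floor, 0)[seq_len(k_free)]
  upper <- c(Inf, 1, control$t2_cap, control$t2_cap, Inf)[seq_len(k_free)]
  best <- NULL
  conv <- FALSE
  for (k in seq_len(nrow(starts))) {
    par0 <- c(a = starts[k, 1L], c1 = starts[k, 2L],
              T2_1 = starts[k, 3L], T2_2 = starts[k, 4L])
    if (offset) par0 <- c(par0, b = b0)
    fit <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = function(p) {
                           p[[1L]] * biexp_curve(
                             c(c1 = p[[2L]], T2_1 = p[[3L]], T2_2 = p[[4L]]), t) +
                             (if (offset) p[[5L]] else 0) - v
                         },
                         control = minpack.lm::nls.lm.control(maxiter = 150))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (fit$info %in% 1:4) conv <- TRUE
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best))
    return(list(par = NULL, rss = NA_real_, converged = FALSE, k = k_free))
  p3 <- canonicalize_params(c(c1 = best$par[["c1"]], T2_1 = best$par[["T2_1"]],
                              T2_2 = best$par[["T2_2"]]))
  b_hat <- if (offset) best$par[["b"]] else 0
  list(par = c(a = best$par[["a"]], p3, b = b_hat), rss = best$rss,
       fitted = best$par[["a"]] * biexp_curve(p3, t) + b_hat,
       converged = conv, k = k_free)
}

#' Akaike information criterion for a least-squares fit
#'
#' Gaussian-residual form \eqn{n \ln(RSS/n) + 2k}; the small-sample
#' correction (AICc) adds \eqn{2k(k+1)/(n-k-1)}. A zero RSS returns
#' `-Inf` (a perfect fit dominates regardless of order).
#'
#' @param rss Residual sum of squares (>= 0).
#' @param n_obs Number of observations (> k_params).
#' @param k_params Number of free parameters.
#' @param correction Use the AICc small-sample correction.
#' @return Scalar score (lower is better).
#' @export
aic_score <- function(rss, n_obs, k_params, correction = FALSE) {
  if (n_obs <= k_params) stop("aic_score: need n_obs > k_params")
  if (!is.finite(rss) || rss < 0) stop("aic_score: invalid RSS")
  if (rss == 0) return(-Inf)
  a <- n_obs * log(rss / n_obs) + 2 * k_params
  if (correction) a <- a + 2 * k_params * (k_params + 1) / (n_obs - k_params - 1)
  a
}

#' Per-voxel SNR estimate from a model fit
#'
#' SNR at a voxel is the fitted signal at t = 0 divided by a residual-based
#' noise estimate from the best-model fit. The initial estimate
#' \eqn{\hat\sigma = \sqrt{RSS/(n - k)}} is refined once using only
#' echoes where the fitted signal exceeds \eqn{2\hat\sigma}: magnitude
#' data are approximately Gaussian there, whereas residuals in the
#' noise-floor tail have Rayleigh-compressed variance and would bias
#' \eqn{\hat\sigma} low (and the SNR high). Invariant under overall
#' signal rescaling. A zero residual yields `+Inf`.
#'
#' @param s A `decay_signal` or numeric vector.
#' @param fit_result A fit list with `rss`, `fitted`, `k` (from
#'   [fit_monoexponential()] or the internal biexponential voxel fit).
#' @return Scalar SNR estimate.
#' @export
estimate_voxel_snr <- function(s, fit_result) {
  v <- signal_values(s)
  n <- length(v)
  rss <- fit_result$rss
  if (!is.finite(rss)) return(NA_real_)
  if (rss == 0) return(Inf)
  sigma_hat <- sqrt(rss / (n - fit_result$k))
  hi <- fit_result$fitted > 2 * sigma_hat
  if (sum(hi) >= 8L) {
    r <- v[hi] - fit_result$fitted[hi]
    sigma_ref <- sqrt(sum(r^2) / max(sum(hi) - fit_result$k, 1L))
    if (is.finite(sigma_ref) && sigma_ref > 0) sigma_hat <- sigma_ref
  }
  fit_result$fitted[1L] / sigma_hat
}

#' Classify voxels as mono- or biexponential by AIC
#'
#' Fits both a 2-parameter monoexponential and a 4-parameter free-amplitude
#' biexponential to every in-mask voxel and labels the voxel
#' `"biexponential"` iff its biexponential AIC is strictly lower (ties go
#' to the simpler model). Fit failures label the voxel `"excluded"`. A
#' per-voxel SNR estimate from the winning model is recorded alongside.
#'
#' @param img A [voxel_image()].
#' @param control A [fit_control()] for the biexponential fits.
#' @param correction Use AICc instead of AIC.
#' @param offset Add a nonnegative baseline to both candidate models
#'   (default TRUE): magnitude data plateau at the Rician noise floor, and
#'   without a baseline the extra exponential of the larger model fits the
#'   floor, classifying everything biexponential.
#' @return A `voxel_class_map`: list of H x W matrices `labels`
#'   (character), `aic_mono`, `aic_biexp`, `snr`.
#' @export
classify_voxels <- function(img, control = fit_control(img$schedule),
                            correction = FALSE, offset = TRUE) {
  d <- dim(img$data)
  H <- d[1L]; W <- d[2L]; N <- d[3L]
  labels <- matrix("excluded", H, W)
  aic_m <- matrix(NA_real_, H, W)
  aic_b <- matrix(NA_real_, H, W)
  snr <- matrix(NA_real_, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!img$mask[i, j]) { labels[i, j] <- "excluded"; next }
    v <- img$data[i, j, ]
    fm <- fit_monoexponential(v, img$schedule, t2_floor = control$t2_floor,
                              t2_cap = control$t2_cap, offset = offset)
    fb <- fit_biexp_free_amp(v, img$schedule, control, offset = offset)
    if (!fm$converged && !fb$converged) next
    am <- if (fm$converged) aic_score(fm$rss, N, fm$k, correction) else Inf
    ab <- if (fb$converged) aic_score(fb$rss, N, fb$k, correction) else Inf
    aic_m[i, j] <- am
    aic_b[i, j] <- ab
    is_bi <- ab < am
    labels[i, j] <- if (is_bi) "biexponential" else "monoexponential"
    best <- if (is_bi) fb else fm
    snr[i, j] <- estimate_voxel_snr(v, best)
  }
  structure(list(labels = labels, aic_mono = aic_m, aic_biexp = aic_b,
                 snr = snr),
            class = "voxel_class_map")
}

#' @export
print.voxel_class_map <- function(x, ...) {
  tb <- table(factor(x$labels, c("biexponential", "monoexponential", "excluded")))
  cat(sprintf("<voxel_class_map> %d biexponential, %d monoexponential, %d excluded; median SNR %.1f\n",
              tb[1L], tb[2L], tb[3L], stats::median(x$snr, na.rm = TRUE)))
  invisible(x)
}

#' Myelin water fraction map over the biexponential voxels
#'
#' Applies an estimator voxelwise to the AIC-classified biexponential
#' voxels: each voxel's signal is normalized by its first echo (the
#' 3-parameter estimators assume a unit-normalized decay), the
#' regularization weight is selected per voxel, and the fraction estimate
#' is entered in the map. Mono/excluded voxels carry `NA` sentinels.
#' With `lambda_method = "auto"` the selection method is routed by the
#' median estimated SNR over the biexponential voxels: GCV below
#' `snr_threshold` (regimes where the oracle distribution is broad and
#' multimodal), the selector network above it.
#'
#' @param img A [voxel_image()].
#' @param classmap The matching [classify_voxels()] output.
#' @param estimator Either a trained `pe_estimator` or one of the classical
#'   method names `"nlls"`, `"trnlls_gcv"`.
#' @param lambda_method `"auto"`, `"gcv"`, or `"network"` (ignored for
#'   `"nlls"` and for an `"ndnd"` network, which need no selection).
#' @param selector A `lambda_selector`, required when the network route is
#'   taken.
#' @param control A [fit_control()].
#' @param snr_threshold Median-SNR routing threshold for `"auto"`.
#' @return List with `c1` (H x W matrix, NA outside biexponential voxels),
#'   `lambda` (per-voxel selected weight), `lambda_method_used`, and
#'   `median_snr`.
#' @export
estimate_mwf_map <- function(img, classmap, estimator,
                             lambda_method = c("auto", "gcv", "network"),
                             selector = NULL,
                             control = fit_control(img$schedule),
                             snr_threshold = 50) {
  lambda_method <- match.arg(lambda_method)
  d <- dim(img$data)
  H <- d[1L]; W <- d[2L]
  c1 <- matrix(NA_real_, H, W)
  lam <- matrix(NA_real_, H, W)
  bi <- classmap$labels == "biexponential"
  med_snr <- stats::median(classmap$snr[bi], na.rm = TRUE)
  if (lambda_method == "auto") {
    lambda_method <- if (!is.finite(med_snr) || med_snr < snr_threshold)
      "gcv" else "network"
  }
  classical <- is.character(estimator)
  if (classical) estimator_name <- match.arg(estimator, c("nlls", "trnlls_gcv"))
  if (!classical && !inherits(estimator, "pe_estimator"))
    stop("estimator must be a pe_estimator or a classical method name")
  needs_net <- !classical && estimator$variant == "ndreg_network"
  if ((lambda_method == "network" || needs_net) &&
      !classical && estimator$variant != "ndnd" && is.null(selector))
    stop("network lambda selection requires a trained selector")
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!bi[i, j]) next
    v <- img$data[i, j, ]
    if (v[1L] <= 0) next
    v <- v / v[1L]
    res <- tryCatch({
      if (classical) {
        if (estimator_name == "nlls") {
          fit <- nlls_fit(v, control)
          list(c1 = canonicalize_params(fit$params)[["c1"]], lambda = 0)
        } else {
          sel <- lambda_gcv(v, control)
          list(c1 = canonicalize_params(sel$fit$params)[["c1"]],
               lambda = sel$lambda)
        }
      } else if (estimator$variant == "ndnd") {
        p <- estimate_params(estimator, duplicate_input(v))
        list(c1 = p[["c1"]], lambda = NA_real_)
      } else {
        sel <- if (lambda_method == "gcv") lambda_gcv(v, control)
               else predict_lambda(selector, v)
        ci <- build_concat_input(v, sel, control)
        ci$method <- if (estimator$variant == "ndreg_gcv") "gcv"
                     else if (estimator$variant == "ndreg_network") "network"
                     else ci$method
        p <- estimate_params(estimator, ci)
        list(c1 = p[["c1"]], lambda = sel$lambda)
      }
    }, error = function(e) NULL)
    if (is.null(res)) next
    c1[i, j] <- res$c1
    lam[i, j] <- res$lambda
  }
  list(c1 = c1, lambda = lam, lambda_method_used = lambda_method,
       median_snr = med_snr)
}

#' Synthetic voxel phantom: biexponential disk on monoexponential background
#'
#' Ground-truth test image for the classification and mapping pipeline: a
#' disk of biexponential voxels (constant parameters) embedded in a
#' monoexponential background, with Rician noise at a common sigma.
#'
#' @param H,W Image size.
#' @param radius Disk radius in voxels (centered).
#' @param p_bi [biexp_params()] inside the disk.
#' @param T2_mono Background relaxation time (ms).
#' @param noise A [noise_spec()].
#' @param schedule An [echo_schedule()].
#' @param seed Integer seed.
#' @return List with `image` (a [voxel_image()]), `truth` (H x W character
#'   matrix of generating model labels), and `disk` (logical matrix).
#' @export
voxel_phantom <- function(H = 24L, W = 24L, radius = 8,
                          p_bi = biexp_params(0.2, 20, 120),
                          T2_mono = 80, noise = noise_spec(sigma = 0.02),
                          schedule = echo_schedule(), seed = 1L) {
  set.seed(seed)
  t <- schedule$times
  g_bi <- biexp_curve(as_param_vector(p_bi), t)
  g_mono <- exp(-t / T2_mono)
  ci <- (H + 1) / 2; cj <- (W + 1) / 2
  disk <- outer(seq_len(H), seq_len(W),
                function(i, j) (i - ci)^2 + (j - cj)^2 <= radius^2)
  data <- array(0, c(H, W, schedule$n))
  for (i in seq_len(H)) for (j in seq_len(W)) {
    g <- if (disk[i, j]) g_bi else g_mono
    if (noise$sigma > 0) {
      xi <- stats::rnorm(schedule$n, 0, noise$sigma)
      eta <- stats::rnorm(schedule$n, 0, noise$sigma)
      data[i, j, ] <- sqrt((g + xi)^2 + eta^2)
    } else data[i, j, ] <- g
  }
  truth <- ifelse(disk, "biexponential", "monoexponential")
  list(image = voxel_image(data, schedule), truth = truth, disk = disk)
}

#' Write an MWF map (or any H x W matrix) as NIfTI
#'
#' @param map Numeric matrix.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly. Requires the RNifti package.
#' @export
write_mwf_nifti <- function(map, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI output")
  RNifti::writeNifti(RNifti::asNifti(map), path)
  invisible(path)
}

#' Read a voxel image from NIfTI
#'
#' @param path A 3-D NIfTI volume interpreted as H x W x N (echo last).
#' @param schedule An [echo_schedule()] matching the third dimension.
#' @param mask Optional H x W logical mask.
#' @return A [voxel_image()]. Requires the RNifti package.
#' @export
read_voxel_nifti <- function(path, schedule, mask = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI input")
  arr <- as.array(RNifti::readNifti(path))
  voxel_image(arr, schedule, mask)
}
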