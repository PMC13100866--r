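#' Multi-echo acquisition schedule
#'
#' Defines the echo times \eqn{t_1 < t_2 < \dots < t_N} at which the
#' transverse decay is sampled. The first echo is pinned at \eqn{t_1 = 0},
#' the usual convention for biexponential relaxometry analysis, so that the
#' clean unit-normalized signal satisfies \eqn{G(p)(0) = 1}.
#'
#' @param times Numeric vector of echo times (ms), strictly increasing,
#'   starting at 0. If missing, `n_echoes` uniformly spaced echoes with step
#'   `spacing` are used.
#' @param n_echoes Number of echoes when `times` is not given (default 64).
#' @param spacing Echo spacing in ms when `times` is not given. The default
#'   11.3 ms emulates a standard 64-echo multi-spin-echo relaxometry
#'   protocol (acquisition window about 712 ms), long enough that the slow
#'   water component is sampled through most of its decay while the fast
#'   myelin component is caught by only the first few echoes.
#' @return An object of class `echo_schedule` with elements `times` and `n`.
#' @examples
#' sch <- echo_schedule()
#' sch$n
#' @export
echo_schedule <- function(times = NULL, n_echoes = 64L, spacing = 11.3) {
  if (is.null(times)) {
    times <- seq(0, by = spacing, length.out = n_echoes)
  }
  times <- as.numeric(times)
  if (length(times) < 4L)
    stop("echo schedule needs at least 4 echoes (more observations than parameters)")
  if (times[1L] != 0)
    stop("first echo time must be 0 (unit-normalized signal convention)")
  if (any(diff(times) <= 0))
    stop("echo times must be strictly increasing")
  structure(list(times = times, n = length(times)), class = "echo_schedule")
}

#' @export
print.echo_schedule <- function(x, ...) {
  cat(sprintf("<echo_schedule> N = %d echoes, t in [%g, %g] ms\n",
              x$n, x$times[1L], x$times[x$n]))
  invisible(x)
}

#' Biexponential parameter triple
#'
#' The estimation target \eqn{p = (c_1, T_{2,1}, T_{2,2})}: the fast
#' (myelin-associated) signal fraction and the two transverse relaxation
#' times. The canonical labelling puts the fast component first,
#' \eqn{T_{2,1} \le T_{2,2}}; the model is invariant under the simultaneous
#' swap \eqn{(c_1, T_{2,1}) \leftrightarrow (1 - c_1, T_{2,2})}, so
#' parameters are remapped into canonical order on construction.
#'
#' @param c1 Signal fraction of the fast component, in \[0, 1\].
#' @param T2_1,T2_2 Relaxation times in ms, strictly positive.
#' @param canonicalize Enforce `T2_1 <= T2_2` by swapping labels (default TRUE).
#' @return Named numeric vector of class `biexp_params`.
#' @examples
#' biexp_params(0.2, 20, 80)
#' biexp_params(0.8, 80, 20)  # remapped to the same model
#' @export
biexp_params <- function(c1, T2_1, T2_2, canonicalize = TRUE) {
  p <- c(c1 = as.numeric(c1), T2_1 = as.numeric(T2_1), T2_2 = as.numeric(T2_2))
  if (anyNA(p)) stop("biexp_params: NA parameter")
  if (p["c1"] < 0 || p["c1"] > 1)
    stop(sprintf("biexp_params: c1 = %g violates 0 <= c1 <= 1", p["c1"]))
  if (p["T2_1"] <= 0) stop(sprintf("biexp_params: T2_1 = %g violates T2_1 > 0", p["T2_1"]))
  if (p["T2_2"] <= 0) stop(sprintf("biexp_params: T2_2 = %g violates T2_2 > 0", p["T2_2"]))
  if (canonicalize) p <- canonicalize_params(p)
  class(p) <- "biexp_params"
  p
}

#' Remap a parameter triple into canonical fast-first order
#'
#' @param p Named numeric vector with entries `c1`, `T2_1`, `T2_2`.
#' @return The same triple with `T2_1 <= T2_2`, swapping the component labels
#'   (and replacing `c1` by `1 - c1`) if needed.
#' @export
canonicalize_params <- function(p) {
  if (p[["T2_1"]] > p[["T2_2"]]) {
    p[c("c1", "T2_1", "T2_2")] <- c(1 - p[["c1"]], p[["T2_2"]], p[["T2_1"]])
  }
  p
}

as_param_vector <- function(p) {
  if (inherits(p, "biexp_params")) return(unclass(p))
  if (is.numeric(p) && length(p) == 3L) {
    names(p) <- c("c1", "T2_1", "T2_2")
    return(p)
  }
  stop("expected a biexp_params object or a numeric triple")
}

#' Noise specification for magnitude decay signals
#'
#' Rician magnitude noise: each sample is
#' \eqn{s_n = \sqrt{(G_n + \xi_n)^2 + \eta_n^2}} with \eqn{\xi_n, \eta_n}
#' independent zero-mean Gaussians of standard deviation \eqn{\sigma}. On the
#' unit-normalized signal scale the noise level and the signal-to-noise ratio
#' are linked by \eqn{\sigma = 1/\mathrm{SNR}}, so SNR 5/50/100 are the low,
#' medium and high quality regimes.
#'
#' @param snr Signal-to-noise ratio (ignored when `sigma` is given).
#' @param sigma Gaussian channel standard deviation; overrides `snr`.
#' @return Object of class `noise_spec` with `snr` and `sigma`.
#' @examples
#' noise_spec(snr = 5)     # sigma = 0.2
#' noise_spec(sigma = 0)   # noiseless
#' @export
noise_spec <- function(snr = NULL, sigma = NULL) {
  if (is.null(sigma)) {
    if (is.null(snr)) stop("give either snr or sigma")
    if (snr <= 0) stop("snr must be positive")
    sigma <- 1 / snr
  } else {
    if (sigma < 0) stop("sigma must be nonnegative")
    if (is.null(snr)) snr <- if (sigma == 0) Inf else 1 / sigma
  }
  structure(list(snr = snr, sigma = sigma), class = "noise_spec")
}

#' Clean biexponential forward model
#'
#' Evaluates \eqn{G(p) = c_1 e^{-t_n/T_{2,1}} + (1-c_1) e^{-t_n/T_{2,2}}}
#' on an echo schedule. With \eqn{t_1 = 0} the clean signal starts at exactly
#' 1 and is strictly positive and nonincreasing.
#'
#' @param p A [biexp_params()] triple (or numeric triple in that order).
#' @param schedule An [echo_schedule()].
#' @return A `decay_signal`: list with `values` (length N), `schedule`,
#'   `clean = TRUE`.
#' @examples
#' s <- forward_model(biexp_params(0.5, 20, 80), echo_schedule())
#' s$values[1]  # exactly 1
#' @export
forward_model <- function(p, schedule = echo_schedule()) {
  p <- as_param_vector(validate_params(p))
  v <- biexp_curve(p, schedule$times)
  decay_signal(v, schedule, clean = TRUE)
}

validate_params <- function(p) {
  p <- as_param_vector(p)
  biexp_params(p[["c1"]], p[["T2_1"]], p[["T2_2"]], canonicalize = FALSE)
}

# bare curve evaluation, no validation; t may be any numeric vector
biexp_curve <- function(p, t) {
  p[["c1"]] * exp(-t / p[["T2_1"]]) + (1 - p[["c1"]]) * exp(-t / p[["T2_2"]])
}

#' Decay signal container
#'
#' @param values Length-N nonnegative magnitude vector.
#' @param schedule The [echo_schedule()] the values were sampled on.
#' @param clean TRUE for a noiseless forward-model evaluation, FALSE for
#'   measured/noised magnitudes.
#' @return Object of class `decay_signal`.
#' @export
decay_signal <- function(values, schedule, clean = FALSE) {
  values <- as.numeric(values)
  if (length(values) != schedule$n)
    stop(sprintf("signal length %d does not match schedule N = %d",
                 length(values), schedule$n))
  structure(list(values = values, schedule = schedule, clean = isTRUE(clean)),
            class = "decay_signal")
}

#' @export
print.decay_signal <- function(x, ...) {
  cat(sprintf("<decay_signal> N = %d, %s, s(0) = %.4f\n",
              x$schedule$n, if (x$clean) "clean" else "noisy", x$values[1L]))
  invisible(x)
}

signal_values <- function(s) {
  if (inherits(s, "decay_signal")) s$values else as.numeric(s)
}

#' Analytic sensitivity matrix of the forward model
#'
#' The N x 3 Jacobian \eqn{DG(p)} with columns
#' \eqn{\partial G/\partial c_1 = e^{-t/T_{2,1}} - e^{-t/T_{2,2}}},
#' \eqn{\partial G/\partial T_{2,1} = c_1 t/T_{2,1}^2\, e^{-t/T_{2,1}}},
#' \eqn{\partial G/\partial T_{2,2} = (1-c_1) t/T_{2,2}^2\, e^{-t/T_{2,2}}}.
#' Used by the regularized solver and by the nonlinear GCV influence trace.
#'
#' @inheritParams forward_model
#' @return N x 3 numeric matrix, columns named `c1`, `T2_1`, `T2_2`.
#' @export
forward_jacobian <- function(p, schedule = echo_schedule()) {
  p <- as_param_vector(validate_params(p))
  biexp_jacobian(p, schedule$times)
}

biexp_jacobian <- function(p, t) {
  e1 <- exp(-t / p[["T2_1"]])
  e2 <- exp(-t / p[["T2_2"]])
  J <- cbind(c1   = e1 - e2,
             T2_1 = p[["c1"]] * t / p[["T2_1"]]^2 * e1,
             T2_2 = (1 - p[["c1"]]) * t / p[["T2_2"]]^2 * e2)
  J
}

#' Corrupt a clean decay with Rician noise
#'
#' Applies the magnitude-MRI noise model
#' \eqn{s_n = \sqrt{(G_n + \xi_n)^2 + \eta_n^2}} elementwise, with
#' \eqn{\xi_n, \eta_n \sim N(0, \sigma^2)} independent. The output is
#' nonnegative by construction and carries the familiar Rician bias: its mean
#' exceeds the clean value where the clean value is small relative to
#' \eqn{\sigma} (Rayleigh mean \eqn{\sigma\sqrt{\pi/2}} at zero signal).
#'
#' @param clean A clean `decay_signal` (from [forward_model()]).
#' @param noise A [noise_spec()].
#' @param seed Optional integer seed for reproducible draws.
#' @return A noisy `decay_signal` (`clean = FALSE`; `clean = TRUE` when
#'   `sigma = 0`, since the transform is then the identity on nonnegative
#'   signals).
#' @export
add_rician_noise <- function(clean, noise, seed = NULL) {
  stopifnot(inherits(clean, "decay_signal"))
  if (!clean$clean) stop("add_rician_noise expects a clean signal")
  sigma <- noise$sigma
  if (sigma < 0) stop("sigma must be nonnegative")
  if (sigma == 0) return(clean)
  if (!is.null(seed)) set.seed(seed)
  n <- clean$schedule$n
  xi <- stats::rnorm(n, 0, sigma)
  eta <- stats::rnorm(n, 0, sigma)
  decay_signal(sqrt((clean$values + xi)^2 + eta^2), clean$schedule, clean = FALSE)
}

# Rician noise applied to a matrix of clean rows (vectorized generator path)
rician_noise_matrix <- function(G, sigma) {
  if (sigma == 0) return(G)
  xi <- matrix(stats::rnorm(length(G), 0, sigma), nrow = nrow(G))
  eta <- matrix(stats::rnorm(length(G), 0, sigma), nrow = nrow(G))
  sqrt((G + xi)^2 + eta^2)
}
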