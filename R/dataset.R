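#' Default prior over biexponential parameters
#'
#' Independent uniform ranges over \eqn{(c_1, T_{2,1}, T_{2,2})}, remapped to
#' canonical fast-first order after sampling. The default emulates a broad
#' myelin-water training regime on the 64-echo protocol window: a fast
#' (myelin-like) fraction up to 0.6 -- spanning physiological myelin water
#' fractions (rarely above 0.45 in vivo) with headroom, the slow compartment
#' remaining the majority one -- a fast T2 between 10 and 60 ms -- resolved
#' by only the first handful of echoes, which is what makes the fraction
#' ill-determined even at high SNR -- and a slow (intra/extracellular)
#' T2 between 60 and 300 ms, well sampled by the window. The ranges meet at
#' 60 ms, so near-degenerate pairs occur and regularization is
#' consequential.
#'
#' @param c1_range,T2_1_range,T2_2_range Length-2 numeric ranges.
#' @return A `prior_config` list of ranges.
#' @export
prior_config <- function(c1_range = c(0, 0.6),
                         T2_1_range = c(10, 60),
                         T2_2_range = c(60, 300)) {
  chk <- function(r, nm, lo_ok) {
    if (length(r) != 2L || anyNA(r) || r[1L] > r[2L])
      stop(sprintf("prior_config: invalid range for %s", nm))
    if (!lo_ok && r[1L] <= 0)
      stop(sprintf("prior_config: %s range must be positive", nm))
    as.numeric(r)
  }
  structure(list(c1_range = chk(c1_range, "c1", TRUE),
                 T2_1_range = chk(T2_1_range, "T2_1", FALSE),
                 T2_2_range = chk(T2_2_range, "T2_2", FALSE)),
            class = "prior_config")
}

#' Draw parameter triples from the prior
#'
#' @param n Number of draws.
#' @param prior A [prior_config()].
#' @param seed Optional integer seed.
#' @return An n x 3 matrix with columns `c1`, `T2_1`, `T2_2`, every row in
#'   canonical order (`T2_1 <= T2_2`).
#' @export
sample_parameters <- function(n, prior = prior_config(), seed = NULL) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  # draws interleaved per signal, so the first k rows of a size-n sample
  # equal a size-k sample under the same seed
  U <- matrix(stats::runif(3L * n), ncol = 3L, byrow = TRUE)
  scale_to <- function(u, r) r[1L] + u * (r[2L] - r[1L])
  P <- cbind(c1 = scale_to(U[, 1L], prior$c1_range),
             T2_1 = scale_to(U[, 2L], prior$T2_1_range),
             T2_2 = scale_to(U[, 3L], prior$T2_2_range))
  if (n == 0L) return(P)
  swap <- P[, "T2_1"] > P[, "T2_2"]
  if (any(swap)) {
    tmp <- P[swap, "T2_1"]
    P[swap, "T2_1"] <- P[swap, "T2_2"]
    P[swap, "T2_2"] <- tmp
    P[swap, "c1"] <- 1 - P[swap, "c1"]
  }
  P
}

# deterministic per-signal substream seed below 2^31, so any subset of a
# dataset reproduces independently of batch size
substream_seed <- function(root_seed, index) {
  (as.double(root_seed %% 1000003L) * 1009 + 97 * as.double(index)) %% 2147483647
}

#' Generate a synthetic ensemble of noisy biexponential decays
#'
#' Composes [sample_parameters()], [forward_model()] and
#' [add_rician_noise()] into an index-aligned dataset: row i of `signals`
#' is the Rician-noised decay of row i of `params`. Noise for signal i is
#' drawn from a deterministic substream of `seed`, so regenerating any
#' subset reproduces the same signals.
#'
#' @param n Number of signals.
#' @param prior A [prior_config()].
#' @param noise A [noise_spec()].
#' @param schedule An [echo_schedule()].
#' @param seed Integer root seed.
#' @return Object of class `signal_dataset`: list with `signals` (n x N
#'   matrix), `clean` (n x N matrix of noiseless curves), `params` (n x 3),
#'   `schedule`, `noise`, `seed`.
#' @examples
#' d <- generate_dataset(5, noise = noise_spec(snr = 50), seed = 1)
#' dim(d$signals)
#' @export
generate_dataset <- function(n, prior = prior_config(),
                             noise = noise_spec(snr = 100),
                             schedule = echo_schedule(), seed = 1L) {
  P <- sample_parameters(n, prior, seed = seed)
  N <- schedule$n
  G <- matrix(0, n, N)
  S <- matrix(0, n, N)
  for (i in seq_len(n)) {
    G[i, ] <- biexp_curve(P[i, ], schedule$times)
    if (noise$sigma > 0) {
      set.seed(substream_seed(seed, i))
      xi <- stats::rnorm(N, 0, noise$sigma)
      eta <- stats::rnorm(N, 0, noise$sigma)
      S[i, ] <- sqrt((G[i, ] + xi)^2 + eta^2)
    } else {
      S[i, ] <- G[i, ]
    }
  }
  structure(list(signals = S, clean = G, params = P, schedule = schedule,
                 noise = noise, seed = as.integer(seed)),
            class = "signal_dataset")
}

#' @export
print.signal_dataset <- function(x, ...) {
  cat(sprintf("<signal_dataset> n = %d signals, N = %d echoes, sigma = %g (SNR %g), seed = %d\n",
              nrow(x$signals), x$schedule$n, x$noise$sigma, x$noise$snr, x$seed))
  invisible(x)
}

# i-th signal of a dataset as a decay_signal
dataset_signal <- function(dataset, i) {
  decay_signal(dataset$signals[i, ], dataset$schedule,
               clean = dataset$noise$sigma == 0)
}

#' Export a dataset to CSV
#'
#' One row per signal with columns `id, c1, T2_1, T2_2, s_1..s_N`, plus a
#' JSON sidecar (`<path>.json`) holding the echo times, noise spec and seed.
#'
#' @param dataset A `signal_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  S <- dataset$signals
  colnames(S) <- paste0("s_", seq_len(ncol(S)))
  df <- data.frame(id = seq_len(nrow(S)), dataset$params, S, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(echo_times = dataset$schedule$times,
               sigma = dataset$noise$sigma, snr = dataset$noise$snr,
               seed = dataset$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dataset written by [write_dataset_csv()]
#'
#' @param path CSV path (expects the `.json` sidecar next to it).
#' @return A `signal_dataset` (with `clean` reconstructed from `params`).
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  schedule <- echo_schedule(meta$echo_times)
  P <- as.matrix(df[, c("c1", "T2_1", "T2_2")])
  S <- as.matrix(df[, grep("^s_", names(df))])
  dimnames(S) <- NULL
  G <- t(vapply(seq_len(nrow(P)),
                function(i) biexp_curve(P[i, ], schedule$times),
                numeric(schedule$n)))
  structure(list(signals = S, clean = G, params = P, schedule = schedule,
                 noise = noise_spec(sigma = meta$sigma),
                 seed = as.integer(meta$seed)),
            class = "signal_dataset")
}
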