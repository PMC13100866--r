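# Shared fixtures, generated in code and cached for the duration of a test
# run. The labelled ensemble is the expensive one (per-signal oracle and GCV
# searches), so several test files reuse it.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small labelled SNR-100 ensemble with oracle and GCV lambdas
labelled_ensemble <- function() {
  fixture("labelled100", function() {
    ctl <- fit_control()
    d <- generate_dataset(120, noise = noise_spec(snr = 100), seed = 73)
    d <- attach_oracle_labels(d, ctl)
    gcv <- build_ilr_inputs(d, "gcv", ctl)
    d$gcv_lambda <- gcv$lambdas
    d$gcv_X <- gcv$X
    list(dataset = d, control = ctl)
  })
}

# low-SNR labelled ensemble (oracle lambdas span orders of magnitude there,
# which is the regime where selector skill is demonstrable)
labelled_ensemble_low_snr <- function() {
  fixture("labelled5", function() {
    ctl <- fit_control()
    d <- generate_dataset(150, noise = noise_spec(snr = 5), seed = 74)
    d <- attach_oracle_labels(d, ctl)
    list(dataset = d, control = ctl)
  })
}

# random feasible parameter triples for property tests
random_params <- function(n, seed = 1) {
  sample_parameters(n, prior_config(), seed = seed)
}

# brute-force 1-D W1 for equal small samples: assignment enumeration
w1_enumerate <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) <= 7)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_along(b))) {
    best <- min(best, mean(abs(a - b[p])))
  }
  best
}

# dense grid evaluation of the (regularized) objective over the feasible box;
# independent of the solver path
grid_objective_min <- function(s_values, ctl, lambda = 0, n_c1 = 40, n_t2 = 40) {
  t <- ctl$schedule$times
  c1s <- seq(0, 1, length.out = n_c1)
  t2s <- exp(seq(log(1), log(ctl$t2_cap), length.out = n_t2))
  E <- exp(-outer(t, t2s, "/"))  # N x n_t2
  best <- Inf
  for (i in seq_along(t2s)) for (j in seq_along(t2s)) {
    # curves for all c1 at this T2 pair in one matrix product
    M <- E[, i, drop = FALSE] %*% t(c1s) + E[, j, drop = FALSE] %*% t(1 - c1s)
    fid <- colSums((M - s_values)^2)
    pen <- lambda * ((ctl$B_pen[1] * c1s)^2 + (ctl$B_pen[2] * t2s[i])^2 +
                       (ctl$B_pen[3] * t2s[j])^2)
    best <- min(best, min(fid + pen))
  }
  best
}
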