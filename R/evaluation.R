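#' Root mean squared error
#'
#' @param pred,true Equal-length numeric vectors.
#' @return \eqn{\sqrt{\mathrm{mean}((pred - true)^2)}}.
#' @export
rmse <- function(pred, true) {
  if (length(pred) != length(true)) stop("rmse: length mismatch")
  if (length(pred) == 0L) stop("rmse: empty input")
  sqrt(mean((pred - true)^2))
}

#' 1-D Wasserstein-1 (earth mover's) distance between empirical samples
#'
#' For equal sample sizes this is the mean absolute difference of the
#' sorted samples; in general it is the integral of the absolute difference
#' of the two empirical CDFs, computed exactly from the pooled order
#' statistics.
#'
#' @param a,b Nonempty numeric samples (sizes may differ).
#' @return Nonnegative scalar distance.
#' @examples
#' wasserstein1_1d(c(0, 1), c(1, 2))  # 1
#' @export
wasserstein1_1d <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("wasserstein1_1d: empty sample")
  if (length(a) == length(b)) {
    return(mean(abs(sort(a) - sort(b))))
  }
  x <- sort(c(a, b))
  dx <- diff(x)
  xs <- x[-length(x)]
  Fa <- stats::ecdf(a)(xs)
  Fb <- stats::ecdf(b)(xs)
  sum(abs(Fa - Fb) * dx)
}

canonicalize_matrix <- function(P) {
  swap <- P[, "T2_1"] > P[, "T2_2"]
  if (any(swap)) {
    tmp <- P[swap, "T2_1"]
    P[swap, "T2_1"] <- P[swap, "T2_2"]
    P[swap, "T2_2"] <- tmp
    P[swap, "c1"] <- 1 - P[swap, "c1"]
  }
  P
}

#' Benchmark parameter estimators on a common test ensemble
#'
#' Runs the requested estimators signal-by-signal on one test set and
#' aggregates per-parameter RMSE (estimates canonicalized before
#' comparison). Classical methods: `"nlls"`, `"trnlls_oracle"` (needs the
#' stored generating parameters), `"trnlls_gcv"`. Network methods:
#' `"ndnd"`, `"ndreg_gcv"`, `"ndreg_network"` (need trained models). A
#' method failing wholesale is reported as missing and the run continues.
#'
#' @param test A `signal_dataset`.
#' @param methods Character vector of method names.
#' @param control A [fit_control()].
#' @param models Named list of trained models: `pe_<variant>` entries
#'   (`pe_estimator`s) for the network methods and `lambda_net` (a
#'   `lambda_selector`) for `"ndreg_network"`.
#' @param lambdas Optional named list of precomputed per-signal lambda
#'   vectors (`oracle`, `gcv`) reused across methods to avoid repeated
#'   searches.
#' @param progress Print a dot every `progress` signals (0 = silent).
#' @return An `evaluation_report`: list with `table` (data.frame of
#'   per-method RMSEs), `predictions` (named list of n x 3 matrices),
#'   `lambdas`, `errors` (per-method failure messages), `n_test`.
#' @export
benchmark_estimators <- function(test,
                                 methods = c("nlls", "trnlls_oracle", "trnlls_gcv"),
                                 control = fit_control(test$schedule),
                                 models = list(), lambdas = list(),
                                 progress = 0L) {
  S <- test$signals
  n <- nrow(S)
  truth <- canonicalize_matrix(test$params)
  preds <- list()
  errors <- list()
  lam_store <- lambdas

  need_oracle <- any(methods %in% c("trnlls_oracle")) ||
    ("ndreg_oracle" %in% methods)
  if (need_oracle && is.null(lam_store$oracle)) {
    if (!is.null(test$oracle_lambda)) lam_store$oracle <- test$oracle_lambda
  }
  run_method <- function(method) {
    switch(method,
      nlls = {
        P <- t(vapply(seq_len(n), function(i) {
          canonicalize_params(nlls_fit(S[i, ], control)$params)
        }, numeric(3L)))
        colnames(P) <- c("c1", "T2_1", "T2_2")
        P
      },
      trnlls_oracle = {
        if (is.null(lam_store$oracle)) {
          lam <- numeric(n)
          P <- matrix(0, n, 3L, dimnames = list(NULL, c("c1", "T2_1", "T2_2")))
          for (i in seq_len(n)) {
            sel <- lambda_oracle(S[i, ], test$params[i, ], control)
            lam[i] <- sel$lambda
            P[i, ] <- canonicalize_params(sel$fit$params)
            if (progress > 0L && i %% progress == 0L) cat(".")
          }
          lam_store$oracle <<- lam
          P
        } else {
          t(vapply(seq_len(n), function(i) {
            canonicalize_params(
              tr_nlls_fit(S[i, ], lam_store$oracle[i], control)$params)
          }, numeric(3L)))
        }
      },
      trnlls_gcv = {
        if (is.null(lam_store$gcv)) {
          lam <- numeric(n)
          P <- matrix(0, n, 3L, dimnames = list(NULL, c("c1", "T2_1", "T2_2")))
          for (i in seq_len(n)) {
            sel <- lambda_gcv(S[i, ], control)
            lam[i] <- sel$lambda
            P[i, ] <- canonicalize_params(sel$fit$params)
            if (progress > 0L && i %% progress == 0L) cat(".")
          }
          lam_store$gcv <<- lam
          P
        } else {
          t(vapply(seq_len(n), function(i) {
            canonicalize_params(
              tr_nlls_fit(S[i, ], lam_store$gcv[i], control)$params)
          }, numeric(3L)))
        }
      },
      ndnd = {
        est <- models$pe_ndnd
        if (is.null(est)) stop("no pe_ndnd model supplied")
        estimate_params(est, cbind(S, S))
      },
      ndreg_gcv = {
        est <- models$pe_ndreg_gcv
        if (is.null(est)) stop("no pe_ndreg_gcv model supplied")
        inp <- build_ilr_inputs(test, "gcv", control,
                                lambdas = lam_store$gcv, progress = progress)
        lam_store$gcv <<- inp$lambdas
        estimate_params(est, inp$X)
      },
      ndreg_network = {
        est <- models$pe_ndreg_network
        if (is.null(est)) stop("no pe_ndreg_network model supplied")
        if (is.null(models$lambda_net)) stop("no lambda_net supplied")
        inp <- build_ilr_inputs(test, "network", control,
                                selector = models$lambda_net,
                                progress = progress)
        estimate_params(est, inp$X)
      },
      stop("unknown method: ", method))
  }

  for (m in methods) {
    res <- tryCatch(run_method(m), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[m]] <- conditionMessage(res)
    } else {
      preds[[m]] <- res
    }
  }
  tab <- do.call(rbind, lapply(names(preds), function(m) {
    P <- preds[[m]]
    data.frame(method = m,
               rmse_c1 = rmse(P[, "c1"], truth[, "c1"]),
               rmse_T2_1 = rmse(P[, "T2_1"], truth[, "T2_1"]),
               rmse_T2_2 = rmse(P[, "T2_2"], truth[, "T2_2"]))
  }))
  structure(list(table = tab, predictions = preds, truth = truth,
                 lambdas = lam_store, errors = errors, n_test = n,
                 snr = test$noise$snr, seed = test$seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d signals, SNR = %g\n", x$n_test, x$snr))
  print(x$table, row.names = FALSE)
  if (length(x$errors)) {
    cat("missing methods:\n")
    for (m in names(x$errors)) cat(sprintf("  %s: %s\n", m, x$errors[[m]]))
  }
  invisible(x)
}

#' Recompute the RMSE table of a report from its stored predictions
#'
#' @param report An `evaluation_report`.
#' @return A data.frame identical to `report$table`.
#' @export
recompute_report <- function(report) {
  do.call(rbind, lapply(names(report$predictions), function(m) {
    P <- report$predictions[[m]]
    data.frame(method = m,
               rmse_c1 = rmse(P[, "c1"], report$truth[, "c1"]),
               rmse_T2_1 = rmse(P[, "T2_1"], report$truth[, "T2_1"]),
               rmse_T2_2 = rmse(P[, "T2_2"], report$truth[, "T2_2"]))
  }))
}

#' Compare lambda-selector ensembles against the oracle ensemble
#'
#' Computes the Wasserstein-1 distance between each selector's empirical
#' lambda distribution and the oracle distribution over a labelled test
#' set, plus shared-bin histogram counts (log10 lambda bins) for overlay
#' plots.
#'
#' @param test A `signal_dataset` with `oracle_lambda` labels.
#' @param selectors Named list of per-signal lambda vectors, e.g.
#'   `list(gcv = ..., network = ...)` (lengths matching the test set).
#' @param breaks Number of log10-lambda histogram bins.
#' @return List with `table` (data.frame: selector, w1), `ensembles`
#'   (including `oracle`), and `histograms` (data.frame of bin counts).
#' @export
lambda_distribution_report <- function(test, selectors, breaks = 40L) {
  oracle <- test$oracle_lambda
  if (is.null(oracle)) stop("test dataset has no oracle_lambda labels")
  tab <- do.call(rbind, lapply(names(selectors), function(nm) {
    lam <- selectors[[nm]]
    if (length(lam) != length(oracle)) stop("selector ensemble length mismatch")
    data.frame(selector = nm, w1 = wasserstein1_1d(lam, oracle))
  }))
  all_l <- c(oracle, unlist(selectors))
  all_l <- pmax(all_l, lambda_search_space[1L])
  edges <- seq(log10(min(all_l)), log10(max(all_l)) + 1e-9, length.out = breaks + 1L)
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  hist_of <- function(lam, nm) {
    bin <- findInterval(log10(pmax(lam, lambda_search_space[1L])), edges,
                        rightmost.closed = TRUE, all.inside = TRUE)
    data.frame(selector = nm, log10_lambda_mid = mids,
               count = tabulate(bin, nbins = breaks))
  }
  histograms <- rbind(hist_of(oracle, "oracle"),
                      do.call(rbind, lapply(names(selectors), function(nm)
                        hist_of(selectors[[nm]], nm))))
  list(table = tab,
       ensembles = c(list(oracle = oracle), selectors),
       histograms = histograms)
}
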