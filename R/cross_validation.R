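#' Two-sided t critical value
#'
#' @param df Degrees of freedom (>= 1).
#' @param level Two-sided significance level (default 0.05).
#' @return The `1 - level/2` quantile of the t distribution.
#' @export
t_critical <- function(df, level = 0.05) {
  stopifnot(df >= 1, level > 0, level < 1)
  stats::qt(1 - level / 2, df)
}

#' Leave-one-double-out prediction
#'
#' For each double mutant in turn: remove it, re-fit the map to the remaining
#' data (with the shift held at its full-data estimate), and predict the
#' removed double's fitness as `f(z_i + z_j)` from the reduced fit's imputed
#' phenotypes. The discrepancy is reported as a number of residual standard
#' deviations, `|observed - predicted| / sigma_hat` with
#' `sigma_hat = sqrt(SSE_reduced / df_SSE_reduced)`, and flagged significant
#' when it exceeds the two-sided t critical value at the reduced df.
#'
#' @param data A `fit_input` or effect table.
#' @param level Significance level for the flag (default 0.05, two-sided).
#' @param ... Passed to [fit_gamma_map()] (e.g. `max_iter`, `tol`,
#'   `free_scale`).
#' @return Data frame with one row per double: `removed`, `predicted`,
#'   `observed`, `df`, `sigma`, `n_sd`, `significant`, `converged`.
#' @export
loo_predict <- function(data, level = 0.05, ...) {
  if (is.data.frame(data)) data <- fit_input(data)
  stopifnot(inherits(data, "fit_input"))
  all_w <- c(data$w_singles, data$w_doubles,
             if (!is.null(data$wt_mean)) data$wt_mean)
  shift <- estimate_shift(all_w)
  # Each reduced fit is cold-started with the same deterministic multistart
  # as a full fit: nothing about the held-out observation (not even the
  # full-data solution as a warm start) may influence the reduced fit.
  labels <- names(data$w_doubles)
  rows <- lapply(seq_along(labels), function(k) {
    reduced <- data
    reduced$w_doubles <- data$w_doubles[-k]
    reduced$pairs <- data$pairs[-k, , drop = FALSE]
    fit <- fit_gamma_map(reduced, shift = shift, ...)
    z <- fit$phenotypes$z
    pred <- gamma_fitness(fit$params,
                          z[[data$pairs[k, 1L]]] + z[[data$pairs[k, 2L]]])
    d <- fit$diagnostics
    err <- abs(data$w_doubles[[k]] - pred)
    if (d$df_sse < 1L || is.na(d$sigma2)) {
      sigma <- NA_real_
      n_sd <- NA_real_
      sig <- NA
    } else {
      sigma <- sqrt(d$sigma2)
      # exact-fit degeneracy: when both the residual SD and the prediction
      # discrepancy are at numerical zero, the discrepancy in SD units is
      # 0, not the ratio of two rounding errors
      n_sd <- if (err < 1e-8 && sigma < 1e-8) 0 else err / sigma
      sig <- n_sd > t_critical(d$df_sse, level)
    }
    data.frame(removed = labels[k], predicted = pred,
               observed = data$w_doubles[[k]], df = d$df_sse, sigma = sigma,
               n_sd = n_sd, significant = sig,
               converged = fit$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
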