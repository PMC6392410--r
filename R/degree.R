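#' Degree sequence of a bipartite matrix
#'
#' @param matrix A `bipartite_matrix`.
#' @param guild `"rows"` (plant families), `"cols"` (hummingbird clades) or
#'   `"combined"` (both guilds pooled, the form used for the network-wide
#'   connectivity distribution).
#' @return Integer vector of node degrees (all positive by matrix invariants).
#' @export
degree_sequence <- function(matrix, guild = c("rows", "cols", "combined")) {
  guild <- match.arg(guild)
  m <- unclass_matrix(matrix)
  switch(guild,
         rows = as.integer(rowSums(m)),
         cols = as.integer(colSums(m)),
         combined = as.integer(c(rowSums(m), colSums(m))))
}

#' Cumulative degree distribution
#'
#' For each distinct degree k, the fraction of nodes with degree at least k:
#' P(k) = #\{degrees >= k\}/n. P at the smallest k is 1 and P is
#' non-increasing in k.
#'
#' @param degrees Non-empty vector of positive integer degrees.
#' @return An object of class `degree_distribution` with elements `k`
#'   (ascending distinct degrees), `cum_prob` and `n_nodes`.
#' @export
cumulative_distribution <- function(degrees) {
  if (length(degrees) == 0) stop("empty degree sequence")
  stopifnot(all(degrees >= 1))
  k <- sort(unique(degrees))
  cum_prob <- vapply(k, function(kk) mean(degrees >= kk), numeric(1))
  structure(list(k = k, cum_prob = cum_prob, n_nodes = length(degrees)),
            class = "degree_distribution")
}

#' Fit connectivity-distribution models and select by AIC
#'
#' Fits three candidate forms to the cumulative degree distribution P(k) by
#' nonlinear least squares on the untransformed probabilities:
#' exponential \eqn{P(k) = e^{-k/\gamma}}, power law \eqn{P(k) = k^{-\gamma}}
#' and truncated power law \eqn{P(k) = k^{-\gamma} e^{-k/k_c}}. Each fit gets
#' a least-squares AIC, \eqn{n \ln(RSS/n) + 2p} with p free parameters (RSS
#' floored at 1e-12), and the model with the lowest AIC is selected. A model
#' whose optimiser fails to converge is flagged unfit and excluded from
#' selection with a warning.
#'
#' Starting values: the exponent/rate from a log-log (or semi-log) regression
#' slope, and the truncation cutoff at the largest observed degree.
#'
#' @param dist A `degree_distribution` with at least 3 distinct degrees.
#' @return An object of class `degree_fit`: list with `fits` (per-model list
#'   of `model`, `params`, `rss`, `aic`, `converged`) and `best` (name of the
#'   AIC-selected model).
#' @export
fit_degree_models <- function(dist) {
  stopifnot(inherits(dist, "degree_distribution"))
  if (length(dist$k) < 3) stop("need at least 3 distinct degrees to fit")
  k <- dist$k
  p <- dist$cum_prob
  n <- length(k)

  slope_loglog <- unname(stats::coef(stats::lm(log(p) ~ log(k)))[2])
  slope_semilog <- unname(stats::coef(stats::lm(log(p) ~ k))[2])
  g0_pow <- max(0.1, -slope_loglog)
  g0_exp <- max(0.5, -1 / min(slope_semilog, -1e-6))

  fit_one <- function(model, formula, start, lower) {
    res <- tryCatch(
      minpack.lm::nlsLM(formula, data = data.frame(k = k, p = p),
                        start = start, lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(res, "error")) {
      return(list(model = model, params = unlist(start), rss = NA_real_,
                  aic = NA_real_, converged = FALSE))
    }
    rss <- max(sum(stats::residuals(res)^2), 1e-12)
    np <- length(start)
    list(model = model, params = stats::coef(res), rss = rss,
         aic = n * log(rss / n) + 2 * np, converged = TRUE)
  }

  fits <- list(
    exponential = fit_one("exponential", p ~ exp(-k / gamma),
                          list(gamma = g0_exp), lower = 1e-8),
    power_law = fit_one("power_law", p ~ k^(-gamma),
                        list(gamma = g0_pow), lower = 1e-8),
    truncated_power_law = fit_one("truncated_power_law",
                                  p ~ k^(-gamma) * exp(-k / kc),
                                  list(gamma = g0_pow, kc = max(k)),
                                  lower = c(1e-8, 1e-8))
  )
  ok <- vapply(fits, function(f) f$converged, logical(1))
  if (!all(ok)) {
    warning("model(s) failed to converge and were excluded from selection: ",
            paste(names(fits)[!ok], collapse = ", "))
  }
  if (!any(ok)) stop("no degree-distribution model converged")
  aics <- vapply(fits[ok], function(f) f$aic, numeric(1))
  structure(list(fits = fits, best = names(aics)[which.min(aics)]),
            class = "degree_fit")
}

#' @export
print.degree_fit <- function(x, ...) {
  cat("cumulative degree distribution fits (least squares on P(k)):\n")
  for (f in x$fits) {
    cat(sprintf("  %-20s %s  RSS = %s  AIC = %s%s\n", f$model,
                paste(sprintf("%s = %.4g", names(f$params), f$params),
                      collapse = ", "),
                if (f$converged) sprintf("%.4g", f$rss) else "-",
                if (f$converged) sprintf("%.3f", f$aic) else "unfit",
                if (identical(f$model, x$best)) "  <- selected" else ""))
  }
  invisible(x)
}
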