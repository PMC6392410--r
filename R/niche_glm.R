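#' Multi-region response for the niche-conservatism model
#'
#' A species is a "success" (1) when it is distributed in two or three of the
#' Nearctic, Neotropical and Austral regions, and a "failure" (0) when it
#' occupies only one. Species with no mainland-region flag get NA (they drop
#' out of the model).
#'
#' @param table A `species_biogeo` data frame.
#' @return Integer vector of 0/1/NA, one per species.
#' @export
make_response <- function(table) {
  nr <- n_regions(table)
  out <- as.integer(nr >= 2)
  out[nr == 0] <- NA_integer_
  out
}

#' Binomial GLM of multi-region occupancy
#'
#' Fits a binomial GLM (via iteratively reweighted least squares) of the
#' multi-region response on either the center of diversification or the
#' clade. The reference level for the center is South America, so the
#' exponentiated coefficient is directly the odds ratio for northern versus
#' southern diversification. Species without a mainland-region flag are
#' dropped, as are clades with a single species (Patagona), for which no
#' within-clade contrast exists.
#'
#' @param table A `species_biogeo` data frame.
#' @param predictor `"center"` or `"clade"`.
#' @param link `"logit"` or `"probit"`.
#' @return An object of class `niche_glm`: list with `coefficients`,
#'   `covariance`, `deviance`, `null_deviance`, `df_residual`,
#'   `odds_ratios` (logit link only), `link`, `predictor`, `n`, and `fit`
#'   (the underlying [stats::glm()] object).
#' @export
fit_niche_glm <- function(table, predictor = c("center", "clade"),
                          link = c("logit", "probit")) {
  predictor <- match.arg(predictor)
  link <- match.arg(link)
  y <- make_response(table)
  keep <- !is.na(y)
  clade_sizes <- table(table$clade[keep])
  single <- names(clade_sizes)[clade_sizes < 2]
  keep <- keep & !(table$clade %in% single)
  dat <- data.frame(
    y = y[keep],
    center = factor(table$center[keep],
                    levels = c("South America", "North America")),
    clade = factor(table$clade[keep]))
  form <- if (predictor == "center") y ~ center else y ~ clade
  x <- stats::model.matrix(form, dat)
  if (qr(x)$rank < ncol(x)) {
    stop("rank-deficient design; aliased level(s) in ", predictor)
  }
  fit <- stats::glm(form, data = dat, family = stats::binomial(link),
                    control = stats::glm.control(epsilon = 1e-8))
  mu <- stats::fitted(fit)
  if (any(mu < 1e-8 | mu > 1 - 1e-8)) {
    warning("fitted probabilities numerically 0 or 1; possible complete ",
            "separation (coefficients may diverge)")
  }
  structure(list(
    coefficients = stats::coef(fit),
    covariance = stats::vcov(fit),
    deviance = stats::deviance(fit),
    null_deviance = fit$null.deviance,
    df_residual = fit$df.residual,
    odds_ratios = if (link == "logit") exp(stats::coef(fit)),
    link = link, predictor = predictor, n = nrow(dat), fit = fit),
    class = "niche_glm")
}

#' @export
print.niche_glm <- function(x, ...) {
  cat(sprintf("binomial GLM (%s link), %s predictor, n = %d\n",
              x$link, x$predictor, x$n))
  cat(sprintf("  deviance %.3f on %d df (null %.3f)\n",
              x$deviance, x$df_residual, x$null_deviance))
  if (!is.null(x$odds_ratios)) {
    print(round(x$odds_ratios, 3))
  } else {
    print(round(x$coefficients, 3))
  }
  invisible(x)
}

#' Likelihood-ratio chi-square test between nested GLMs
#'
#' Chi = deviance(reduced) - deviance(full) on df = difference in parameter
#' counts, with an upper-tail chi-square p-value. With `reduced = NULL` the
#' full model is tested against its own intercept-only null.
#'
#' @param full A `niche_glm`.
#' @param reduced A `niche_glm` nested in `full`, or `NULL`.
#' @return List with `chi`, `df`, `p`.
#' @export
lr_chi_test <- function(full, reduced = NULL) {
  stopifnot(inherits(full, "niche_glm"))
  if (is.null(reduced)) {
    chi <- full$null_deviance - full$deviance
    df <- full$fit$df.null - full$df_residual
  } else {
    stopifnot(inherits(reduced, "niche_glm"))
    if (reduced$df_residual < full$df_residual ||
        full$n != reduced$n ||
        !all(names(reduced$coefficients) %in% names(full$coefficients))) {
      stop("models are not nested (reduced must use a subset of terms on ",
           "the same observations)")
    }
    chi <- reduced$deviance - full$deviance
    df <- reduced$df_residual - full$df_residual
  }
  list(chi = chi, df = df,
       p = stats::pchisq(chi, df, lower.tail = FALSE))
}

#' Pairwise contrasts between clade levels
#'
#' Wald chi-square tests of all pairwise differences between the levels of
#' the clade predictor, on the coefficient scale, with Bonferroni adjustment
#' over the full number of pairs tested (choose(k, 2) for k levels).
#'
#' @param model A `niche_glm` fitted with the clade predictor.
#' @param alpha Significance level used for the `significant` flag.
#' @return A data frame of class `contrast_table` with one row per pair:
#'   `pair`, `estimate`, `odds_ratio`, `chi`, `df`, `p_raw`, `p_bonferroni`,
#'   `significant`.
#' @export
pairwise_contrasts <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "niche_glm"))
  if (model$predictor != "clade") {
    stop("pairwise contrasts need the clade predictor")
  }
  lev <- levels(model$fit$model$clade)
  k <- length(lev)
  if (k < 2) stop("need at least 2 clade levels")
  beta <- model$coefficients
  V <- model$covariance
  coef_of <- function(l) {
    # reference level has implicit coefficient 0
    nm <- paste0("clade", l)
    if (nm %in% names(beta)) {
      v <- numeric(length(beta)); names(v) <- names(beta); v[nm] <- 1; v
    } else {
      numeric(length(beta))
    }
  }
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(i) {
    cv <- coef_of(pairs[1, i]) - coef_of(pairs[2, i])
    est <- sum(cv * beta)
    se <- sqrt(drop(t(cv) %*% V %*% cv))
    chi <- (est / se)^2
    p <- stats::pchisq(chi, 1, lower.tail = FALSE)
    data.frame(pair = paste(pairs[1, i], "-", pairs[2, i]),
               estimate = est,
               odds_ratio = if (model$link == "logit") exp(abs(est)) else NA_real_,
               chi = chi, df = 1L, p_raw = p,
               p_bonferroni = min(1, m * p))
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_bonferroni <= alpha
  class(out) <- c("contrast_table", class(out))
  out
}

#' Overdispersion check
#'
#' Dispersion ratio = Pearson chi-square statistic / residual degrees of
#' freedom; values well above 1 (flagged at > 1.5) suggest overdispersion.
#' For a strictly binary response the ratio is reported with the usual
#' caveat that it is only a rough diagnostic (binary data carry little
#' information about dispersion).
#'
#' @param model A `niche_glm`.
#' @param flag_above Ratio above which the `overdispersed` flag is set.
#' @return List with `ratio`, `pearson_chisq`, `df`, `overdispersed`.
#' @export
overdispersion_check <- function(model, flag_above = 1.5) {
  stopifnot(inherits(model, "niche_glm"))
  if (model$df_residual == 0) {
    stop("residual df is 0; dispersion ratio undefined")
  }
  chisq <- sum(stats::residuals(model$fit, type = "pearson")^2)
  ratio <- chisq / model$df_residual
  list(ratio = ratio, pearson_chisq = chisq, df = model$df_residual,
       overdispersed = ratio > flag_above)
}
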