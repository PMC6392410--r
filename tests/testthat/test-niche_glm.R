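glm_table <- function(success, n, center, clade = NULL) {
  k <- length(n)
  if (is.null(clade)) clade <- paste0("Clade", seq_len(k))
  rows <- mapply(function(s, nn, ctr, cl) {
    data.frame(nearctic = c(rep(TRUE, s), rep(FALSE, nn - s)),
               neotropical = TRUE, austral = FALSE,
               center = ctr, clade = cl)
  }, success, n, center, clade, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  out$species <- paste0("sp", seq_len(nrow(out)))
  out$lat_min <- -10; out$lat_max <- 10
  out$elev_min <- 0; out$elev_max <- 1000
  out
}

test_that("the response is 1 for two or more regions, NA for none", {
  tab <- data.frame(nearctic = c(TRUE, FALSE, FALSE),
                    neotropical = c(TRUE, TRUE, FALSE),
                    austral = c(FALSE, FALSE, FALSE))
  expect_identical(make_response(tab), c(1L, 0L, NA_integer_))
})

test_that("a 2x2 logistic fit recovers the cross-product odds ratio", {
  tab <- glm_table(c(8, 2), c(10, 10),
                   c("North America", "South America"),
                   c("Bees", "Hermits"))
  fit <- fit_niche_glm(tab, "center", "logit")
  expect_equal(unname(fit$odds_ratios["centerNorth America"]),
               (8 * 8) / (2 * 2), tolerance = 1e-6)
  expect_lte(fit$deviance, fit$null_deviance + 1e-8)
  expect_true(all(fit$odds_ratios > 0))

  probit <- fit_niche_glm(tab, "center", "probit")
  expect_equal(sign(probit$coefficients[2]), sign(fit$coefficients[2]))
  expect_null(probit$odds_ratios)

  # single-species clades are dropped before fitting
  tab2 <- rbind(tab, glm_table(1, 1, "South America", "Patagona"))
  fit2 <- fit_niche_glm(tab2, "clade", "logit")
  expect_equal(fit2$n, 20)

  # all-equal response pins the fit at the boundary
  expect_warning(fit_niche_glm(glm_table(c(10, 10), c(10, 10),
                                         c("North America", "South America"),
                                         c("Bees", "Hermits")),
                               "center"),
                 "separation|0 or 1")
})

test_that("the LR test is zero for identical models and calibrated under the null", {
  tab <- glm_table(c(8, 5), c(20, 20),
                   c("North America", "South America"), c("Bees", "Hermits"))
  fit <- fit_niche_glm(tab, "center")
  same <- lr_chi_test(fit, fit)
  expect_equal(same$chi, 0)
  expect_equal(same$p, 1)

  lrt <- lr_chi_test(fit)
  expect_equal(lrt$chi, fit$null_deviance - fit$deviance)
  expect_equal(lrt$df, 1)

  # type-I rate near alpha for data with no center effect
  set.seed(200)
  rej <- 0
  n_trial <- 400
  for (i in seq_len(n_trial)) {
    s <- stats::rbinom(2, 50, 0.3)
    t <- glm_table(s, c(50, 50), c("North America", "South America"),
                   c("Bees", "Hermits"))
    rej <- rej + (lr_chi_test(fit_niche_glm(t, "center"))$p <= 0.05)
  }
  expect_gt(rej / n_trial, 0.02)
  expect_lt(rej / n_trial, 0.08)
})

test_that("pairwise contrasts enumerate all pairs with Bonferroni adjustment", {
  clades <- c("Bees", "Brilliants", "Coquettes", "Emeralds",
              "Hermits", "Mangoes", "Mountain Gems", "Topazes")
  set.seed(42)
  tab <- glm_table(c(20, 5, 8, 12, 3, 6, 10, 4), rep(30, 8),
                   rep("South America", 8), clades)
  fit <- fit_niche_glm(tab, "clade")
  ct <- pairwise_contrasts(fit)
  expect_equal(nrow(ct), choose(8, 2))
  expect_equal(ct$p_bonferroni, pmin(1, 28 * ct$p_raw))
  expect_true(all(ct$df == 1))
  expect_true(all(ct$odds_ratio >= 1))  # reported as |difference| on exp scale
})

test_that("pairwise Wald contrasts agree with multcomp::glht", {
  skip_if_not_installed("multcomp")
  set.seed(43)
  tab <- glm_table(c(15, 5, 9, 20), rep(30, 4), rep("South America", 4),
                   c("Bees", "Brilliants", "Hermits", "Mangoes"))
  fit <- fit_niche_glm(tab, "clade")
  ct <- pairwise_contrasts(fit)
  gl <- summary(multcomp::glht(fit$fit, multcomp::mcp(clade = "Tukey")),
                test = multcomp::adjusted("none"))
  # glht reports level2 - level1; ours is level1 - level2
  expect_equal(unname(abs(ct$estimate)),
               unname(abs(as.numeric(gl$test$coefficients))),
               tolerance = 1e-6)
  expect_equal(unname(ct$p_raw), unname(as.numeric(gl$test$pvalues)),
               tolerance = 1e-5)
})

test_that("dispersion ratio is near one for well-specified binomial data", {
  set.seed(77)
  ratios <- replicate(50, {
    tab <- glm_table(stats::rbinom(2, 100, c(0.6, 0.3)), c(100, 100),
                     c("North America", "South America"),
                     c("Bees", "Hermits"))
    overdispersion_check(fit_niche_glm(tab, "center"))$ratio
  })
  expect_equal(mean(ratios), 1, tolerance = 0.1)

  tab <- glm_table(c(8, 2), c(10, 10), c("North America", "South America"),
                   c("Bees", "Hermits"))
  fit <- fit_niche_glm(tab, "center")
  expect_false(overdispersion_check(fit)$overdispersed)
  fit0 <- fit
  fit0$df_residual <- 0
  expect_error(overdispersion_check(fit0), "df")
})

test_that("the fixture table reproduces the published GLM statistics", {
  bio <- read_biogeo(extdata("synthetic_biogeo.csv"))
  fit <- fit_niche_glm(bio, "center", "logit")
  expect_equal(unname(fit$odds_ratios["centerNorth America"]), 9.080,
               tolerance = 1e-4)
  lrt <- lr_chi_test(fit)
  expect_equal(lrt$chi, 46.114, tolerance = 1e-4)
  expect_equal(lrt$df, 1)
  expect_lt(lrt$p, 0.001)

  fit_cl <- fit_niche_glm(bio, "clade", "logit")
  lrt_cl <- lr_chi_test(fit_cl)
  expect_equal(lrt_cl$chi, 21.887, tolerance = 1e-4)
  expect_equal(lrt_cl$df, 7)
  expect_equal(nrow(pairwise_contrasts(fit_cl)), 28)
  # Patagona (single species) is excluded; islanders carry no region
  expect_equal(fit$n, 276)
})
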