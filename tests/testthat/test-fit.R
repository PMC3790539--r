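test_that("null-model fit recovers the generating density", {
  ms <- model_true_history(11, D = 1.5, g0 = 0.1, sigma = 600,
                           nx = 8, ny = 5, spacing = 1000, S = 20)
  mask <- build_mask(ms$cameras, 2500, 300)
  fit <- fit_secr(ms$history, mask, secr_spec("null", "bernoulli", "poisson"),
                  n_restarts = 2)
  expect_true(fit$convergence)
  expect_lt(abs(fit$derived$D - 1.5) / fit$derived$se_D, 3)
  expect_true(fit$derived$lcl_D < fit$derived$D &&
                fit$derived$D < fit$derived$ucl_D)
  expect_equal(fit$AIC, 2 * fit$k - 2 * fit$logLik)
})

test_that("AICc prefers the null model when sexes are assigned at random", {
  wins <- 0
  for (seed in 1:5) {
    ms <- model_true_history(seed + 40, D = 2, g0 = 0.15, sigma = 600,
                             nx = 6, ny = 4, spacing = 900, S = 10,
                             buffer = 2000)
    h <- ms$history
    set.seed(seed)
    h$covariates$sex <- sample(c("female", "male"), h$n, replace = TRUE)
    mask <- build_mask(ms$cameras, 2400, 400)
    f0 <- fit_secr(h, mask, secr_spec("null", "bernoulli", "poisson"),
                   n_restarts = 1)
    f1 <- fit_secr(h, mask, secr_spec("sex", "bernoulli", "poisson"),
                   n_restarts = 1)
    if (isTRUE(f0$convergence) && isTRUE(f1$convergence) &&
        f0$AICc < f1$AICc) wins <- wins + 1
  }
  expect_gte(wins, 3)
})

fake_fit <- function(variant, k, logLik, n = 50) {
  aic <- 2 * k - 2 * logLik
  structure(list(spec = list(variant = variant), k = k, n = n,
                 logLik = logLik, AIC = aic,
                 AICc = if (n > k + 1) {
                   aic + 2 * k * (k + 1) / (n - k - 1)
                 } else NA_real_),
            class = "secr_fit")
}

test_that("model tables rank by AICc with normalized Akaike weights", {
  single <- compare_models(list(fake_fit("null", 3, -100)))
  expect_equal(single$dAICc, 0)
  expect_equal(single$AICwt, 1)

  pair <- compare_models(list(fake_fit("null", 3, -100),
                              fake_fit("sex", 3, -100)))
  expect_equal(pair$AICwt, c(0.5, 0.5))

  # dAICc pattern 0 / 3.6 / 12.3 reproduces the published weight pattern
  f1 <- fake_fit("grouphet", 3, -100)
  f2 <- fake_fit("group", 3, -100 - 3.6 / 2)
  f3 <- fake_fit("sexhet", 3, -100 - 12.3 / 2)
  tab <- compare_models(list(f2, f3, f1))
  expect_equal(tab$model, c("grouphet", "group", "sexhet"))
  expect_equal(round(tab$AICwt, 2), c(0.86, 0.14, 0))
  expect_equal(sum(tab$AICwt), 1, tolerance = 1e-12)

  # AICc undefined when n <= k + 1
  low_n <- compare_models(list(fake_fit("null", 3, -100, n = 4),
                               fake_fit("sex", 6, -95, n = 4)))
  expect_true(all(is.na(low_n$AICc)))
})

test_that("region abundance scales density and its interval by area", {
  fit <- fake_fit("null", 3, -100)
  fit$convergence <- TRUE
  fit$derived <- list(D = 1, lcl_D = 0.93, ucl_D = 1.68)
  expect_equal(region_abundance(fit, 100)$N, 100)
  ab <- region_abundance(fit, 160)
  expect_equal(c(ab$lcl, ab$ucl), c(148.8, 268.8))
  expect_equal(region_abundance(fit, 0)$N, 0)
  expect_error(region_abundance(fit, -1), "non-negative")
})

test_that("circular 95% radius follows the chi-square quantile identity", {
  expect_equal(circular_r95(1)$r95_m, sqrt(qchisq(0.95, 2)), tolerance = 1e-12)
  a1 <- circular_r95(700)$area_km2
  a2 <- circular_r95(1400)$area_km2
  expect_equal(a2 / a1, 4, tolerance = 1e-12)
  # sigma ~ 1475 m corresponds to roughly a 41 km^2 circular home range
  expect_equal(circular_r95(1475)$area_km2, 41, tolerance = 0.02)
  ci <- circular_r95(1475, sigma_ci = c(1300, 1650))
  expect_lt(ci$area_ci_km2[1], 41)
  expect_gt(ci$area_ci_km2[2], 41)
  expect_error(circular_r95(-2), "positive")
})

test_that("precision is CI width over the estimate, reported as a percent", {
  expect_equal(precision(1.72, 1.54, 1.95)$percent, 24)
  expect_equal(precision(2.32, 2.30, 2.35)$percent, 2)
  expect_equal(precision(5, 5, 5)$percent, 0)
  expect_error(precision(0, -1, 1), "zero")
  expect_error(precision(1, 2, 3), "ci_low")
})
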