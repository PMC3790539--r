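test_that("single-cell closed form matches the Poisson-process likelihood", {
  cams <- data.frame(camera_id = "D1", x = 0, y = 0, grid_cell = "R01C01")
  mask <- manual_mask(data.frame(x = 300, y = 0), cell_area_km2 = 0.25)
  y <- array(0L, dim = c(1, 1, 1)); y[1, 1, 1] <- 1
  h <- manual_history(y, cams)
  spec <- secr_spec("null", "bernoulli", "poisson")

  D <- 2; g0 <- 0.3; sigma <- 500
  par <- c(log(D), qlogis(g0), log(sigma))
  p <- g0 * exp(-300^2 / (2 * sigma^2))
  a <- 0.25
  expect_equal(-secr_nll(par, h, mask, spec),
               -D * a * p + log(D * a * p), tolerance = 1e-10)

  # the maximum over D sits at D a p = 1
  Dhat <- 1 / (a * p)
  nll_at <- secr_nll(c(log(Dhat), qlogis(g0), log(sigma)), h, mask, spec)
  for (f in c(0.8, 1.25)) {
    expect_gt(secr_nll(c(log(Dhat * f), qlogis(g0), log(sigma)), h, mask, spec),
              nll_at)
  }
})

test_that("vanishing g0 gives zero expected detections and impossible histories", {
  cams <- tiny_cameras(2, 1)
  mask <- manual_mask(expand.grid(x = c(500, 1500), y = c(500, 1500)), 1)
  y <- array(0L, dim = c(1, 2, 1)); y[1, 1, 1] <- 1
  h <- manual_history(y, cams)
  spec <- secr_spec("null", "bernoulli", "poisson")
  par <- c(log(1), qlogis(1e-11), log(600))
  parts <- secr_loglik_parts(par, h, mask, spec)
  expect_lt(parts$Lambda, 1e-6)
  expect_gt(secr_nll(par, h, mask, spec), 20)
})

test_that("conditional history probabilities sum to one (enumeration oracle)", {
  # 2 detectors x 2 occasions, 4-cell mask, Bernoulli with uneven effort
  cams <- data.frame(camera_id = c("D1", "D2"), x = c(0, 800), y = c(0, 0),
                     grid_cell = c("R01C01", "R01C02"))
  mask <- manual_mask(expand.grid(x = c(-200, 1000), y = c(-300, 300)), 0.36)
  eff <- matrix(c(1, 0.5, 0.75, 1), 2, 2, dimnames = list(cams$camera_id, NULL))
  spec <- secr_spec("null", "bernoulli", "poisson")
  par <- c(log(1.4), qlogis(0.22), log(450))

  hists <- enum_bernoulli_histories(2, 2)
  Ivals <- vapply(hists, function(y) {
    if (sum(y) == 0) return(NA_real_)
    h <- manual_history(y, cams, effort = eff)
    exp(secr_loglik_parts(par, h, mask, spec)$logI)
  }, numeric(1))
  h1 <- manual_history(hists[[2]], cams, effort = eff)
  Lam <- secr_loglik_parts(par, h1, mask, spec)$Lambda
  # sum over nonempty histories of I_omega equals Lambda...
  expect_equal(sum(Ivals, na.rm = TRUE), Lam, tolerance = 1e-10)
  # ... so conditional probabilities I/Lambda sum to exactly one
  expect_equal(sum(Ivals / Lam, na.rm = TRUE), 1, tolerance = 1e-10)

  # independent oracle: brute-force the likelihood of one history by
  # direct products over cells
  yobs <- hists[[7]]
  h7 <- manual_history(yobs, cams, effort = eff)
  D <- exp(par[1]); g0 <- plogis(par[2]); sigma <- exp(par[3])
  direct <- 0
  for (m in seq_len(nrow(mask))) {
    pr <- 1
    for (k in 1:2) {
      d2 <- (mask$x[m] - cams$x[k])^2 + (mask$y[m] - cams$y[k])^2
      g <- g0 * exp(-d2 / (2 * sigma^2))
      for (s in 1:2) {
        pks <- 1 - (1 - g)^eff[k, s]
        pr <- pr * ifelse(yobs[1, k, s] == 1, pks, 1 - pks)
      }
    }
    direct <- direct + 0.36 * D * pr
  }
  expect_equal(exp(secr_loglik_parts(par, h7, mask, spec)$logI), direct,
               tolerance = 1e-10)
})

test_that("Poisson-count history probabilities sum to one over truncated support", {
  cams <- data.frame(camera_id = c("D1", "D2"), x = c(0, 800), y = c(0, 0),
                     grid_cell = c("R01C01", "R01C02"))
  mask <- manual_mask(expand.grid(x = c(-200, 1000), y = c(-300, 300)), 0.36)
  eff <- matrix(c(1, 0.5, 0.75, 1), 2, 2, dimnames = list(cams$camera_id, NULL))
  spec <- secr_spec("null", "poisson_count", "poisson")
  par <- c(log(1.4), log(0.4), log(450))

  cap <- 8
  grids <- expand.grid(rep(list(0:cap), 4))
  tot <- 0
  h1 <- manual_history(array(c(1L, 0L, 0L, 0L), dim = c(1, 2, 2)), cams,
                       effort = eff)
  Lam <- secr_loglik_parts(par, h1, mask, spec)$Lambda
  for (r in seq_len(nrow(grids))) {
    y <- array(as.integer(grids[r, ]), dim = c(1, 2, 2))
    if (sum(y) == 0) next
    h <- manual_history(y, cams, effort = eff)
    tot <- tot + exp(secr_loglik_parts(par, h, mask, spec)$logI)
  }
  expect_equal(tot / Lam, 1, tolerance = 1e-8)
})

test_that("likelihood is invariant to mask refinement and cell relabeling", {
  cams <- tiny_cameras(3, 2, spacing = 800)
  set.seed(5)
  ms <- model_true_history(5, D = 2, g0 = 0.2, sigma = 500, nx = 3, ny = 2,
                           spacing = 800, S = 5, buffer = 1500)
  spec <- secr_spec("null", "bernoulli", "poisson")
  par <- c(log(2), qlogis(0.2), log(500))

  # buffer deep enough (6 sigma) that the integrand vanishes at the mask
  # edge; the residual quadrature error is then dominated by lattice
  # resolution and must be far below reporting precision
  m1 <- build_mask(ms$cameras, 3000, 150)
  m2 <- build_mask(ms$cameras, 3000, 75)
  l1 <- secr_nll(par, ms$history, m1, spec)
  l2 <- secr_nll(par, ms$history, m2, spec)
  expect_lt(abs(l1 - l2), 1e-6)

  # duplicating every cell at half the cell area changes nothing
  m_dup <- manual_mask(rbind(as.data.frame(m1), as.data.frame(m1)),
                       attr(m1, "cell_area_km2") / 2)
  expect_equal(secr_nll(par, ms$history, m_dup, spec), l1, tolerance = 1e-8)
})

test_that("finite-mixture parameterization collapses to its nested models", {
  set.seed(7)
  ms <- model_true_history(7, D = 2, g0 = 0.15, sigma = 600, nx = 4, ny = 3,
                           spacing = 900, S = 8, buffer = 1800)
  h <- ms$history
  h$covariates$sex <- rep(c("female", "male"), length.out = h$n)
  mask <- build_mask(ms$cameras, 1800, 450)

  base <- c(log(1.2), qlogis(0.15), log(600))
  par_sex <- c(log(1.2), log(0.8), qlogis(0.15), qlogis(0.15), log(600), log(600))
  par_het <- c(par_sex, 0.9, -0.4, qlogis(1 - 1e-12))

  sp_null <- secr_spec("null", "bernoulli", "poisson")
  sp_sex <- secr_spec("sex", "bernoulli", "poisson")
  sp_het <- secr_spec("sexhet", "bernoulli", "poisson")

  # pmix pinned at 1 removes the latent class entirely
  expect_equal(secr_nll(par_het, h, mask, sp_het),
               secr_nll(par_sex, h, mask, sp_sex), tolerance = 1e-8)
  # with sexes unobserved and equal classes, pmix 1 reproduces the null
  # likelihood exactly (observed sexes add the marked-process term)
  h_unk <- h
  h_unk$covariates$sex <- "unknown"
  par_het0 <- c(base[1] - log(2), base[1] - log(2), base[2], base[2],
                base[3], base[3], 0.5, 0.5, qlogis(1 - 1e-12))
  expect_equal(secr_nll(par_het0, h_unk, mask, sp_het),
               secr_nll(c(base[1], base[2], base[3]), h_unk, mask, sp_null),
               tolerance = 1e-8)
  # observed sexes shift the likelihood by exactly n log 2 in this
  # balanced equal-parameter case
  expect_equal(secr_nll(par_het0, h, mask, sp_het),
               secr_nll(base, h, mask, sp_null) + h$n * log(2),
               tolerance = 1e-6)
})

test_that("binomial n-distribution matches Poisson conditioning structure", {
  set.seed(9)
  ms <- model_true_history(9, D = 2, g0 = 0.2, sigma = 500, nx = 4, ny = 3,
                           spacing = 800, S = 6, buffer = 1500)
  mask <- build_mask(ms$cameras, 1500, 400)
  par <- c(log(2), qlogis(0.2), log(500))
  sp_p <- secr_spec("null", "bernoulli", "poisson")
  sp_b <- secr_spec("null", "bernoulli", "binomial")
  lp <- secr_nll(par, ms$history, mask, sp_p)
  lb <- secr_nll(par, ms$history, mask, sp_b)
  expect_true(is.finite(lp) && is.finite(lb))
  # law of rare events: with detection rare and the mask population
  # N = D*A large, binomial conditioning approaches the Poisson n-term
  # (the finite-N correction is n(n-1)/2N)
  gaps <- vapply(c(2, 20, 200), function(D) {
    pr <- c(log(D), -6, log(500))
    abs(secr_nll(pr, ms$history, mask, sp_p) -
          secr_nll(pr, ms$history, mask, sp_b))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  # residual is the O(n^2/N, n p) finite-population correction
  expect_lt(gaps[3], 0.2)
  expect_gt(gaps[1], 1)
})
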