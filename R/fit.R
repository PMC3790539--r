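default_start <- function(history, mask, spec) {
  A <- attr(mask, "area_km2")
  lv <- known_levels(spec)
  G <- length(lv)
  sig0 <- tryCatch(rpsv(history), error = function(e) attr(mask, "buffer_m") / 4)
  if (G == 1) {
    logD <- log(max(history$n, 1) / A)
  } else {
    covv <- if (spec$known == "sex") history$covariates$sex else history$covariates$solitary
    ng <- pmax(vapply(lv, function(l) sum(covv == l), numeric(1)), 0.5)
    ng <- ng * history$n / sum(ng)
    logD <- log(pmax(ng, 0.5) / A)
  }
  b0 <- if (spec$encounter == "bernoulli") rep(qlogis(0.05), G) else rep(log(0.05), G)
  par <- c(logD, b0, rep(log(sig0), G))
  # het start: a well-separated low-detection latent class; restart
  # jitters explore around it
  if (spec$latent == 2L) par <- c(par, -1.5, 0, qlogis(0.7))
  names(par) <- secr_par_names(spec)
  par
}

## deterministic jitter patterns for optimizer restarts
restart_jitters <- function(npar) {
  list(rep(0, npar),
       rep_len(c(0.4, -0.4), npar),
       rep_len(c(-0.3, 0.5, 0.2), npar))
}

#' Fit a SECR model by maximum likelihood
#'
#' Quasi-Newton maximization of the full SECR likelihood on the link scale
#' (`log D`, `logit g0` or `log lambda0`, `log sigma`, mixture offsets,
#' `logit pmix`), with deterministic jittered restarts. Standard errors
#' come from the inverse numerical Hessian; 95% intervals are Wald on the
#' link scale, back-transformed (log-normal style asymmetric interval for
#' the derived total density).
#'
#' @param history capture_history.
#' @param mask habitat_mask.
#' @param spec secr_spec.
#' @param start optional link-scale start vector.
#' @param coverage optional per-detector coverage covariate in `(0, 1]`.
#' @param n_restarts number of deterministic jittered starts screened
#'   before the polishing pass (1-3; more restarts are more robust to
#'   mixture-likelihood local optima).
#' @return object of class `secr_fit` with elements `par`, `vcov`,
#'   `estimates` (per-parameter table), `derived` (total density with SE
#'   and CI, per-class densities, sex/class ratio), `logLik`, `k`, `n`,
#'   `AIC`, `AICc`, `convergence`.
#' @export
fit_secr <- function(history, mask, spec, start = NULL, coverage = NULL,
                     n_restarts = 3) {
  if (history$n < 1) stop("capture history has no individuals")
  obj <- function(p) secr_nll(p, history, mask, spec, coverage)
  base <- if (is.null(start)) default_start(history, mask, spec) else start
  # box constraints on the link scale keep sparse-data fits from
  # diverging (density 1e-4..1000 /km^2, sigma 50 m..50 km)
  lv <- known_levels(spec)
  G <- length(lv)
  lower <- c(rep(log(1e-4), G), rep(-15, G), rep(log(50), G))
  upper <- c(rep(log(1000), G), rep(if (spec$encounter == "bernoulli") 8 else 3, G),
             rep(log(5e4), G))
  if (spec$latent == 2L) {
    lower <- c(lower, -8, -4, -6); upper <- c(upper, 8, 4, 6)
  }
  # screening pass from each start at loose tolerance, then a polishing
  # pass from the best screen
  best <- NULL
  for (jit in restart_jitters(length(base))[seq_len(max(1, min(n_restarts, 3)))]) {
    st <- base + jit
    fit <- tryCatch(nlminb(st, obj, lower = lower, upper = upper,
                           control = list(rel.tol = 1e-7,
                                          eval.max = 350,
                                          iter.max = 150)),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) next
    if (is.null(best) || fit$objective < best$objective - 1e-9) best <- fit
  }
  if (!is.null(best)) {
    polish <- tryCatch(nlminb(best$par, obj, lower = lower, upper = upper,
                              control = list(rel.tol = 1e-9,
                                             eval.max = 600,
                                             iter.max = 250)),
                       error = function(e) NULL)
    if (!is.null(polish) && is.finite(polish$objective) &&
        polish$objective <= best$objective) best <- polish
  }
  if (is.null(best)) {
    return(structure(list(spec = spec, convergence = FALSE, n = history$n),
                     class = "secr_fit"))
  }
  par <- best$par
  names(par) <- secr_par_names(spec)
  at_bound <- any(par <= lower + 1e-6) || any(par >= upper - 1e-6)
  hess <- tryCatch(optimHess(par, obj), error = function(e) NULL)
  vc <- if (!is.null(hess)) tryCatch(solve(hess), error = function(e) NULL) else NULL
  se <- if (!is.null(vc)) sqrt(pmax(diag(vc), 0)) else rep(NA_real_, length(par))
  z <- qnorm(0.975)
  back <- function(nm, v) {
    if (startsWith(nm, "logD") || startsWith(nm, "logsigma")) return(exp(v))
    if (nm == "b0" || startsWith(nm, "b0.")) {
      return(if (spec$encounter == "bernoulli") plogis(v) else exp(v))
    }
    if (nm == "logitpmix") return(plogis(v))
    v
  }
  est <- data.frame(parameter = names(par), link = unname(par),
                    se_link = unname(se),
                    estimate = NA_real_, lcl = NA_real_, ucl = NA_real_,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(est))) {
    nm <- est$parameter[r]
    est$estimate[r] <- back(nm, est$link[r])
    est$lcl[r] <- back(nm, est$link[r] - z * est$se_link[r])
    est$ucl[r] <- back(nm, est$link[r] + z * est$se_link[r])
  }
  # derived total density with delta-method SE and lognormal CI
  lv <- known_levels(spec)
  G <- length(lv)
  Dg <- exp(par[seq_len(G)])
  D <- sum(Dg)
  grad <- c(Dg, rep(0, length(par) - G))
  varD <- if (!is.null(vc)) drop(t(grad) %*% vc %*% grad) else NA_real_
  seD <- sqrt(max(varD, 0))
  if (is.finite(seD) && seD > 0) {
    cv <- seD / D
    cfac <- exp(z * sqrt(log(1 + cv^2)))
    ciD <- c(D / cfac, D * cfac)
  } else {
    ciD <- c(NA_real_, NA_real_)
  }
  derived <- list(D = unname(D), se_D = unname(seD),
                  lcl_D = unname(ciD[1]), ucl_D = unname(ciD[2]),
                  D_by_class = stats::setNames(unname(Dg), lv))
  if (G == 2 && spec$known == "sex") {
    derived$male_to_female_ratio <- unname(Dg["logD.male"] / Dg["logD.female"])
  }
  ll <- -best$objective
  k <- length(par)
  n <- history$n
  aic <- 2 * k - 2 * ll
  aicc <- if (n > k + 1) aic + 2 * k * (k + 1) / (n - k - 1) else NA_real_
  structure(list(spec = spec, par = par, vcov = vc, estimates = est,
                 derived = derived, logLik = ll, k = k, n = n,
                 AIC = aic, AICc = aicc,
                 convergence = best$convergence == 0 && !at_bound,
                 at_bound = at_bound,
                 mask_area_km2 = attr(mask, "area_km2"),
                 buffer_m = attr(mask, "buffer_m")),
            class = "secr_fit")
}

#' @export
print.secr_fit <- function(x, ...) {
  cat("secr_fit:", x$spec$variant, "(", x$spec$encounter, ", n ~",
      x$spec$n_distribution, ")\n")
  if (!isTRUE(x$convergence)) cat("  ** did not converge **\n")
  if (!is.null(x$derived)) {
    cat(sprintf("  D = %.3f /km^2 (%.3f-%.3f), logLik = %.1f, k = %d, AICc = %.1f\n",
                x$derived$D, x$derived$lcl_D, x$derived$ucl_D,
                x$logLik, x$k, x$AICc))
  }
  invisible(x)
}

#' AICc model comparison table
#'
#' @param fits list of `secr_fit` objects fitted to the same data.
#' @return data.frame of class `secr_modeltable` with columns `model`,
#'   `npar`, `logLik`, `AIC`, `AICc`, `dAICc`, `AICwt` (weights from
#'   `exp(-dAICc/2)` normalized over models with defined AICc).
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "secr_fit")) fits <- list(fits)
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1) stop("fits must be on identical data (same n)")
  tab <- data.frame(
    model = vapply(fits, function(f) f$spec$variant, character(1)),
    npar = vapply(fits, function(f) f$k, numeric(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    AIC = vapply(fits, function(f) f$AIC, numeric(1)),
    AICc = vapply(fits, function(f) f$AICc, numeric(1)),
    stringsAsFactors = FALSE)
  ok <- is.finite(tab$AICc)
  tab$dAICc <- NA_real_
  tab$AICwt <- NA_real_
  if (any(ok)) {
    tab$dAICc[ok] <- tab$AICc[ok] - min(tab$AICc[ok])
    w <- exp(-tab$dAICc[ok] / 2)
    tab$AICwt[ok] <- w / sum(w)
  }
  tab <- tab[order(tab$dAICc), ]
  rownames(tab) <- NULL
  class(tab) <- c("secr_modeltable", "data.frame")
  tab
}

#' Expected abundance over a region
#'
#' `N = D * area`, with the interval obtained by scaling the density CI.
#'
#' @param fit converged secr_fit.
#' @param region_area_km2 region area in km^2.
#' @return list with `N`, `lcl`, `ucl`.
#' @export
region_abundance <- function(fit, region_area_km2) {
  if (region_area_km2 < 0) stop("region area must be non-negative")
  if (!isTRUE(fit$convergence)) stop("fit did not converge")
  list(N = fit$derived$D * region_area_km2,
       lcl = fit$derived$lcl_D * region_area_km2,
       ucl = fit$derived$ucl_D * region_area_km2)
}

#' Circular 95% home-range radius and area
#'
#' For a circular bivariate normal activity distribution the radius
#' containing 95% of activity is `sigma * sqrt(qchisq(0.95, 2))`; the
#' associated area is `pi r^2` in km^2.
#'
#' @param sigma_m half-normal spatial scale in meters.
#' @param sigma_ci optional length-2 CI for sigma, transformed through the
#'   same formulas.
#' @return list with `r95_m`, `area_km2` and (if requested) their CIs.
#' @export
circular_r95 <- function(sigma_m, sigma_ci = NULL) {
  if (sigma_m <= 0) stop("sigma must be positive")
  mult <- sqrt(qchisq(0.95, df = 2))
  r <- sigma_m * mult
  out <- list(r95_m = r, area_km2 = m2_to_km2(pi * r^2))
  if (!is.null(sigma_ci)) {
    rs <- sort(sigma_ci) * mult
    out$r95_ci_m <- rs
    out$area_ci_km2 <- m2_to_km2(pi * rs^2)
  }
  out
}

#' Relative precision of an estimate
#'
#' Entire width of the 95% confidence interval divided by the estimate.
#'
#' @param estimate point estimate (nonzero).
#' @param ci_low,ci_high interval endpoints with
#'   `ci_low <= estimate <= ci_high`.
#' @return list with `fraction` and `percent` (rounded).
#' @export
precision <- function(estimate, ci_low, ci_high) {
  if (estimate == 0) stop("precision undefined for a zero estimate")
  if (!(ci_low <= estimate && estimate <= ci_high)) {
    stop("require ci_low <= estimate <= ci_high")
  }
  frac <- (ci_high - ci_low) / estimate
  list(fraction = frac, percent = round(100 * frac))
}
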