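## Two-innate-rates model (TIRM): N individuals of which a proportion q are
## "easy" (captured at rate alpha * lambda) and the rest "hard" (rate
## lambda). Observed capture counts per identified individual are modeled
## as a two-component Poisson mixture with the N - n zero-count individuals
## unobserved; N is profiled over a grid with the rate parameters maximized
## at each N.

tirm_loglik <- function(N, counts_tab, theta) {
  # theta = c(logit q, log lambda, log(alpha - 1))
  q <- invlogit(theta[1]); lam <- exp(theta[2]); alpha <- 1 + exp(theta[3])
  n <- sum(counts_tab$m)
  cts <- counts_tab$count; m <- counts_tab$m
  p0 <- q * exp(-alpha * lam) + (1 - q) * exp(-lam)
  li <- q * dpois(cts, alpha * lam) + (1 - q) * dpois(cts, lam)
  if (any(li <= 0) || p0 >= 1) return(-Inf)
  lgamma(N + 1) - lgamma(N - n + 1) + (N - n) * log(p0) + sum(m * log(li))
}

tirm_profile_at_N <- function(N, counts_tab, theta0) {
  opt <- tryCatch(
    nlminb(theta0, function(th) -tirm_loglik(N, counts_tab, th),
           control = list(rel.tol = 1e-9)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective)) {
    return(list(loglik = -Inf, theta = theta0))
  }
  list(loglik = -opt$objective, theta = opt$par)
}

tirm_search <- function(counts, max_N) {
  tab <- as.data.frame(table(counts), stringsAsFactors = FALSE)
  counts_tab <- list(count = as.numeric(tab$counts), m = as.numeric(tab$Freq))
  n <- length(counts)
  theta0 <- c(0, log(max(mean(counts) / 2, 0.1)), log(max(mean(counts), 1.5)))
  Ns <- unique(round(seq(n, max_N, length.out = min(max_N - n + 1, 40))))
  prof <- rep(-Inf, length(Ns))
  th <- theta0
  for (j in seq_along(Ns)) {
    r <- tirm_profile_at_N(Ns[j], counts_tab, th)
    prof[j] <- r$loglik; th <- r$theta
  }
  jbest <- which.max(prof)
  # refine to step 1 around the coarse optimum
  lo <- Ns[max(jbest - 1, 1)]; hi <- Ns[min(jbest + 1, length(Ns))]
  Nf <- lo:hi
  proff <- rep(-Inf, length(Nf))
  th <- theta0
  for (j in seq_along(Nf)) {
    r <- tirm_profile_at_N(Nf[j], counts_tab, th)
    proff[j] <- r$loglik; th <- r$theta
  }
  jb <- which.max(proff)
  rfin <- tirm_profile_at_N(Nf[jb], counts_tab, theta0)
  list(N = Nf[jb], loglik = proff[jb], theta = rfin$theta)
}

#' Fit the two-innate-rates abundance model
#'
#' Maximum-likelihood abundance from per-individual capture counts under a
#' two-class capture-rate mixture, with a parametric-bootstrap percentile
#' confidence interval.
#'
#' @param counts integer vector of capture events per identified individual
#'   (all `>= 1`).
#' @param max_N upper bound of the profile search (default `20 * n`).
#' @param n_boot parametric bootstrap replicates for the CI.
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level.
#' @return list of class `tirm_fit`: `N_hat`, `ci`, `q`, `lambda`, `alpha`,
#'   `loglik`, `boundary` (TRUE when the MLE sits at `max_N`,
#'   unidentifiable), `single_rate` (TRUE when the degenerate equal-counts
#'   fallback was used), `n`, `T` (total events).
#' @export
fit_tirm <- function(counts, max_N = NULL, n_boot = 200, seed = 17,
                     conf = 0.95) {
  counts <- as.numeric(counts)
  if (length(counts) < 2) stop("need at least two identified individuals")
  if (any(counts < 1)) stop("capture counts must be >= 1")
  n <- length(counts)
  if (is.null(max_N)) max_N <- 20L * n
  single_rate <- length(unique(counts)) == 1
  if (single_rate) {
    warning("all capture counts equal; falling back to a single-rate model")
  }
  if (all(counts == 1)) {
    return(structure(list(N_hat = max_N, ci = c(NA_real_, NA_real_),
                          q = NA_real_, lambda = NA_real_, alpha = NA_real_,
                          loglik = NA_real_, boundary = TRUE,
                          single_rate = TRUE, n = n, T = sum(counts)),
                     class = "tirm_fit"))
  }
  fit <- tirm_search(counts, max_N)
  q <- invlogit(fit$theta[1]); lam <- exp(fit$theta[2])
  alpha <- 1 + exp(fit$theta[3])
  boundary <- fit$N >= max_N
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0 && !boundary) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    boots <- numeric(n_boot)
    # bootstrap populations have size N_hat, so the profile search can be
    # bounded well below the user's max_N without affecting the quantiles
    boot_max <- min(max_N, max(3 * fit$N, fit$N + 20))
    for (b in seq_len(n_boot)) {
      cls <- rbinom(fit$N, 1, q)
      cb <- rpois(fit$N, ifelse(cls == 1, alpha * lam, lam))
      cb <- cb[cb > 0]
      boots[b] <- if (length(cb) < 2 || length(unique(cb)) == 1) {
        length(cb)
      } else {
        tirm_search(cb, boot_max)$N
      }
    }
    ci <- unname(stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
  }
  structure(list(N_hat = fit$N, ci = ci, q = q, lambda = lam, alpha = alpha,
                 loglik = fit$loglik, boundary = boundary,
                 single_rate = single_rate, n = n, T = sum(counts)),
            class = "tirm_fit")
}

#' @export
print.tirm_fit <- function(x, ...) {
  cat(sprintf("tirm_fit: N = %d (%.0f-%.0f), n = %d, T = %d%s\n",
              x$N_hat, x$ci[1], x$ci[2], x$n, x$T,
              if (x$boundary) " [boundary: unidentifiable]" else ""))
  invisible(x)
}

#' Naive density: abundance over sampled area
#'
#' @param abundance number of individuals.
#' @param area_km2 actual sampled area in km^2 (positive).
#' @return density in individuals per km^2, rounded to 2 decimals.
#' @export
naive_density <- function(abundance, area_km2) {
  if (area_km2 <= 0) stop("area must be positive")
  round(abundance / area_km2, 2)
}

#' Simulate capture counts from the two-rates model
#'
#' @param N true population size.
#' @param q proportion of easy individuals.
#' @param lambda base capture rate.
#' @param alpha rate multiplier for easy individuals (`>= 1`).
#' @return integer vector of nonzero capture counts (observed individuals).
#' @export
simulate_tirm_counts <- function(N, q, lambda, alpha) {
  cls <- rbinom(N, 1, q)
  cts <- rpois(N, ifelse(cls == 1, alpha * lambda, lambda))
  cts[cts > 0]
}
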