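#' Specify a SECR model variant
#'
#' The five variants parameterize heterogeneity in density and half-normal
#' detection:
#' \describe{
#'   \item{null}{one density, one `(g0, sigma)`; 3 parameters.}
#'   \item{sex}{density, `g0` and `sigma` split by known sex; 6 parameters.}
#'   \item{sexhet}{sex split plus a 2-class latent finite mixture on
#'     `(g0, sigma)` within sexes, sharing link-scale offsets and one mixing
#'     proportion; 9 parameters.}
#'   \item{group / grouphet}{as sex/sexhet but the known class is
#'     solitary-vs-group-living.}
#' }
#'
#' @param variant model variant.
#' @param encounter `"bernoulli"` (binary proximity detector per occasion,
#'   effort as exponent) or `"poisson_count"` (counts, effort as rate
#'   multiplier).
#' @param n_distribution distribution of the number of activity centers in
#'   the mask: `"poisson"` (full Poisson-process likelihood) or
#'   `"binomial"` (fixed `N = D * A`).
#' @return object of class `secr_spec`.
#' @export
secr_spec <- function(variant = c("null", "sex", "sexhet", "group", "grouphet"),
                      encounter = c("bernoulli", "poisson_count"),
                      n_distribution = c("poisson", "binomial")) {
  variant <- match.arg(variant)
  encounter <- match.arg(encounter)
  n_distribution <- match.arg(n_distribution)
  known <- switch(variant, null = NULL,
                  sex = "sex", sexhet = "sex",
                  group = "solitary", grouphet = "solitary")
  latent <- if (variant %in% c("sexhet", "grouphet")) 2L else 1L
  npar <- c(null = 3L, sex = 6L, group = 6L, sexhet = 9L, grouphet = 9L)[[variant]]
  structure(list(variant = variant, encounter = encounter,
                 n_distribution = n_distribution, known = known,
                 latent = latent, npar = npar),
            class = "secr_spec")
}

#' @export
print.secr_spec <- function(x, ...) {
  cat("secr_spec:", x$variant, "|", x$encounter, "| n ~", x$n_distribution,
    "|", x$npar, "parameters\n")
  invisible(x)
}

known_levels <- function(spec) {
  switch(spec$known %||% "none",
         sex = c("female", "male"),
         solitary = c("group", "solitary"),
         none = "all")
}

#' Parameter vector layout for a model spec
#'
#' @param spec secr_spec.
#' @return character vector of link-scale parameter names, in order.
#' @export
secr_par_names <- function(spec) {
  lv <- known_levels(spec)
  nm <- c(paste0("logD.", lv), paste0("b0.", lv), paste0("logsigma.", lv))
  if (length(lv) == 1) nm <- c("logD", "b0", "logsigma")
  if (spec$latent == 2L) nm <- c(nm, "delta.b0", "delta.logsigma", "logitpmix")
  nm
}

# Expand a link-scale parameter vector into per-class natural parameters.
# Classes are the cross of known levels and latent classes; psi_c = D_g *
# pi_l is the class intensity entering the Poisson-process likelihood.
secr_classes <- function(par, spec) {
  lv <- known_levels(spec)
  G <- length(lv)
  logD <- par[seq_len(G)]
  b0 <- par[G + seq_len(G)]
  ls <- par[2 * G + seq_len(G)]
  if (spec$latent == 2L) {
    db <- par[3 * G + 1]; dls <- par[3 * G + 2]
    pmix <- invlogit(par[3 * G + 3])
    pis <- c(pmix, 1 - pmix)
  } else {
    db <- 0; dls <- 0; pis <- 1
  }
  cls <- expand.grid(l = seq_len(spec$latent), g = seq_len(G))
  D <- exp(logD)[cls$g]
  psi <- D * pis[cls$l]
  b0c <- b0[cls$g] + db * (cls$l == 2L)
  sigc <- exp(ls[cls$g] + dls * (cls$l == 2L))
  g0c <- if (spec$encounter == "bernoulli") invlogit(b0c) else exp(b0c)
  list(known = lv[cls$g], psi = psi, g0 = g0c, sigma = sigc,
       D_by_known = exp(logD), levels = lv)
}

# Flatten a capture history into the sparse form the C++ kernel expects.
flatten_history <- function(history, spec) {
  y <- history$y
  if (spec$encounter == "bernoulli") y <- pmin(y, 1L)
  n <- history$n
  idx <- which(y > 0, arr.ind = TRUE)
  ord <- order(idx[, 1])
  idx <- idx[ord, , drop = FALSE]
  start <- integer(n + 1L)
  start[1] <- 0L
  tab <- tabulate(idx[, 1], nbins = n)
  start <- c(0L, cumsum(tab))
  e <- history$effort
  list(start = as.integer(start),
       dk = as.integer(idx[, 2] - 1L),
       dy = as.numeric(y[idx]),
       de = as.numeric(e[cbind(idx[, 2], idx[, 3])]))
}

# Known-class weight matrix: 1 where the class is admissible for the
# individual (unknown covariate values marginalize over all classes).
class_weights <- function(history, spec) {
  cls_known <- secr_classes(rep(0, spec$npar), spec)$known
  n <- history$n
  C <- length(cls_known)
  W <- matrix(1L, n, C)
  if (is.null(spec$known)) return(W)
  covv <- if (spec$known == "sex") {
    history$covariates$sex
  } else {
    if (is.null(history$covariates$solitary)) {
      stop("solitary/group covariate missing; run attach_solitary_covariate() first")
    }
    history$covariates$solitary
  }
  lv <- known_levels(spec)
  for (i in seq_len(n)) {
    if (covv[i] %in% lv) W[i, ] <- as.integer(cls_known == covv[i])
  }
  W
}

detector_offsets <- function(history, coverage = NULL) {
  K <- nrow(history$detectors)
  if (is.null(coverage)) return(rep(0, K))
  if (length(coverage) != K) stop("coverage must have one value per detector")
  if (any(coverage <= 0 | coverage > 1)) stop("coverage values must be in (0, 1]")
  log(coverage)
}

#' Likelihood building blocks
#'
#' Computes the expected number of detected individuals `Lambda` and the
#' per-individual log-integrals `log I_i` of the SECR Poisson-process
#' likelihood at a link-scale parameter vector. Exposed for oracle testing;
#' [secr_nll()] assembles them into the negative log-likelihood.
#'
#' @param par link-scale parameter vector (see [secr_par_names()]).
#' @param history capture_history.
#' @param mask habitat_mask.
#' @param spec secr_spec.
#' @param coverage optional per-detector coverage in `(0, 1]`, entering as
#'   an additive offset `log(coverage)` on the detection-intercept link
#'   scale.
#' @return list with `Lambda`, `logI` (length `n`), and `classes`.
#' @export
secr_loglik_parts <- function(par, history, mask, spec, coverage = NULL) {
  cls <- secr_classes(par, spec)
  fl <- flatten_history(history, spec)
  W <- class_weights(history, spec)
  parts <- secr_nll_parts_cpp(
    as.matrix(mask[, c("x", "y")]),
    as.matrix(history$detectors[, c("x", "y")]),
    attr(mask, "cell_area_km2"),
    rowSums(history$effort),
    if (spec$encounter == "bernoulli") 0L else 1L,
    cls$psi, cls$g0, cls$sigma,
    detector_offsets(history, coverage),
    W, fl$start, fl$dk, fl$dy, fl$de)
  parts$classes <- cls
  parts
}

#' SECR negative log-likelihood
#'
#' Full likelihood of a capture history under the half-normal SECR model:
#' for the Poisson n-distribution,
#' `-logL = Lambda - sum_i log I_i`; the binomial variant conditions the
#' number of activity centers in the mask on `N = D * A`.
#'
#' @inheritParams secr_loglik_parts
#' @return negative log-likelihood (scalar); non-finite parameter points
#'   return `Inf`.
#' @export
secr_nll <- function(par, history, mask, spec, coverage = NULL) {
  if (any(!is.finite(par))) return(Inf)
  parts <- try(secr_loglik_parts(par, history, mask, spec, coverage),
               silent = TRUE)
  if (inherits(parts, "try-error")) return(Inf)
  Lam <- parts$Lambda
  logI <- parts$logI
  n <- history$n
  if (!is.finite(Lam) || any(!is.finite(logI))) return(Inf)
  if (spec$n_distribution == "poisson") {
    nll <- Lam - sum(logI)
  } else {
    A <- attr(mask, "area_km2")
    Ntot <- sum(parts$classes$D_by_known) * A
    if (Ntot <= n) return(Inf)
    p <- Lam / Ntot
    if (p <= 0 || p >= 1) return(Inf)
    nll <- -(lgamma(Ntot + 1) - lgamma(Ntot - n + 1) +
               (Ntot - n) * log(1 - p) + n * log(p) +
               sum(logI) - n * log(Lam))
  }
  if (!is.finite(nll)) Inf else nll
}
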