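#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement from the 2x2 cross-tabulation:
#' `kappa = (po - pe) / (1 - pe)` with `pe` from the marginal products.
#'
#' @param a,b equal-length binary (or two-level) judgment vectors.
#' @return list of class `kappa_result`: `kappa`, `po`, `pe`, `n`.
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b) || length(a) < 1) {
    stop("judgment vectors must have equal positive length")
  }
  lev <- sort(unique(c(a, b)))
  if (length(lev) > 2) stop("binary judgments expected")
  fa <- factor(a, levels = lev); fb <- factor(b, levels = lev)
  tab <- table(fa, fb)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - pe < .Machine$double.eps) {
    if (po == 1) {
      return(structure(list(kappa = 1, po = po, pe = pe, n = n),
                       class = "kappa_result"))
    }
    stop("chance agreement is 1 but observed agreement is not; kappa undefined")
  }
  structure(list(kappa = (po - pe) / (1 - pe), po = po, pe = pe, n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (po = %.3f, pe = %.3f, n = %d)\n",
              x$kappa, x$po, x$pe, x$n))
  invisible(x)
}

## Exact distribution of T+ over the 2^n equally likely sign assignments,
## by convolution over doubled mid-ranks (mid-ranks are multiples of 1/2,
## so doubling keeps the support integral). Equivalent to full
## enumeration.
wilcoxon_exact_dist <- function(ranks2) {
  maxs <- sum(ranks2)
  f <- numeric(maxs + 1)
  f[1] <- 1
  for (r in ranks2) {
    g <- f
    idx <- seq_len(maxs + 1 - r)
    g[idx + r] <- g[idx + r] + f[idx]
    f <- g
  }
  f / sum(f)
}

#' Exact Wilcoxon signed-rank test for matched pairs
#'
#' Zero differences are dropped (counted as ties), tied magnitudes get
#' mid-ranks, and `T+` is the sum of positive ranks. For `n <= exact_max`
#' the two-sided p-value is exact over all `2^n` sign assignments
#' (computed by convolution), doubling the smaller tail and capping at 1;
#' larger samples use the normal approximation with tie correction.
#'
#' @param x paired differences, or first member of each pair when `y`
#'   given.
#' @param y optional second member; differences are `x - y`.
#' @param exact_max maximum n for exact enumeration (default 25).
#' @return list of class `test_result`: `statistic` (T+), `n` (after
#'   dropping zeros), `p`, `exact`, `n_zeros` dropped.
#' @export
wilcoxon_signed_rank_exact <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) x else x - y
  n_zeros <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero")
  rk <- rank(abs(d))
  tplus <- sum(rk[d > 0])
  if (n <= exact_max) {
    ranks2 <- as.integer(round(2 * rk))
    f <- wilcoxon_exact_dist(ranks2)
    t2 <- as.integer(round(2 * tplus))
    p_ge <- sum(f[(t2 + 1):length(f)])
    p_le <- sum(f[1:(t2 + 1)])
    p <- min(1, 2 * min(p_ge, p_le))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (tplus - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(statistic = tplus, n = n, p = p, exact = exact,
                 n_zeros = n_zeros, test = "wilcoxon_signed_rank"),
            class = "test_result")
}

#' Friedman rank test with tie correction
#'
#' Within-block mid-ranks; the tie-corrected statistic
#' `chi2 = (k - 1) * sum_j (R_j - n(k+1)/2)^2 / (sum_ij r_ij^2 - n k (k+1)^2 / 4)`
#' is referred to the chi-squared upper tail with `k - 1` df.
#'
#' @param scores matrix, blocks (participants) in rows, treatments
#'   (e.g., species) in columns.
#' @return list of class `test_result`: `statistic`, `df`, `p`.
#' @export
friedman_test <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores); k <- ncol(scores)
  if (n < 2 || k < 2) stop("need at least 2 blocks and 2 treatments")
  r <- t(apply(scores, 1, rank))
  Rj <- colSums(r)
  denom <- sum(r^2) - n * k * (k + 1)^2 / 4
  if (denom <= 0) {
    return(structure(list(statistic = 0, df = k - 1, p = 1,
                          test = "friedman"), class = "test_result"))
  }
  stat <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / denom
  structure(list(statistic = stat, df = k - 1,
                 p = chi2_upper_tail(stat, k - 1), test = "friedman"),
            class = "test_result")
}

#' Upper-tail chi-squared probability
#'
#' @param x statistic (`>= 0`).
#' @param df degrees of freedom (`>= 1`).
#' @return `P(X >= x)` for `X ~ chi^2_df`; for `df = 2` this equals
#'   `exp(-x/2)`.
#' @export
chi2_upper_tail <- function(x, df) {
  if (any(x < 0) || df < 1) stop("require x >= 0 and df >= 1")
  pchisq(x, df = df, lower.tail = FALSE)
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.3f, %s = %s, p = %.4g%s\n",
              x$test, x$statistic,
              if (!is.null(x$df)) "df" else "n",
              if (!is.null(x$df)) paste(x$df, collapse = ",") else x$n,
              x$p,
              if (isTRUE(x$exact)) " (exact)" else ""))
  invisible(x)
}

#' Interobserver reliability summary
#'
#' Cohen's kappa of each participant against the gold standard, per
#' species, from a long-format judgment table.
#'
#' @param judgments data.frame with columns `participant_id`, `category`,
#'   `species`, `pair_id`, `judgment`, `gold`.
#' @return data.frame `participant_id`, `category`, `species`, `n_pairs`,
#'   `po`, `kappa`.
#' @export
reliability_summary <- function(judgments) {
  required <- c("participant_id", "category", "species", "pair_id",
                "judgment", "gold")
  missing_cols <- setdiff(required, names(judgments))
  if (length(missing_cols) > 0) {
    stop("judgments missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  keys <- unique(judgments[, c("participant_id", "category", "species")])
  out <- lapply(seq_len(nrow(keys)), function(r) {
    sub <- judgments[judgments$participant_id == keys$participant_id[r] &
                       judgments$species == keys$species[r], , drop = FALSE]
    kp <- cohens_kappa(sub$judgment, sub$gold)
    data.frame(keys[r, , drop = FALSE], n_pairs = kp$n, po = kp$po,
               kappa = kp$kappa, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
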