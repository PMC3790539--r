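#' Minimum convex polygon home range
#'
#' Convex hull of detection locations with shoelace area, reported in
#' km^2. Fewer than three unique non-collinear points give area 0 with a
#' degenerate flag.
#'
#' @param points matrix or data.frame of planar coordinates (meters).
#' @param subject_id optional label.
#' @return object of class `home_range`: `subject_id`, `hull` (vertex
#'   matrix, counter-clockwise), `area_km2`, `degenerate`, `n_points`.
#' @export
mcp_area <- function(points, subject_id = NA_character_) {
  pts <- unique(as.matrix(points)[, 1:2, drop = FALSE])
  colnames(pts) <- c("x", "y")
  degenerate <- FALSE
  if (nrow(pts) < 3) {
    hull <- pts
    area <- 0
    degenerate <- TRUE
  } else {
    h <- chull(pts[, 1], pts[, 2])
    hull <- pts[rev(h), , drop = FALSE]  # chull is clockwise; reverse
    xs <- hull[, 1]; ys <- hull[, 2]
    j <- c(seq_len(nrow(hull))[-1], 1L)
    area_m2 <- abs(sum(xs * ys[j] - xs[j] * ys)) / 2
    area <- m2_to_km2(area_m2)
    if (area == 0) degenerate <- TRUE
  }
  structure(list(subject_id = subject_id, hull = hull, area_km2 = area,
                 degenerate = degenerate, n_points = nrow(pts)),
            class = "home_range")
}

#' @export
print.home_range <- function(x, ...) {
  cat(sprintf("home_range %s: %.3f km^2 over %d points%s\n",
              x$subject_id, x$area_km2, x$n_points,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Approximate home ranges per subject from camera locations
#'
#' MCP over the camera locations at which each subject (individual or
#' group) was detected.
#'
#' @param records identified detection records.
#' @param cameras camera registry.
#' @param by `"individual"` or a membership data.frame
#'   (`individual_id`, `group_id`) to pool by group.
#' @return data.frame `subject_id`, `area_km2`, `n_cameras`,
#'   `n_observations`, `degenerate`.
#' @export
home_range_table <- function(records, cameras, by = "individual") {
  rec <- records[!is.na(records$individual_id) &
                   records$individual_id != "UNID", , drop = FALSE]
  if (is.data.frame(by)) {
    rec$subject <- by$group_id[match(rec$individual_id, by$individual_id)]
    rec <- rec[!is.na(rec$subject), , drop = FALSE]
  } else {
    rec$subject <- rec$individual_id
  }
  subs <- sort(unique(rec$subject))
  out <- lapply(subs, function(s) {
    rs <- rec[rec$subject == s, , drop = FALSE]
    cams <- cameras[match(unique(rs$camera_id), cameras$camera_id), , drop = FALSE]
    hr <- mcp_area(cams[, c("x", "y")], s)
    data.frame(subject_id = s, area_km2 = hr$area_km2,
               n_cameras = nrow(cams), n_observations = nrow(rs),
               degenerate = hr$degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' z-scored log observation counts
#'
#' Log-transform then center and scale to unit sample standard deviation
#' (n - 1 denominator).
#'
#' @param obs_counts positive observation counts.
#' @return numeric vector with mean 0 and sd 1.
#' @export
transform_predictors <- function(obs_counts) {
  if (any(obs_counts < 1)) stop("observation counts must be >= 1")
  lx <- log(obs_counts)
  s <- sd(lx)
  if (!is.finite(s) || s == 0) stop("constant observation counts: z-score undefined")
  (lx - mean(lx)) / s
}

#' Sex effect on home-range size, general linear model
#'
#' OLS of log approximate home range on sex, z-scored log observation
#' count and their interaction; the sex effect is judged by the
#' full-vs-null F test (sex and interaction dropped together, df 2 and
#' n - 4).
#'
#' @param data data.frame with columns `area_km2` (> 0), `sex`, `n_obs`.
#' @return object of class `sex_effect_model` with the fitted models, `F`,
#'   `df`, `p`.
#' @export
sex_effect_lm <- function(data) {
  if (any(data$area_km2 <= 0)) stop("AHR must be positive for log transform")
  if (length(unique(data$sex)) < 2) stop("need both sexes")
  d <- data.frame(y = log(data$area_km2), sex = factor(data$sex),
                  z = transform_predictors(data$n_obs))
  full <- lm(y ~ sex * z, data = d)
  if (any(is.na(stats::coef(full)))) {
    stop("rank-deficient design; aliased term: ",
         paste(names(stats::coef(full))[is.na(stats::coef(full))], collapse = ", "))
  }
  null <- lm(y ~ z, data = d)
  an <- anova(null, full)
  structure(list(full = full, null = null,
                 statistic = an$F[2], df = c(an$Df[2], an$Res.Df[2]),
                 p = an$`Pr(>F)`[2], test = "F"),
            class = "sex_effect_model")
}

#' Sex effect on home-range size, random-intercept mixed model
#'
#' Linear mixed model (maximum likelihood) of log AHR with sex, z-scored
#' log observation count and their interaction as fixed effects and a
#' random intercept per social group; the sex effect is the full-vs-null
#' likelihood-ratio test on 2 df.
#'
#' @param data data.frame with columns `area_km2` (> 0), `sex`, `n_obs`,
#'   `group_id`.
#' @return object of class `sex_effect_model` with `statistic` (chi^2),
#'   `df`, `p`, and `boundary` flag when the random-effect variance is
#'   estimated at zero.
#' @export
sex_effect_lmm <- function(data) {
  if (any(data$area_km2 <= 0)) stop("AHR must be positive for log transform")
  if (length(unique(data$group_id)) < 2) stop("need at least two groups")
  d <- data.frame(y = log(data$area_km2), sex = factor(data$sex),
                  z = transform_predictors(data$n_obs),
                  group = factor(data$group_id))
  full <- suppressWarnings(suppressMessages(
    lme4::lmer(y ~ sex * z + (1 | group), data = d, REML = FALSE)))
  null <- suppressWarnings(suppressMessages(
    lme4::lmer(y ~ z + (1 | group), data = d, REML = FALSE)))
  stat <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null))))
  p <- chi2_upper_tail(stat, 2)
  vc <- as.data.frame(lme4::VarCorr(full))
  tau2 <- vc$vcov[vc$grp == "group"]
  structure(list(full = full, null = null, statistic = stat, df = 2,
                 p = p, test = "chi2_LRT", tau2 = tau2,
                 boundary = isTRUE(tau2 < 1e-8)),
            class = "sex_effect_model")
}

#' @export
print.sex_effect_model <- function(x, ...) {
  if (x$test == "F") {
    cat(sprintf("sex effect (LM): F(%d, %d) = %.2f, p = %.3f\n",
                x$df[1], x$df[2], x$statistic, x$p))
  } else {
    cat(sprintf("sex effect (LMM LRT): chi^2 = %.2f, df = %d, p = %.3f%s\n",
                x$statistic, x$df, x$p,
                if (isTRUE(x$boundary)) " [variance at boundary]" else ""))
  }
  invisible(x)
}
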