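#' Build a habitat mask
#'
#' Regular lattice of potential activity-center cells covering the camera
#' bounding box plus a buffer, with cells whose centers fall outside the
#' habitat polygons flagged nonhabitat and excluded from the integration
#' area.
#'
#' @param cameras camera registry (planar meters).
#' @param buffer_m buffer width around the outermost cameras (m).
#' @param spacing_m lattice spacing (m).
#' @param habitat_polygons optional list of polygon vertex matrices
#'   (see [read_habitat()]); `NULL` means all cells are habitat.
#' @return object of class `habitat_mask`: data.frame of habitat cell
#'   centers with attributes `cell_area_km2`, `area_km2` (total habitat
#'   area `A`), `spacing_m`, `buffer_m`.
#' @export
build_mask <- function(cameras, buffer_m, spacing_m, habitat_polygons = NULL) {
  if (buffer_m <= 0) stop("buffer_m must be positive")
  if (spacing_m <= 0) stop("spacing_m must be positive")
  xs <- seq(min(cameras$x) - buffer_m, max(cameras$x) + buffer_m, by = spacing_m)
  ys <- seq(min(cameras$y) - buffer_m, max(cameras$y) + buffer_m, by = spacing_m)
  # make sure the lattice reaches the far buffer edge
  if (max(xs) < max(cameras$x) + buffer_m - 1e-9) xs <- c(xs, max(xs) + spacing_m)
  if (max(ys) < max(cameras$y) + buffer_m - 1e-9) ys <- c(ys, max(ys) + spacing_m)
  grid <- expand.grid(x = xs, y = ys)
  habitat <- rep(TRUE, nrow(grid))
  if (!is.null(habitat_polygons) && length(habitat_polygons) > 0) {
    inside <- rep(FALSE, nrow(grid))
    for (poly in habitat_polygons) {
      inside <- inside | in_polygon(grid$x, grid$y, poly)
    }
    habitat <- inside
  }
  if (!any(habitat)) stop("habitat mask has zero habitat cells")
  cells <- grid[habitat, , drop = FALSE]
  rownames(cells) <- NULL
  a <- m2_to_km2(spacing_m^2)
  structure(cells, class = c("habitat_mask", "data.frame"),
            cell_area_km2 = a, area_km2 = a * nrow(cells),
            spacing_m = spacing_m, buffer_m = buffer_m)
}

#' @export
print.habitat_mask <- function(x, ...) {
  cat("habitat_mask:", nrow(x), "cells, cell area",
      attr(x, "cell_area_km2"), "km^2, total area",
      round(attr(x, "area_km2"), 2), "km^2, buffer",
      attr(x, "buffer_m"), "m\n")
  invisible(x)
}

#' Root pooled spatial variance of detection locations
#'
#' Pooled dispersion of each individual's detection coordinates about its
#' own centroid: `sqrt(sum_i sum_j ((x_ij - xbar_i)^2 + (y_ij - ybar_i)^2)
#' / sum_i (n_i - 1))`. A data-driven proxy for the half-normal spatial
#' scale, used to suggest mask buffers and optimizer starts.
#'
#' @param history capture_history.
#' @return RPSV in meters.
#' @export
rpsv <- function(history) {
  detcoord <- as.matrix(history$detectors[, c("x", "y")])
  ss <- 0; df <- 0
  for (i in seq_len(history$n)) {
    counts <- apply(history$y[i, , , drop = FALSE], 2, sum)
    idx <- rep(seq_along(counts), counts)
    if (length(idx) < 2) next
    pts <- detcoord[idx, , drop = FALSE]
    ss <- ss + sum(sweep(pts, 2, colMeans(pts))^2)
    df <- df + (nrow(pts) - 1)
  }
  if (df == 0 || ss <= 0) {
    stop("no spatial recaptures: RPSV undefined, supply a buffer manually")
  }
  sqrt(ss / df)
}

#' Suggest a mask buffer width
#'
#' `4 x RPSV`, the conventional rule for half-normal detection.
#'
#' @param history capture_history with at least one individual detected at
#'   two or more distinct detectors.
#' @return buffer width in meters.
#' @export
suggest_buffer <- function(history) 4 * rpsv(history)

#' Half-normal detection function
#'
#' Probability (or encounter-rate scale) of detection at distance `d` from
#' an activity center: `g0 * exp(-d^2 / (2 sigma^2))`.
#'
#' @param d distance in meters (vectorized).
#' @param g0 detection intercept (probability for a Bernoulli detector,
#'   rate `lambda0` for a count detector).
#' @param sigma half-normal spatial scale in meters.
#' @return numeric vector.
#' @export
detection_prob <- function(d, g0, sigma) {
  if (any(d < 0)) stop("distances must be non-negative")
  if (sigma <= 0) stop("sigma must be positive")
  g0 * exp(-d^2 / (2 * sigma^2))
}
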