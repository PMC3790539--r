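# Small builders and independent oracles shared across the suite.

tiny_cameras <- function(nx = 2, ny = 2, spacing = 1000, origin = 0) {
  g <- expand.grid(col = seq_len(nx), row = seq_len(ny))
  data.frame(camera_id = sprintf("C%02d", seq_len(nrow(g))),
             x = origin + g$col * spacing, y = origin + g$row * spacing,
             grid_cell = sprintf("R%02dC%02d", g$row, g$col),
             stringsAsFactors = FALSE)
}

rec_row <- function(id, cam, ts, sex = "female", age = "adult") {
  data.frame(individual_id = id, camera_id = cam,
             timestamp = as.POSIXct(ts, tz = "UTC"),
             sex = sex, age_class = age, stringsAsFactors = FALSE)
}

make_records <- function(...) do.call(rbind, list(...))

# capture_history built directly from a count array (bypasses CSV plumbing)
manual_history <- function(y, cameras, effort = NULL, sex = NULL) {
  n <- dim(y)[1]; K <- dim(y)[2]; S <- dim(y)[3]
  ids <- sprintf("I%03d", seq_len(n))
  dimnames(y) <- list(ids, cameras$camera_id, NULL)
  if (is.null(effort)) {
    effort <- matrix(1, K, S, dimnames = list(cameras$camera_id, NULL))
  }
  structure(list(
    y = y,
    covariates = data.frame(individual_id = ids,
                            sex = sex %||% rep("unknown", n),
                            n_detections = as.integer(apply(y, 1, sum)),
                            stringsAsFactors = FALSE),
    detectors = cameras, effort = effort,
    occasions = data.frame(occasion = seq_len(S)), n = n),
    class = "capture_history")
}

manual_mask <- function(centers, cell_area_km2, buffer_m = 1000) {
  structure(as.data.frame(centers), class = c("habitat_mask", "data.frame"),
            cell_area_km2 = cell_area_km2,
            area_km2 = cell_area_km2 * nrow(centers),
            spacing_m = sqrt(cell_area_km2) * 1000, buffer_m = buffer_m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Simulate straight from the half-normal SECR model (no social structure);
# independent oracle data for estimator checks.
model_true_history <- function(seed, D = 1.5, g0 = 0.1, sigma = 600,
                               nx = 8, ny = 5, spacing = 1000, S = 20,
                               buffer = 2500, encounter = "bernoulli") {
  set.seed(seed)
  cams <- tiny_cameras(nx, ny, spacing)
  xr <- range(cams$x) + c(-buffer, buffer)
  yr <- range(cams$y) + c(-buffer, buffer)
  A <- diff(xr) * diff(yr) / 1e6
  N <- rpois(1, D * A)
  cx <- runif(N, xr[1], xr[2]); cy <- runif(N, yr[1], yr[2])
  h <- g0 * exp(-(outer(cx, cams$x, "-")^2 + outer(cy, cams$y, "-")^2) /
                  (2 * sigma^2))
  y <- if (encounter == "bernoulli") {
    array(rbinom(N * nrow(cams) * S, 1, rep(as.vector(h), S)),
          dim = c(N, nrow(cams), S))
  } else {
    array(rpois(N * nrow(cams) * S, rep(as.vector(h), S)),
          dim = c(N, nrow(cams), S))
  }
  keep <- apply(y, 1, sum) > 0
  list(history = manual_history(y[keep, , , drop = FALSE], cams),
       cameras = cams, N = N, area_km2 = A)
}

# --- independent oracles ----------------------------------------------------

# connected components by breadth-first search over an adjacency list
bfs_components <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      adj[[edges$a[r]]] <- c(adj[[edges$a[r]]], edges$b[r])
      adj[[edges$b[r]]] <- c(adj[[edges$b[r]]], edges$a[r])
    }
  }
  seen <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (v in nodes) {
    if (seen[v]) next
    queue <- v; seen[v] <- TRUE; comp <- c()
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      comp <- c(comp, u)
      for (w in adj[[u]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, min, character(1)))]
}

# O(n^3) convex hull area for points in general position (no three
# collinear, true for continuous random draws): a directed pair (i, j) is a
# hull edge iff every other point lies strictly left of segment i -> j;
# the signed shoelace terms of the collected edges sum to twice the area.
hull_area_oracle <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 3) return(0)
  area2 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      others <- setdiff(seq_len(n), c(i, j))
      cr <- (pts[j, 1] - pts[i, 1]) * (pts[others, 2] - pts[i, 2]) -
        (pts[j, 2] - pts[i, 2]) * (pts[others, 1] - pts[i, 1])
      if (all(cr > 0)) {
        area2 <- area2 + (pts[i, 1] * pts[j, 2] - pts[j, 1] * pts[i, 2])
      }
    }
  }
  abs(area2) / 2
}

# exact Wilcoxon two-sided p by explicit enumeration of all 2^n signs
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  tobs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  tall <- signs %*% rk
  p_ge <- mean(tall >= tobs - 1e-9)
  p_le <- mean(tall <= tobs + 1e-9)
  min(1, 2 * min(p_ge, p_le))
}

# single-individual SECR history enumeration over all Bernoulli outcomes
# at K detectors x S occasions (used to check that conditional history
# probabilities sum to one)
enum_bernoulli_histories <- function(K, S) {
  g <- expand.grid(rep(list(0:1), K * S))
  lapply(seq_len(nrow(g)), function(r) {
    array(as.integer(g[r, ]), dim = c(1, K, S))
  })
}
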