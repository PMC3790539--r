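#' Read timestamped detection records
#'
#' Parses a detections CSV with columns `individual_id, camera_id,
#' timestamp, sex, age_class` (optional `group_hint`). Timestamps are
#' ISO-8601 and normalized to UTC-naive minute resolution. Unidentified
#' visits may carry the reserved id `"UNID"`; they are kept (they feed the
#' identification-rate summary and minimum group-size tallies) but are
#' excluded from capture histories and co-detection graphs.
#'
#' @param path CSV file path.
#' @param cameras optional camera registry (from [read_cameras()]); when
#'   supplied, records referencing unknown cameras raise a validation error
#'   naming the offenders.
#' @return data.frame of detection records with `timestamp` as POSIXct (UTC).
#' @export
read_detections <- function(path, cameras = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("individual_id", "camera_id", "timestamp", "sex", "age_class")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("detections file missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) {
    df$timestamp <- as.POSIXct(character(), tz = "UTC")
    return(df)
  }
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
                                  "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                  "%Y-%m-%d"))
  bad <- which(is.na(ts))
  if (length(bad) > 0) {
    stop("malformed timestamp in row(s): ",
         paste(head(bad, 10), collapse = ", "))
  }
  df$timestamp <- as.POSIXct(trunc(ts, "mins"))
  df$sex <- ifelse(df$sex %in% c("male", "female"), df$sex, "unknown")
  validate_against_registry(df, cameras)
  df
}

validate_against_registry <- function(records, cameras) {
  if (is.null(cameras)) return(invisible(TRUE))
  unknown <- setdiff(unique(records$camera_id), cameras$camera_id)
  if (length(unknown) > 0) {
    stop("detections reference camera(s) absent from registry: ",
         paste(sort(unknown), collapse = ", "))
  }
  invisible(TRUE)
}

#' Read the camera registry
#'
#' @param path CSV with columns `camera_id, x, y, grid_cell` and optional
#'   `coverage_<species>` columns (per-species camera coverage in `[0,1]`).
#' @return data.frame; coordinates are planar meters in a projected CRS.
#' @export
read_cameras <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("camera_id", "x", "y", "grid_cell")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("cameras file missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$camera_id)) stop("duplicate camera_id in registry")
  if (!all(is.finite(df$x)) || !all(is.finite(df$y))) {
    stop("non-finite camera coordinates")
  }
  df
}

#' Read the camera activity log
#'
#' @param path CSV with columns `camera_id, active_from, active_to`
#'   (inclusive dates).
#' @return data.frame with Date columns.
#' @export
read_activity <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("camera_id", "active_from", "active_to")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("activity file missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$active_from <- as.Date(df$active_from)
  df$active_to <- as.Date(df$active_to)
  if (any(df$active_to < df$active_from)) stop("activity range ends before it starts")
  df
}

#' Read habitat polygons from GeoJSON
#'
#' Accepts Polygon and MultiPolygon features; only outer rings are used
#' (nonhabitat here is open water, which the study geometry excludes by
#' outer boundary, not holes).
#'
#' @param path GeoJSON file.
#' @return list of two-column matrices (x, y vertices, planar meters).
#' @export
read_habitat <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  polys <- list()
  for (f in feats) {
    geom <- if (!is.null(f$geometry)) f$geometry else f
    rings <- switch(geom$type,
      Polygon = list(geom$coordinates[[1]]),
      MultiPolygon = lapply(geom$coordinates, function(p) p[[1]]),
      stop("unsupported GeoJSON geometry type: ", geom$type))
    for (r in rings) {
      polys[[length(polys) + 1L]] <-
        do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]])))
    }
  }
  polys
}

#' Split a study window into trapping occasions
#'
#' Consecutive half-open date ranges `[start, start + occasion_days)`; a
#' detection falling exactly on a boundary belongs to the later occasion.
#' The final occasion may be shorter than `occasion_days`.
#'
#' @param study_start,study_end Dates (end exclusive).
#' @param occasion_days occasion length in days (default 30).
#' @return data.frame with `occasion`, `start`, `end` (half-open) and
#'   `days` columns.
#' @export
build_occasions <- function(study_start, study_end, occasion_days = 30L) {
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  if (occasion_days <= 0) stop("occasion_days must be positive")
  if (!(study_start < study_end)) stop("study_start must precede study_end")
  span <- as.integer(study_end - study_start)
  n_occ <- ceiling(span / occasion_days)
  starts <- study_start + (seq_len(n_occ) - 1L) * occasion_days
  ends <- pmin(starts + occasion_days, study_end)
  data.frame(occasion = seq_len(n_occ), start = starts, end = ends,
             days = as.integer(ends - starts))
}

#' Build the camera-by-occasion effort matrix
#'
#' `e[k, s]` is the fraction of occasion `s` during which camera `k` was
#' filming, from an activity log of inclusive date ranges. Overlapping
#' ranges for one camera are merged with a warning.
#'
#' @param activity activity log (see [read_activity()]).
#' @param occasions occasion table from [build_occasions()].
#' @param cameras optional camera registry fixing row order; defaults to the
#'   cameras present in the log.
#' @return matrix `K x S` with camera ids as rownames, values in `[0, 1]`.
#' @export
build_effort <- function(activity, occasions, cameras = NULL) {
  ids <- if (!is.null(cameras)) cameras$camera_id else sort(unique(activity$camera_id))
  e <- matrix(0, nrow = length(ids), ncol = nrow(occasions),
              dimnames = list(ids, NULL))
  for (k in seq_along(ids)) {
    rows <- activity[activity$camera_id == ids[k], , drop = FALSE]
    if (nrow(rows) == 0) next
    # inclusive date ranges -> half-open [from, to + 1)
    iv <- cbind(as.integer(rows$active_from), as.integer(rows$active_to) + 1L)
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    merged <- iv[1, , drop = FALSE]
    overlapped <- FALSE
    if (nrow(iv) > 1) {
      for (r in 2:nrow(iv)) {
        last <- nrow(merged)
        if (iv[r, 1] <= merged[last, 2]) {
          if (iv[r, 1] < merged[last, 2]) overlapped <- TRUE
          merged[last, 2] <- max(merged[last, 2], iv[r, 2])
        } else {
          merged <- rbind(merged, iv[r, ])
        }
      }
    }
    if (overlapped) {
      warning("overlapping activity ranges for camera ", ids[k], "; merged")
    }
    os <- as.integer(occasions$start); oe <- as.integer(occasions$end)
    for (s in seq_len(nrow(occasions))) {
      ov <- sum(pmax(0L, pmin(merged[, 2], oe[s]) - pmax(merged[, 1], os[s])))
      e[k, s] <- ov / (oe[s] - os[s])
    }
  }
  stopifnot(all(e >= 0), all(e <= 1 + 1e-12))
  e[e > 1] <- 1
  e
}

#' Build an effort-corrected capture history
#'
#' Tallies identified detections into counts `y[i, k, s]` per individual,
#' detector and occasion. Identification is restricted to weaned
#' individuals, implemented as `age_class` in `{adult, adolescent}`.
#' Unidentified (`"UNID"`) rows are dropped. A detection at a
#' camera-occasion with zero effort is a data inconsistency and raises an
#' error.
#'
#' @param records detection records (see [read_detections()]).
#' @param cameras camera registry.
#' @param occasions occasion table.
#' @param effort effort matrix from [build_effort()]; rownames must cover
#'   all cameras.
#' @param min_age_classes age classes retained (weaning filter).
#' @return object of class `capture_history`: list with the count array
#'   `y`, individual `covariates` (sex, solitary flag, detection count),
#'   `detectors` (camera registry rows), `effort`, `occasions`, `n`.
#' @export
build_capture_history <- function(records, cameras, occasions, effort,
                                  min_age_classes = c("adult", "adolescent")) {
  stopifnot(nrow(effort) == nrow(cameras), ncol(effort) == nrow(occasions))
  validate_against_registry(records, cameras)
  rec <- records[!is.na(records$individual_id) &
                   records$individual_id != "UNID" &
                   records$age_class %in% min_age_classes, , drop = FALSE]
  ids <- sort(unique(rec$individual_id))
  K <- nrow(cameras); S <- nrow(occasions)
  y <- array(0L, dim = c(length(ids), K, S),
             dimnames = list(ids, cameras$camera_id, NULL))
  if (nrow(rec) > 0) {
    day <- as.Date(rec$timestamp)
    occ <- findInterval(as.integer(day), as.integer(occasions$start))
    occ[day >= occasions$end[S]] <- NA
    if (anyNA(occ) || any(occ < 1)) stop("detection timestamp outside study window")
    ii <- match(rec$individual_id, ids)
    kk <- match(rec$camera_id, cameras$camera_id)
    for (r in seq_len(nrow(rec))) {
      y[ii[r], kk[r], occ[r]] <- y[ii[r], kk[r], occ[r]] + 1L
    }
    bad <- which(apply(y, c(2, 3), sum) > 0 & effort[cameras$camera_id, ] == 0,
                 arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop("detections recorded at camera-occasions with zero effort: ",
           paste(cameras$camera_id[bad[, 1]], "occasion", bad[, 2],
                 collapse = "; "))
    }
  }
  sex <- vapply(ids, function(id) {
    s <- unique(rec$sex[rec$individual_id == id])
    s <- s[s %in% c("male", "female")]
    if (length(s) == 1) s else "unknown"
  }, character(1))
  covariates <- data.frame(individual_id = ids, sex = unname(sex),
                           n_detections = as.integer(apply(y, 1, sum)),
                           stringsAsFactors = FALSE)
  structure(list(y = y, covariates = covariates, detectors = cameras,
                 effort = effort[cameras$camera_id, , drop = FALSE],
                 occasions = occasions, n = length(ids)),
            class = "capture_history")
}

#' @export
print.capture_history <- function(x, ...) {
  cat("capture_history:", x$n, "individuals,", nrow(x$detectors),
      "detectors,", nrow(x$occasions), "occasions,",
      sum(x$y), "detections\n")
  invisible(x)
}

#' Attach a solitary/group covariate to a capture history
#'
#' Marks each individual as `"solitary"` or `"group"` for the
#' group/grouphet model variants. Individuals in multi-member co-detection
#' components are `"group"`. For singletons the default rule is
#' sex-aware: in the one-male-group social systems this covariate serves,
#' solitary individuals are males, so a female captured alone is still a
#' group animal that happened never to be co-identified; only
#' never-co-detected males are labeled `"solitary"`. Set
#' `females_solitary = TRUE` to label all singletons solitary instead.
#'
#' @param history capture_history.
#' @param assignment group assignment from [assign_groups()].
#' @param females_solitary if `TRUE`, singleton females are labeled
#'   solitary too.
#' @return the history with a `solitary` covariate column added.
#' @export
attach_solitary_covariate <- function(history, assignment,
                                      females_solitary = FALSE) {
  memb <- assignment$membership
  grp_size <- table(memb$group_id)
  lab <- ifelse(memb$individual_id %in%
                  memb$individual_id[memb$group_id %in%
                                       names(grp_size)[grp_size > 1]],
                "group", "solitary")
  names(lab) <- memb$individual_id
  out <- lab[history$covariates$individual_id]
  out[is.na(out)] <- "solitary"
  if (!females_solitary) {
    out[out == "solitary" & history$covariates$sex == "female"] <- "group"
  }
  history$covariates$solitary <- unname(out)
  history
}

parse_grid_rc <- function(grid_cell) {
  parts <- regmatches(grid_cell, gregexpr("[0-9]+", grid_cell))
  ok <- vapply(parts, length, integer(1)) >= 2
  if (!all(ok)) {
    stop("grid_cell labels must contain row and column indices: ",
         paste(unique(grid_cell[!ok]), collapse = ", "))
  }
  rc <- t(vapply(parts, function(p) as.integer(p[1:2]), integer(2)))
  colnames(rc) <- c("row", "col")
  rc
}

#' Retain every second camera in the grid (checkerboard subset)
#'
#' Keeps cameras whose grid-cell row+column parity matches `parity`,
#' emulating the camera-number sensitivity analysis of removing every
#' second camera. Individuals with no remaining detections are dropped.
#'
#' @param history capture_history built on the full grid.
#' @param parity 0 or 1, which checkerboard color to keep.
#' @return a reduced `capture_history`.
#' @export
half_grid_subset <- function(history, parity = 0L) {
  cams <- history$detectors
  if (is.null(cams$grid_cell) || anyNA(cams$grid_cell)) {
    stop("grid_cell assignments required for half-grid subsetting")
  }
  rc <- parse_grid_rc(cams$grid_cell)
  keep <- ((rc[, "row"] + rc[, "col"]) %% 2L) == (parity %% 2L)
  y <- history$y[, keep, , drop = FALSE]
  nz <- apply(y, 1, sum) > 0
  cov <- history$covariates[nz, , drop = FALSE]
  cov$n_detections <- as.integer(apply(y[nz, , , drop = FALSE], 1, sum))
  structure(list(y = y[nz, , , drop = FALSE], covariates = cov,
                 detectors = cams[keep, , drop = FALSE],
                 effort = history$effort[keep, , drop = FALSE],
                 occasions = history$occasions, n = sum(nz)),
            class = "capture_history")
}

#' Fraction of camera visits with a positive identification
#'
#' @param records detection records including anonymous `"UNID"` rows.
#' @return list with counts (`visits`, `identified`) and `rate`
#'   (identified / visits); `percent` is the rounded percentage.
#' @export
identification_rate <- function(records) {
  visits <- nrow(records)
  identified <- sum(!is.na(records$individual_id) & records$individual_id != "UNID")
  rate <- if (visits > 0) identified / visits else NA_real_
  list(visits = visits, identified = identified, rate = rate,
       percent = round(100 * rate))
}
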