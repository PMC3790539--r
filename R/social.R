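#' Build the co-detection graph
#'
#' Two identified individuals are linked when they appear on the same
#' camera during the same trigger or within `window_minutes` of one another
#' (inclusive boundary). Anonymous (`"UNID"`) rows are excluded.
#'
#' @param records detection records.
#' @param window_minutes co-capture window (default 15).
#' @return object of class `codetection_graph`: `nodes` (individual ids)
#'   and `edges` data.frame (`a`, `b`, `camera_id`, `time_a`, `time_b`)
#'   with one row per co-capture event; undirected, no self-edges.
#' @export
build_codetection_graph <- function(records, window_minutes = 15) {
  rec <- records[!is.na(records$individual_id) &
                   records$individual_id != "UNID", , drop = FALSE]
  nodes <- sort(unique(rec$individual_id))
  edges <- list()
  for (cam in unique(rec$camera_id)) {
    rc <- rec[rec$camera_id == cam, , drop = FALSE]
    rc <- rc[order(rc$timestamp), , drop = FALSE]
    nr <- nrow(rc)
    if (nr < 2) next
    tt <- as.numeric(rc$timestamp) / 60  # minutes
    for (i in seq_len(nr - 1)) {
      j <- i + 1
      while (j <= nr && tt[j] - tt[i] <= window_minutes) {
        if (rc$individual_id[i] != rc$individual_id[j]) {
          pair <- sort(c(rc$individual_id[i], rc$individual_id[j]))
          edges[[length(edges) + 1L]] <- data.frame(
            a = pair[1], b = pair[2], camera_id = cam,
            time_a = rc$timestamp[i], time_b = rc$timestamp[j],
            stringsAsFactors = FALSE)
        }
        j <- j + 1
      }
    }
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(a = character(), b = character(), camera_id = character(),
               time_a = as.POSIXct(character(), tz = "UTC"),
               time_b = as.POSIXct(character(), tz = "UTC"),
               stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 window_minutes = window_minutes),
            class = "codetection_graph")
}

## union-find with path compression
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Assign social groups by transitive closure of co-detection
#'
#' Connected components of the co-detection graph (if A was captured with B
#' and B with C, then A, B and C share group identity), computed by
#' union-find. Component ids are deterministic, ordered by each
#' component's smallest member id.
#'
#' @param graph codetection_graph.
#' @return object of class `group_assignment`: `membership` data.frame
#'   (`individual_id`, `group_id`), `groups` (list of member vectors),
#'   `solitary` (ids in singleton components).
#' @export
assign_groups <- function(graph) {
  nodes <- graph$nodes
  n <- length(nodes)
  parent <- seq_len(n)
  if (nrow(graph$edges) > 0) {
    ia <- match(graph$edges$a, nodes)
    ib <- match(graph$edges$b, nodes)
    for (r in seq_along(ia)) {
      ra <- uf_find(parent, ia[r]); rb <- uf_find(parent, ib[r])
      if (ra != rb) parent[rb] <- ra
    }
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  comp <- split(nodes, root)
  comp <- comp[order(vapply(comp, min, character(1)))]
  names(comp) <- sprintf("G%03d", seq_along(comp))
  membership <- data.frame(
    individual_id = unlist(comp, use.names = FALSE),
    group_id = rep(names(comp), lengths(comp)),
    stringsAsFactors = FALSE)
  solitary <- unlist(comp[lengths(comp) == 1], use.names = FALSE)
  structure(list(membership = membership, groups = comp,
                 solitary = solitary %||% character(0)),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  sizes <- lengths(x$groups)
  cat("group_assignment:", sum(sizes > 1), "multi-member groups,",
      length(x$solitary), "solitary individuals\n")
  invisible(x)
}

#' Group composition and minimum group size
#'
#' Without anchors, tallies the identified members of each assigned group
#' by age-sex class. With `anchors` (e.g., the silverback of each
#' one-male group), applies the clip rule: for every clip containing an
#' anchor (same camera, within `window_minutes`), tally the age-sex
#' classes of all other individuals present (identified or not); the
#' per-class maxima across clips plus the anchor give the minimum group
#' size.
#'
#' @param records detection records (anonymous rows participate in
#'   anchored tallies).
#' @param assignment group_assignment (used for the non-anchored mode).
#' @param anchors optional character vector of anchor individual ids.
#' @param window_minutes clip window (default 15).
#' @return data.frame with one row per group/anchor: counts per age-sex
#'   class and `min_group_size`.
#' @export
group_composition <- function(records, assignment = NULL, anchors = NULL,
                              window_minutes = 15) {
  classes <- c("adult_female", "adult_male", "adolescent", "juvenile", "infant")
  tally_row <- function(sub) {
    c(adult_female = sum(sub$age_class == "adult" & sub$sex == "female"),
      adult_male = sum(sub$age_class == "adult" & sub$sex == "male"),
      adolescent = sum(sub$age_class == "adolescent"),
      juvenile = sum(sub$age_class == "juvenile"),
      infant = sum(sub$age_class == "infant"))
  }
  if (is.null(anchors)) {
    if (is.null(assignment)) stop("need a group assignment or anchors")
    out <- lapply(names(assignment$groups), function(g) {
      ids <- assignment$groups[[g]]
      sub <- records[records$individual_id %in% ids, , drop = FALSE]
      sub <- sub[!duplicated(sub$individual_id), , drop = FALSE]
      cnt <- tally_row(sub)
      data.frame(group_id = g, t(cnt), min_group_size = length(ids),
                 stringsAsFactors = FALSE)
    })
    return(do.call(rbind, out))
  }
  out <- list()
  for (anc in anchors) {
    det <- records[records$individual_id == anc, , drop = FALSE]
    if (nrow(det) == 0) {
      warning("anchor ", anc, " has no detections; skipped")
      next
    }
    best <- stats::setNames(rep(0, length(classes)), classes)
    for (r in seq_len(nrow(det))) {
      clip <- records[records$camera_id == det$camera_id[r] &
                        abs(as.numeric(records$timestamp) -
                              as.numeric(det$timestamp[r])) <=
                        window_minutes * 60, , drop = FALSE]
      clip <- clip[is.na(clip$individual_id) |
                     clip$individual_id != anc, , drop = FALSE]
      idd <- clip[!is.na(clip$individual_id) & clip$individual_id != "UNID", ]
      idd <- idd[!duplicated(idd$individual_id), , drop = FALSE]
      anon <- clip[is.na(clip$individual_id) | clip$individual_id == "UNID", ]
      cnt <- tally_row(rbind(idd, anon))
      best <- pmax(best, cnt)
    }
    out[[anc]] <- data.frame(group_id = anc, t(best),
                             min_group_size = sum(best) + 1,
                             stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Classify residency from biweekly capture gaps
#'
#' Splits the residency window into `n_periods` biweekly periods, records
#' presence/absence per individual, and scores each individual by the mean
#' waiting time (in biweeks) between successive presence periods.
#' Waiting time `<= resident_max` is resident, `>= nonresident_min`
#' nonresident, values in between intermediate; individuals present in
#' fewer than two periods are unclassifiable.
#'
#' @param records detection records (identified only).
#' @param window_start first day of the residency window.
#' @param n_periods number of biweekly periods (default 26).
#' @param period_days days per period (default 14).
#' @param resident_max,nonresident_min waiting-time thresholds in biweeks.
#' @return data.frame `individual_id`, `n_periods_present`,
#'   `mean_waiting_biweeks`, `label`; presence matrix in attribute
#'   `presence`.
#' @export
residency <- function(records, window_start, n_periods = 26,
                      period_days = 14, resident_max = 5,
                      nonresident_min = 15) {
  rec <- records[!is.na(records$individual_id) &
                   records$individual_id != "UNID", , drop = FALSE]
  window_start <- as.Date(window_start)
  window_end <- window_start + n_periods * period_days
  day <- as.Date(rec$timestamp)
  inside <- day >= window_start & day < window_end
  if (!any(inside)) stop("residency window contains no detections")
  rec <- rec[inside, , drop = FALSE]
  period <- floor(as.integer(as.Date(rec$timestamp) - window_start) /
                    period_days) + 1L
  ids <- sort(unique(rec$individual_id))
  pres <- matrix(FALSE, length(ids), n_periods,
                 dimnames = list(ids, NULL))
  pres[cbind(match(rec$individual_id, ids), period)] <- TRUE
  wbar <- rep(NA_real_, length(ids))
  label <- rep("unclassifiable", length(ids))
  for (i in seq_along(ids)) {
    pp <- which(pres[i, ])
    if (length(pp) < 2) next
    wbar[i] <- mean(diff(pp))
    label[i] <- if (wbar[i] <= resident_max) "resident"
      else if (wbar[i] >= nonresident_min) "nonresident"
      else "intermediate"
  }
  out <- data.frame(individual_id = ids,
                    n_periods_present = rowSums(pres),
                    mean_waiting_biweeks = wbar, label = label,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "presence") <- pres
  out
}
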