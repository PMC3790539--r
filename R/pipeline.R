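#' Write a simulated study dataset to disk
#'
#' Emits `detections.csv`, `cameras.csv`, `activity.csv` and `truth.json`
#' in the dialects the readers of this package expect. Output is
#' byte-identical for a fixed scenario and seed.
#'
#' @param scenario sim_scenario.
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @return the dataset list, invisibly.
#' @export
run_simulation <- function(scenario, dir, seed) {
  ds <- simulate_dataset(scenario, seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  det <- ds$records
  det$timestamp <- format(det$timestamp, "%Y-%m-%dT%H:%M", tz = "UTC")
  write.csv(det, file.path(dir, "detections.csv"), row.names = FALSE)
  write.csv(ds$cameras, file.path(dir, "cameras.csv"), row.names = FALSE)
  act <- ds$activity
  act$active_from <- format(act$active_from)
  act$active_to <- format(act$active_to)
  write.csv(act, file.path(dir, "activity.csv"), row.names = FALSE)
  truth <- ds$truth
  jsonlite::write_json(
    list(D = truth$D, region = truth$region,
         individuals = truth$individuals,
         scenario = list(species = ds$scenario$species,
                         profile = ds$scenario$profile,
                         seed = seed)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(ds)
}

assess_config <- function(...) {
  cfg <- list(variants = c("null", "sex", "sexhet"),
              encounter = "bernoulli", n_distribution = "poisson",
              buffer_m = "auto", spacing_m = NULL,
              occasion_days = 30, window_minutes = 15,
              n_residency_periods = 26, residency_resident_max = 5,
              residency_nonresident_min = 15,
              half_grid = FALSE, region_area_km2 = NULL,
              min_age_classes = c("adult", "adolescent"),
              tirm_max_N = NULL, tirm_boot = 200, seed = 17)
  override <- list(...)
  if (length(override) == 1 && is.list(override[[1]]) &&
      is.null(names(override))) {
    override <- override[[1]]
  }
  for (nm in names(override)) cfg[[nm]] <- override[[nm]]
  cfg
}

#' Run the full population assessment on a dataset directory
#'
#' Reads the detection, camera and activity files, builds the
#' effort-corrected capture history, fits the requested SECR variants,
#' selects the best by AICc, derives density, abundance and circular
#' home-range size, runs the TIRM comparison estimator, infers social
#' groups and residency, and fits MCP-based sex-effect models. Writes
#' `model_table.csv`, `density_report.csv`, `groups.csv`,
#' `residency.csv` and `report.json` to `out_dir`.
#'
#' @param data_dir directory with `detections.csv`, `cameras.csv`,
#'   `activity.csv` (as produced by [run_simulation()]).
#' @param out_dir report directory (created if needed).
#' @param study_start,study_end study window (dates); required because
#'   occasion 1 is anchored at `study_start`.
#' @param ... configuration overrides: `variants`, `encounter`,
#'   `n_distribution`, `buffer_m` (`"auto"` = 4 x RPSV), `spacing_m`,
#'   `half_grid`, `region_area_km2`, thresholds, `seed`.
#' @return list of stage outputs (also serialized to `report.json`),
#'   invisibly.
#' @export
run_assessment <- function(data_dir, out_dir, study_start, study_end, ...) {
  cfg <- assess_config(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  report <- list(config = cfg[setdiff(names(cfg), "min_age_classes")])
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      warning("stage ", name, " failed: ", conditionMessage(e))
      structure(list(error = conditionMessage(e)), class = "stage_error")
    })
    stages[[name]] <<- if (inherits(res, "stage_error")) res$error else "ok"
    res
  }

  cameras <- read_cameras(file.path(data_dir, "cameras.csv"))
  records <- read_detections(file.path(data_dir, "detections.csv"), cameras)
  activity <- read_activity(file.path(data_dir, "activity.csv"))
  occasions <- build_occasions(study_start, study_end, cfg$occasion_days)
  effort <- build_effort(activity, occasions, cameras)
  history <- build_capture_history(records, cameras, occasions, effort,
                                   cfg$min_age_classes)
  report$identification <- identification_rate(records)

  graph <- run_stage("social_graph",
                     build_codetection_graph(records, cfg$window_minutes))
  groups <- run_stage("group_assignment", assign_groups(graph))
  if (!inherits(groups, "stage_error") &&
      any(cfg$variants %in% c("group", "grouphet"))) {
    history <- attach_solitary_covariate(history, groups)
  }
  if (isTRUE(cfg$half_grid)) history <- half_grid_subset(history)
  report$n_individuals <- history$n

  buffer <- if (identical(cfg$buffer_m, "auto")) suggest_buffer(history) else cfg$buffer_m
  sig0 <- tryCatch(rpsv(history), error = function(e) buffer / 4)
  spacing <- cfg$spacing_m %||% max(sig0 / 2, buffer / 30)
  mask <- build_mask(cameras, buffer, spacing)
  report$mask <- list(buffer_m = buffer, spacing_m = spacing,
                      area_km2 = attr(mask, "area_km2"), cells = nrow(mask))

  fits <- list()
  for (v in cfg$variants) {
    sp <- secr_spec(v, cfg$encounter, cfg$n_distribution)
    fits[[v]] <- run_stage(paste0("fit_", v), fit_secr(history, mask, sp))
  }
  fits <- Filter(function(f) inherits(f, "secr_fit") && isTRUE(f$convergence), fits)
  if (length(fits) > 0) {
    mt <- compare_models(fits)
    write.csv(mt, file.path(out_dir, "model_table.csv"), row.names = FALSE)
    best <- fits[[mt$model[1]]]
    region_area <- cfg$region_area_km2 %||% attr(mask, "area_km2")
    ab <- region_abundance(best, region_area)
    prec <- precision(best$derived$D, best$derived$lcl_D, best$derived$ucl_D)
    sig_row <- best$estimates[grep("^logsigma", best$estimates$parameter)[1], ]
    hr <- circular_r95(sig_row$estimate, c(sig_row$lcl, sig_row$ucl))
    dens <- data.frame(model = mt$model[1],
                       density = best$derived$D,
                       lcl = best$derived$lcl_D, ucl = best$derived$ucl_D,
                       precision_pct = prec$percent,
                       abundance = ab$N, abundance_lcl = ab$lcl,
                       abundance_ucl = ab$ucl,
                       region_area_km2 = region_area,
                       hr_area_km2 = hr$area_km2)
    write.csv(dens, file.path(out_dir, "density_report.csv"), row.names = FALSE)
    report$model_table <- mt
    report$best_model <- mt$model[1]
    report$density <- dens
  }

  cts <- history$covariates$n_detections
  tirm <- run_stage("tirm", fit_tirm(cts[cts >= 1], max_N = cfg$tirm_max_N,
                                     n_boot = cfg$tirm_boot, seed = cfg$seed))
  if (!inherits(tirm, "stage_error")) {
    report$tirm <- list(N_hat = tirm$N_hat, ci = tirm$ci,
                        naive_density = naive_density(
                          tirm$N_hat, cfg$region_area_km2 %||%
                            m2_to_km2(diff(range(cameras$x)) *
                                        diff(range(cameras$y)))))
  }

  if (!inherits(groups, "stage_error")) {
    write.csv(groups$membership, file.path(out_dir, "groups.csv"),
              row.names = FALSE)
    report$n_groups <- sum(lengths(groups$groups) > 1)
    report$n_solitary <- length(groups$solitary)
  }
  res <- run_stage("residency",
                   residency(records, occasions$start[1],
                             cfg$n_residency_periods,
                             resident_max = cfg$residency_resident_max,
                             nonresident_min = cfg$residency_nonresident_min))
  if (!inherits(res, "stage_error")) {
    write.csv(res, file.path(out_dir, "residency.csv"), row.names = FALSE)
    report$residency <- as.list(table(res$label))
  }

  hrtab <- run_stage("home_ranges", home_range_table(records, cameras))
  if (!inherits(hrtab, "stage_error")) {
    write.csv(hrtab, file.path(out_dir, "homeranges.csv"), row.names = FALSE)
    sexes <- history$covariates$sex[match(hrtab$subject_id,
                                          history$covariates$individual_id)]
    hd <- data.frame(hrtab, sex = sexes)
    hd <- hd[!is.na(hd$sex) & hd$sex %in% c("male", "female") &
               hd$area_km2 > 0 & hd$n_observations >= 2, ]
    if (nrow(hd) >= 8 && length(unique(hd$sex)) == 2) {
      sm <- run_stage("sex_effect", sex_effect_lm(
        data.frame(area_km2 = hd$area_km2, sex = hd$sex, n_obs = hd$n_observations)))
      if (!inherits(sm, "stage_error")) {
        report$sex_effect <- list(test = sm$test, statistic = sm$statistic,
                                  df = sm$df, p = sm$p)
      }
    }
  }

  report$stages <- stages
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

#' Interobserver reliability report
#'
#' Kappa per participant and species plus the category-level Wilcoxon and
#' species-level Friedman comparisons, written as a results table.
#'
#' @param judgments judgment table (data.frame or CSV path) with columns
#'   `participant_id`, `category`, `species`, `pair_id`, `judgment`,
#'   `gold`.
#' @param out_dir optional directory for `reliability.csv`.
#' @return list with `kappa` (per participant/species) and `tests`.
#' @export
run_reliability <- function(judgments, out_dir = NULL) {
  if (is.character(judgments)) judgments <- read.csv(judgments,
                                                     stringsAsFactors = FALSE)
  kap <- reliability_summary(judgments)
  # per-participant agreement score, blocks = participants, treatments = species
  tests <- list()
  sp <- sort(unique(kap$species))
  if (length(sp) >= 2) {
    parts <- sort(unique(kap$participant_id))
    m <- matrix(NA_real_, length(parts), length(sp),
                dimnames = list(parts, sp))
    for (r in seq_len(nrow(kap))) {
      m[kap$participant_id[r], kap$species[r]] <- kap$po[r]
    }
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) >= 2) {
      tests$friedman <- friedman_test(m)
      if (length(sp) >= 2) {
        for (i in seq_len(length(sp) - 1)) {
          for (j in (i + 1):length(sp)) {
            nm <- paste0("wilcoxon_", sp[i], "_vs_", sp[j])
            tests[[nm]] <- wilcoxon_signed_rank_exact(m[, i], m[, j])
          }
        }
      }
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(kap, file.path(out_dir, "reliability.csv"), row.names = FALSE)
  }
  list(kappa = kap, tests = tests)
}
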