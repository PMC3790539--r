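with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Define a camera-trap simulation scenario
#'
#' Bundles the study design (camera grid, occasions), the population
#' (density, sex ratio, social profile) and the observation process
#' (half-normal detection per class, identification success, co-trigger
#' probability, residency structure) into one validated object. The three
#' presets in [default_scenarios()] emulate sympatric rainforest species
#' with contrasting social systems.
#'
#' @param species label.
#' @param profile social system: `"fission_fusion"` (flexible parties
#'   within stable communities), `"stable_groups"` (one-male groups plus
#'   solitary males), or `"core_groups_plus_solitary_males"` (female core
#'   groups, dispersed solitary males, resident/transient mix).
#' @param D true density of weaned individuals per km^2 over the buffered
#'   region.
#' @param prop_male proportion of males among weaned individuals.
#' @param detect named list of per-class detection parameters, each
#'   `list(g0 = , sigma = )`; `g0` is an occasion-level probability for the
#'   Bernoulli encounter model or an occasion-level rate for the count
#'   model.
#' @param detect_class `"sex"` (classes female/male) or `"solitary"`
#'   (classes group/solitary).
#' @param encounter `"bernoulli"` or `"poisson_count"`.
#' @param n_distribution `"poisson"` or `"binomial"` (used when fitting).
#' @param grid_rows,grid_cols,cell_m camera grid geometry (1-km cells by
#'   default; `grid_rows * grid_cols` cells cover the study area).
#' @param n_cameras cameras actually deployed (one per occupied cell).
#' @param n_occasions,occasion_days sampling occasions.
#' @param study_start first study day.
#' @param id_success probability a camera visit yields a positive
#'   identification.
#' @param co_trigger_prob probability a present group-mate is co-captured
#'   within 15 min of a member's detection.
#' @param region_buffer_m buffer around the camera grid inside which true
#'   activity centers are placed.
#' @param resident_fraction fraction of individuals resident year-round;
#'   the rest are occasional (nonresident) users of the area.
#' @param transient_availability per-occasion probability that a
#'   nonresident is inside the study area (intermittent revisiting; this
#'   is what produces the long between-capture waiting times that define
#'   nonresidents).
#' @param downtime_prob probability a camera suffers one downtime gap.
#' @param downtime_days range (days) of the downtime gap length.
#' @param member_spread_m sd of member activity centers about their group
#'   center.
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(species, profile, D, prop_male, detect,
                         detect_class = c("sex", "solitary"),
                         encounter = c("bernoulli", "poisson_count"),
                         n_distribution = c("poisson", "binomial"),
                         grid_rows = 6, grid_cols = 10, cell_m = 1000,
                         n_cameras = 45, n_occasions = 20,
                         occasion_days = 30, study_start = "2009-04-01",
                         id_success = 0.42, co_trigger_prob = 0.35,
                         region_buffer_m = 3000, resident_fraction = 1,
                         transient_availability = 0.12, downtime_prob = 0.3,
                         downtime_days = c(15, 45), member_spread_m = 300) {
  detect_class <- match.arg(detect_class)
  encounter <- match.arg(encounter)
  n_distribution <- match.arg(n_distribution)
  stopifnot(D >= 0, prop_male >= 0, prop_male <= 1,
            id_success >= 0, id_success <= 1,
            co_trigger_prob >= 0, co_trigger_prob <= 1,
            resident_fraction > 0, resident_fraction <= 1,
            transient_availability > 0, transient_availability <= 1,
            n_cameras <= grid_rows * grid_cols)
  expected <- if (detect_class == "sex") c("female", "male") else c("group", "solitary")
  if (!all(expected %in% names(detect))) {
    stop("detect must have entries for: ", paste(expected, collapse = ", "))
  }
  for (cl in expected) {
    stopifnot(detect[[cl]]$g0 > 0, detect[[cl]]$sigma > 0)
    if (encounter == "bernoulli") stopifnot(detect[[cl]]$g0 < 1)
  }
  structure(list(species = species, profile = profile, D = D,
                 prop_male = prop_male, detect = detect,
                 detect_class = detect_class, encounter = encounter,
                 n_distribution = n_distribution, grid_rows = grid_rows,
                 grid_cols = grid_cols, cell_m = cell_m,
                 n_cameras = n_cameras, n_occasions = n_occasions,
                 occasion_days = occasion_days,
                 study_start = as.Date(study_start),
                 id_success = id_success,
                 co_trigger_prob = co_trigger_prob,
                 region_buffer_m = region_buffer_m,
                 resident_fraction = resident_fraction,
                 transient_availability = transient_availability,
                 downtime_prob = downtime_prob,
                 downtime_days = downtime_days,
                 member_spread_m = member_spread_m),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("sim_scenario %s: %s, D = %.2f /km^2, %d cameras, %d x %d-day occasions\n",
              x$species, x$profile, x$D, x$n_cameras, x$n_occasions,
              x$occasion_days))
  invisible(x)
}

#' Preset scenarios for three social systems
#'
#' Three species-like presets matching the headline study conditions:
#' a fission-fusion community dweller (density 1.72 /km^2, male:female
#' 1:2.1, 42% identification success), a stable one-male-group species
#' (1.2 /km^2, 1:3.2, 22%), and a core-group species with solitary males
#' and a resident/transient mix (1.37 /km^2, 1:2, 43%).
#'
#' @return named list of three `sim_scenario` objects
#'   (`chimpanzee`, `gorilla`, `elephant`).
#' @export
default_scenarios <- function() {
  list(
    chimpanzee = sim_scenario(
      species = "chimpanzee", profile = "fission_fusion",
      D = 1.72, prop_male = 1 / 3.1,
      detect = list(female = list(g0 = 0.024, sigma = 1200),
                    male = list(g0 = 0.037, sigma = 1550)),
      detect_class = "sex", encounter = "bernoulli",
      n_distribution = "binomial",
      id_success = 0.42, co_trigger_prob = 0.06),
    gorilla = sim_scenario(
      species = "gorilla", profile = "stable_groups",
      D = 1.2, prop_male = 1 / 4.2,
      detect = list(group = list(g0 = 0.029, sigma = 1400),
                    solitary = list(g0 = 0.044, sigma = 1900)),
      detect_class = "solitary", encounter = "poisson_count",
      n_distribution = "poisson",
      id_success = 0.22, co_trigger_prob = 0.5),
    elephant = sim_scenario(
      species = "elephant", profile = "core_groups_plus_solitary_males",
      D = 1.37, prop_male = 1 / 3,
      detect = list(female = list(g0 = 0.068, sigma = 1700),
                    male = list(g0 = 0.100, sigma = 2300)),
      detect_class = "sex", encounter = "poisson_count",
      n_distribution = "poisson",
      id_success = 0.43, co_trigger_prob = 0.45,
      resident_fraction = 0.65, transient_availability = 0.12))
}

#' Lay out the systematic camera grid
#'
#' One camera per occupied 1-km grid cell; when `n_cameras` is smaller
#' than the number of cells, unoccupied cells are spread evenly through
#' the grid (camera availability was limited in the emulated design).
#' Cameras sit at cell centers.
#'
#' @param scenario sim_scenario.
#' @return camera registry data.frame (`camera_id`, `x`, `y`,
#'   `grid_cell`).
#' @export
make_camera_grid <- function(scenario) {
  cells <- expand.grid(row = seq_len(scenario$grid_rows),
                       col = seq_len(scenario$grid_cols))
  n_cells <- nrow(cells)
  n_skip <- n_cells - scenario$n_cameras
  keep <- rep(TRUE, n_cells)
  if (n_skip > 0) {
    skip_idx <- round(seq(2, n_cells - 1, length.out = n_skip))
    keep[skip_idx] <- FALSE
  }
  cells <- cells[keep, , drop = FALSE]
  data.frame(camera_id = sprintf("CAM%02d", seq_len(nrow(cells))),
             x = (cells$col - 0.5) * scenario$cell_m,
             y = (cells$row - 0.5) * scenario$cell_m,
             grid_cell = sprintf("R%02dC%02d", cells$row, cells$col),
             stringsAsFactors = FALSE)
}

## Draw the weaned population plus attached unweaned juveniles/infants.
simulate_population_impl <- function(scenario, cameras) {
  buf <- scenario$region_buffer_m
  xr <- range(cameras$x) + c(-buf, buf)
  yr <- range(cameras$y) + c(-buf, buf)
  area <- m2_to_km2(diff(xr) * diff(yr))
  N <- rpois(1, scenario$D * area)
  if (N == 0) {
    return(list(individuals = data.frame(),
                presence = matrix(TRUE, 0, scenario$n_occasions),
                groups = list(), D = scenario$D, D_available = 0,
                region = list(xlim = xr, ylim = yr, area_km2 = area)))
  }
  runifx <- function(n) runif(n, xr[1], xr[2])
  runify <- function(n) runif(n, yr[1], yr[2])
  spread <- scenario$member_spread_m
  ind <- NULL
  juv <- NULL
  gid <- 0
  new_gid <- function() sprintf("T%03d", gid)
  add_juveniles <- function(gx, gy, group_id, n_juv) {
    if (n_juv <= 0) return(NULL)
    data.frame(individual_id = NA_character_,
               sex = sample(c("female", "male"), n_juv, replace = TRUE),
               age_class = sample(c("juvenile", "infant"), n_juv,
                                  replace = TRUE, prob = c(0.6, 0.4)),
               x = gx + rnorm(n_juv, 0, spread),
               y = gy + rnorm(n_juv, 0, spread),
               group_id = group_id, solitary = "group",
               stringsAsFactors = FALSE)
  }
  weaned_ages <- function(n) sample(c("adult", "adolescent"), n,
                                    replace = TRUE, prob = c(0.85, 0.15))
  if (scenario$profile == "fission_fusion") {
    # four communities hold contiguous adjacent territories tiling the
    # region (quadrants with an overlap margin), so realized density is
    # homogeneous while association structure stays community-specific
    n_comm <- 4
    xm <- mean(xr); ym <- mean(yr)
    px <- runifx(N); py <- runify(N)
    # community = quadrant of the jittered position, so realized density
    # stays exactly uniform while territories overlap near boundaries
    jx <- px + rnorm(N, 0, 500); jy <- py + rnorm(N, 0, 500)
    comm <- 1L + (jx > xm) + 2L * (jy > ym)
    ind <- data.frame(individual_id = NA_character_,
                      sex = ifelse(runif(N) < scenario$prop_male, "male", "female"),
                      age_class = weaned_ages(N),
                      x = px, y = py,
                      group_id = sprintf("T%03d", comm), solitary = "group",
                      stringsAsFactors = FALSE)
    for (g in seq_len(n_comm)) {
      if (!any(comm == g)) next
      juv <- rbind(juv, add_juveniles(mean(px[comm == g]),
                                      mean(py[comm == g]),
                                      sprintf("T%03d", g),
                                      rpois(1, 0.25 * sum(comm == g))))
    }
  } else if (scenario$profile == "stable_groups") {
    # one-male groups assembled until the weaned population is used up,
    # with a fixed share of males living solitarily
    n_solitary_males <- rbinom(1, N, 0.12)
    remaining <- N - n_solitary_males
    rows <- list()
    while (remaining > 0) {
      gid <- gid + 1
      n_fem <- min(1 + rpois(1, 2.9), max(remaining - 1, 1))
      n_adol <- if (remaining - 1 - n_fem > 0) rpois(1, 1.2) else 0
      n_adol <- min(n_adol, remaining - 1 - n_fem)
      size <- min(1 + n_fem + max(n_adol, 0), remaining)
      gx <- runifx(1); gy <- runify(1)
      sexes <- c("male", rep("female", n_fem),
                 sample(c("female", "male"), max(n_adol, 0), replace = TRUE))
      ages <- c("adult", rep("adult", n_fem), rep("adolescent", max(n_adol, 0)))
      sexes <- sexes[seq_len(size)]; ages <- ages[seq_len(size)]
      rows[[gid]] <- data.frame(
        individual_id = NA_character_, sex = sexes, age_class = ages,
        x = gx + rnorm(size, 0, spread), y = gy + rnorm(size, 0, spread),
        group_id = new_gid(), solitary = "group", stringsAsFactors = FALSE)
      juv <- rbind(juv, add_juveniles(gx, gy, new_gid(),
                                      rpois(1, 0.5 * size)))
      remaining <- remaining - size
    }
    sol <- if (n_solitary_males > 0) data.frame(
      individual_id = NA_character_, sex = "male", age_class = "adult",
      x = runifx(n_solitary_males), y = runify(n_solitary_males),
      group_id = sprintf("S%03d", seq_len(n_solitary_males)),
      solitary = "solitary", stringsAsFactors = FALSE) else NULL
    ind <- rbind(do.call(rbind, rows), sol)
  } else if (scenario$profile == "core_groups_plus_solitary_males") {
    n_male <- rbinom(1, N, scenario$prop_male)
    n_fem <- N - n_male
    n_sol_fem <- rbinom(1, n_fem, 0.35)
    rows <- list()
    remaining <- n_fem - n_sol_fem
    while (remaining > 0) {
      gid <- gid + 1
      size <- min(sample(2:4, 1), remaining)
      gx <- runifx(1); gy <- runify(1)
      rows[[gid]] <- data.frame(
        individual_id = NA_character_, sex = "female",
        age_class = weaned_ages(size),
        x = gx + rnorm(size, 0, spread), y = gy + rnorm(size, 0, spread),
        group_id = new_gid(), solitary = "group", stringsAsFactors = FALSE)
      juv <- rbind(juv, add_juveniles(gx, gy, new_gid(),
                                      rpois(1, 0.8 * size)))
      remaining <- remaining - size
    }
    singles <- data.frame(
      individual_id = NA_character_,
      sex = c(rep("female", n_sol_fem), rep("male", n_male)),
      age_class = weaned_ages(n_sol_fem + n_male),
      x = runifx(n_sol_fem + n_male), y = runify(n_sol_fem + n_male),
      group_id = sprintf("S%03d", seq_len(n_sol_fem + n_male)),
      solitary = "solitary", stringsAsFactors = FALSE)
    ind <- rbind(do.call(rbind, rows), singles)
  } else {
    stop("unknown profile: ", scenario$profile)
  }
  ind$resident <- runif(nrow(ind)) < scenario$resident_fraction
  if (!is.null(juv) && nrow(juv) > 0) {
    juv$resident <- TRUE
    ind <- rbind(ind, juv)
  }
  ind$individual_id <- sprintf("IND%04d", seq_len(nrow(ind)))
  rownames(ind) <- NULL
  # per-occasion availability: residents always in the area, nonresidents
  # revisit intermittently
  S <- scenario$n_occasions
  presence <- matrix(TRUE, nrow(ind), S,
                     dimnames = list(ind$individual_id, NULL))
  trans <- which(!ind$resident)
  if (length(trans) > 0) {
    presence[trans, ] <- matrix(runif(length(trans) * S) <
                                  scenario$transient_availability,
                                length(trans), S)
  }
  groups <- split(ind$individual_id, ind$group_id)
  # estimand of a closed-population model under temporary emigration:
  # expected time-averaged density of weaned individuals present per
  # occasion (equals D when everyone is resident)
  D_avail <- scenario$D * (scenario$resident_fraction +
                             (1 - scenario$resident_fraction) *
                               scenario$transient_availability)
  list(individuals = ind, presence = presence, groups = groups,
       D = scenario$D, D_available = D_avail,
       region = list(xlim = xr, ylim = yr, area_km2 = area))
}

#' Simulate the true population
#'
#' Population size is Poisson with mean `D` times the buffered region
#' area; activity centers follow the scenario's social profile (shared
#' group centers, community polygons, or dispersed singles). Unweaned
#' juveniles and infants are attached to groups (they are detectable only
#' alongside group members and are excluded from capture histories by the
#' weaning filter).
#'
#' @param scenario sim_scenario.
#' @param cameras camera registry (from [make_camera_grid()]).
#' @param seed RNG seed.
#' @return truth bundle: `individuals` data.frame, `groups` partition,
#'   `D`, `region`.
#' @export
simulate_population <- function(scenario, cameras, seed) {
  with_seed(seed, simulate_population_impl(scenario, cameras))
}

simulate_detections_impl <- function(truth, cameras, scenario) {
  occasions <- build_occasions(scenario$study_start,
                               scenario$study_start +
                                 scenario$n_occasions * scenario$occasion_days,
                               scenario$occasion_days)
  S <- nrow(occasions); K <- nrow(cameras)
  study_days <- as.integer(occasions$end[S] - occasions$start[1])
  # camera downtime: at most one gap per camera
  act_rows <- list()
  active_days <- matrix(TRUE, K, study_days)  # day index 1..study_days
  for (k in seq_len(K)) {
    if (runif(1) < scenario$downtime_prob) {
      len <- sample(scenario$downtime_days[1]:scenario$downtime_days[2], 1)
      st <- sample.int(study_days - len, 1)
      active_days[k, st:(st + len - 1)] <- FALSE
    }
    runs <- rle(active_days[k, ])
    pos <- cumsum(c(0, runs$lengths))
    for (r in seq_along(runs$values)) {
      if (!runs$values[r]) next
      act_rows[[length(act_rows) + 1L]] <- data.frame(
        camera_id = cameras$camera_id[k],
        active_from = occasions$start[1] + pos[r],
        active_to = occasions$start[1] + pos[r + 1] - 1,
        stringsAsFactors = FALSE)
    }
  }
  activity <- do.call(rbind, act_rows)
  effort <- build_effort(activity, occasions, cameras)

  ind <- truth$individuals
  if (nrow(ind) == 0) {
    return(list(records = data.frame(individual_id = character(),
                                     camera_id = character(),
                                     timestamp = as.POSIXct(character(), tz = "UTC"),
                                     sex = character(), age_class = character(),
                                     stringsAsFactors = FALSE),
                activity = activity, occasions = occasions, effort = effort))
  }
  weaned <- which(ind$age_class %in% c("adult", "adolescent"))
  cls <- if (scenario$detect_class == "sex") ind$sex else ind$solitary
  g0v <- vapply(cls, function(cc) scenario$detect[[cc]]$g0 %||% NA_real_, numeric(1))
  sgv <- vapply(cls, function(cc) scenario$detect[[cc]]$sigma %||% NA_real_, numeric(1))
  dx <- outer(ind$x, cameras$x, "-"); dy <- outer(ind$y, cameras$y, "-")
  hmat <- exp(-(dx^2 + dy^2) / (2 * sgv^2))  # N x K half-normal kernel
  gmat <- g0v * hmat
  members <- split(seq_len(nrow(ind)), ind$group_id)

  ev_i <- integer(0); ev_k <- integer(0); ev_t <- numeric(0)
  day0 <- occasions$start[1]
  emit <- function(i, k, stamp) {
    ev_i[length(ev_i) + 1L] <<- i
    ev_k[length(ev_k) + 1L] <<- k
    ev_t[length(ev_t) + 1L] <<- as.numeric(stamp)
  }
  sample_stamp <- function(k, s) {
    days <- which(active_days[k, ] &
                    seq_len(ncol(active_days)) > as.integer(occasions$start[s] - day0) &
                    seq_len(ncol(active_days)) <= as.integer(occasions$end[s] - day0))
    if (length(days) == 0) return(NULL)
    d <- if (length(days) == 1) days else sample(days, 1)
    as.POSIXct(day0, tz = "UTC") + (d - 1) * 86400 +
      sample.int(1440, 1) * 60 - 60
  }
  presence <- truth$presence
  cohesive <- scenario$profile %in% c("stable_groups",
                                      "core_groups_plus_solitary_males")
  if (cohesive) {
    # two-level observation model for cohesive groups: the group passes a
    # camera as a Poisson count process with half-normal decay from the
    # GROUP center, and each present member (weaned or not) is captured
    # with probability `cohesion` given a passage; solitary individuals
    # are their own unit with cohesion 1. This keeps each member's
    # marginal spatial kernel exactly half-normal while inducing the
    # within-group detection correlation of group-living species.
    cohesion <- scenario$co_trigger_prob
    units <- members
    u_center <- t(vapply(units, function(mm) {
      c(mean(ind$x[mm]), mean(ind$y[mm]))
    }, numeric(2)))
    u_wean <- lapply(units, function(mm) intersect(mm, weaned))
    first_weaned <- vapply(u_wean, function(mm) {
      if (length(mm) > 0) mm[1] else NA_integer_
    }, integer(1))
    u_multi <- lengths(units) > 1
    u_g0 <- ifelse(u_multi, g0v[first_weaned] / cohesion, g0v[first_weaned])
    u_sg <- sgv[first_weaned]
    ok <- !is.na(first_weaned)
    du2 <- outer(u_center[, 1], cameras$x, "-")^2 +
      outer(u_center[, 2], cameras$y, "-")^2
    u_rate <- matrix(0, length(units), K)
    u_rate[ok, ] <- u_g0[ok] * exp(-du2[ok, , drop = FALSE] / (2 * u_sg[ok]^2))
    for (s in seq_len(S)) {
      es <- effort[, s]
      lam <- sweep(u_rate, 2, es, "*")
      yk <- matrix(rpois(length(lam), lam), nrow(lam))
      hits <- which(yk > 0, arr.ind = TRUE)
      for (r in seq_len(nrow(hits))) {
        u <- hits[r, 1]; k <- hits[r, 2]
        mm <- units[[u]]
        mm <- mm[presence[mm, s]]
        if (length(mm) == 0) next
        for (v in seq_len(yk[u, k])) {
          stamp <- sample_stamp(k, s)
          if (is.null(stamp)) next
          cap <- if (length(mm) == 1) mm else
            mm[runif(length(mm)) < cohesion]
          for (j in cap) emit(j, k, stamp + round(runif(1, 0, 15)) * 60)
        }
      }
    }
  } else {
    for (s in seq_len(S)) {
      present <- weaned[presence[weaned, s]]
      if (length(present) == 0) next
      es <- effort[, s]
      g <- gmat[present, , drop = FALSE]
      if (scenario$encounter == "bernoulli") {
        p <- 1 - sweep(1 - pmin(g, 1 - 1e-12), 2, es, "^")
        yk <- matrix(rbinom(length(p), 1, p), nrow(p))
      } else {
        lam <- sweep(g, 2, es, "*")
        yk <- matrix(rpois(length(lam), lam), nrow(lam))
      }
      hits <- which(yk > 0, arr.ind = TRUE)
      for (r in seq_len(nrow(hits))) {
        i <- present[hits[r, 1]]; k <- hits[r, 2]
        for (v in seq_len(yk[hits[r, 1], k])) {
          stamp <- sample_stamp(k, s)
          if (is.null(stamp)) next
          emit(i, k, stamp)
          gmem <- members[[ind$group_id[i]]]
          gmem <- setdiff(gmem, i)
          gmem <- gmem[presence[gmem, s]]
          if (length(gmem) > 0 && scenario$co_trigger_prob > 0) {
            # party companions: co-capture damped by the companion's own
            # half-normal kernel so distant mates are not teleported here
            p_co <- scenario$co_trigger_prob * hmat[gmem, k]
            co <- gmem[runif(length(gmem)) < p_co]
            for (j in co) emit(j, k, stamp + round(runif(1, 0, 15)) * 60)
          }
        }
      }
    }
  }
  records <- if (length(ev_i) > 0) {
    data.frame(individual_id = ind$individual_id[ev_i],
               camera_id = cameras$camera_id[ev_k],
               timestamp = as.POSIXct(ev_t, origin = "1970-01-01", tz = "UTC"),
               sex = ind$sex[ev_i], age_class = ind$age_class[ev_i],
               stringsAsFactors = FALSE)
  } else {
    data.frame(individual_id = character(), camera_id = character(),
               timestamp = as.POSIXct(character(), tz = "UTC"),
               sex = character(), age_class = character(),
               stringsAsFactors = FALSE)
  }
  if (nrow(records) > 0) {
    unid <- runif(nrow(records)) >= scenario$id_success
    records$individual_id[unid] <- "UNID"
    records <- records[order(records$timestamp, records$camera_id), ]
    rownames(records) <- NULL
  }
  list(records = records, activity = activity, occasions = occasions,
       effort = effort)
}

#' Simulate the camera-trap observation process
#'
#' Per occasion, individual-camera detections follow the scenario's
#' encounter model with half-normal distance decay from the true activity
#' center, scaled by camera effort (downtime is injected and logged).
#' Each detection of a group member co-triggers other present group mates
#' with probability `co_trigger_prob` within 0-15 minutes. Every visit is
#' identified with probability `id_success`; the rest are emitted as
#' anonymous `"UNID"` rows.
#'
#' @param truth from [simulate_population()].
#' @param cameras camera registry.
#' @param scenario sim_scenario.
#' @param seed RNG seed.
#' @return list with `records`, `activity`, `occasions`, `effort`.
#' @export
simulate_detections <- function(truth, cameras, scenario, seed) {
  with_seed(seed, simulate_detections_impl(truth, cameras, scenario))
}

#' Simulate a complete study dataset
#'
#' @param scenario sim_scenario.
#' @param seed RNG seed (drives population and detections).
#' @return list with `records`, `cameras`, `activity`, `occasions`,
#'   `effort`, `truth`, `scenario`.
#' @export
simulate_dataset <- function(scenario, seed) {
  cameras <- make_camera_grid(scenario)
  truth <- simulate_population(scenario, cameras, seed)
  det <- simulate_detections(truth, cameras, scenario, seed + 1000003L)
  c(det, list(cameras = cameras, truth = truth, scenario = scenario))
}
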