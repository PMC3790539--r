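test_that("presets load with the headline study conditions", {
  scn <- default_scenarios()
  expect_named(scn, c("chimpanzee", "gorilla", "elephant"))
  expect_equal(scn$chimpanzee$D, 1.72)
  expect_equal(scn$gorilla$D, 1.2)
  expect_equal(scn$elephant$D, 1.37)
  expect_equal(scn$chimpanzee$prop_male, 1 / 3.1)
  expect_equal(scn$elephant$id_success, 0.43)
  expect_equal(scn$chimpanzee$n_occasions, 20)
  expect_equal(scn$chimpanzee$occasion_days, 30)
  for (sc in scn) expect_s3_class(sc, "sim_scenario")
})

test_that("population size follows the Poisson(D x area) law", {
  sc <- default_scenarios()$chimpanzee
  cams <- make_camera_grid(sc)
  expect_equal(nrow(cams), 45)

  sc0 <- sc; sc0$D <- 0
  t0 <- simulate_population(sc0, cams, 1)
  expect_equal(nrow(t0$individuals), 0)

  sc1 <- sc; sc1$D <- 1.5
  Ns <- vapply(1:100, function(s) {
    tr <- simulate_population(sc1, cams, s)
    sum(tr$individuals$age_class %in% c("adult", "adolescent"))
  }, numeric(1))
  A <- t0$region$area_km2
  expect_lt(abs(mean(Ns) - 1.5 * A) / (sd(Ns) / 10), 3.5)
})

test_that("social profiles build the advertised group structures", {
  scn <- default_scenarios()
  cams <- make_camera_grid(scn$gorilla)

  tg <- simulate_population(scn$gorilla, cams, 7)
  sizes <- lengths(tg$groups)
  expect_gt(sum(sizes > 1), 5)          # one-male groups
  sol_males <- tg$individuals$solitary == "solitary"
  expect_true(all(tg$individuals$sex[sol_males] == "male"))

  te <- simulate_population(scn$elephant, cams, 7)
  expect_true(any(te$individuals$resident) && any(!te$individuals$resident))
  grp <- te$individuals[te$individuals$solitary == "group" &
                          te$individuals$age_class %in% c("adult", "adolescent"), ]
  expect_true(all(grp$sex == "female"))  # core groups are female

  tc <- simulate_population(scn$chimpanzee, cams, 7)
  expect_lte(length(unique(tc$individuals$group_id[
    tc$individuals$age_class %in% c("adult", "adolescent")])), 4)
})

test_that("empirical detection frequency follows the half-normal curve", {
  sc <- default_scenarios()$chimpanzee
  sc$co_trigger_prob <- 0
  sc$id_success <- 1
  sc$downtime_prob <- 0
  sc$n_occasions <- 10
  cams <- make_camera_grid(sc)
  # 400 independent individuals planted at a fixed point
  n <- 400
  ind <- data.frame(
    individual_id = sprintf("IND%04d", 1:n), sex = "female",
    age_class = "adult", x = 5100, y = 3100,
    group_id = sprintf("S%04d", 1:n), solitary = "solitary",
    resident = TRUE, stringsAsFactors = FALSE)
  truth <- list(individuals = ind,
                presence = matrix(TRUE, n, sc$n_occasions,
                                  dimnames = list(ind$individual_id, NULL)),
                groups = split(ind$individual_id, ind$group_id))
  det <- simulate_detections(truth, cams, sc, 5)
  counts <- table(factor(det$records$camera_id, levels = cams$camera_id))
  d <- sqrt((cams$x - 5100)^2 + (cams$y - 3100)^2)
  p_exp <- detection_prob(d, sc$detect$female$g0, sc$detect$female$sigma)
  trials <- n * sc$n_occasions
  # z-scores of observed vs binomial expectation, nearby cameras only
  near <- p_exp * trials >= 5
  z <- (as.numeric(counts[near]) - p_exp[near] * trials) /
    sqrt(trials * p_exp[near] * (1 - p_exp[near]))
  expect_lt(mean(abs(z) > 3.5), 0.1)
  expect_lt(abs(mean(z)), 1)
})

test_that("identification thinning hits the configured rate", {
  ds <- simulate_dataset(default_scenarios()$chimpanzee, 13)
  idr <- identification_rate(ds$records)
  expect_lt(abs(idr$rate - 0.42), 0.05)
  # anonymous rows never enter capture histories
  h <- build_capture_history(ds$records, ds$cameras, ds$occasions, ds$effort)
  expect_false("UNID" %in% h$covariates$individual_id)
})

test_that("identified detections trace back to true individuals in range", {
  ds <- simulate_dataset(default_scenarios()$chimpanzee, 17)
  ids <- ds$records$individual_id
  known <- ids[ids != "UNID"]
  expect_true(all(known %in% ds$truth$individuals$individual_id))
  # every identified detection lies within plausible half-normal range of
  # the individual's center (6 sigma)
  tr <- ds$truth$individuals
  rec <- ds$records[ds$records$individual_id != "UNID", ]
  i <- match(rec$individual_id, tr$individual_id)
  k <- match(rec$camera_id, ds$cameras$camera_id)
  dd <- sqrt((tr$x[i] - ds$cameras$x[k])^2 + (tr$y[i] - ds$cameras$y[k])^2)
  expect_true(all(dd < 6 * 1550))
})

test_that("without co-capture the fission-fusion social signal disappears", {
  sc <- default_scenarios()$chimpanzee
  sc$co_trigger_prob <- 0
  ds <- simulate_dataset(sc, 23)
  ga <- assign_groups(build_codetection_graph(ds$records))
  frac_grouped <- 1 - length(ga$solitary) / length(ga$membership$individual_id)
  # true structure has everyone in one of four communities; by-chance
  # co-detections should group only a small minority
  expect_lt(frac_grouped, 0.35)

  ds1 <- simulate_dataset(default_scenarios()$chimpanzee, 23)
  ga1 <- assign_groups(build_codetection_graph(ds1$records))
  frac1 <- 1 - length(ga1$solitary) / length(ga1$membership$individual_id)
  expect_gt(frac1, frac_grouped)
})

test_that("scenario validation rejects out-of-range rates", {
  expect_error(sim_scenario("x", "fission_fusion", D = 1, prop_male = 2,
                            detect = list(female = list(g0 = .1, sigma = 500),
                                          male = list(g0 = .1, sigma = 500))))
  expect_error(sim_scenario("x", "fission_fusion", D = 1, prop_male = .5,
                            detect = list(female = list(g0 = .1, sigma = 500))),
               "detect must have entries")
})
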