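test_that("co-detection edges respect the 15-minute same-camera rule", {
  recs <- make_records(
    rec_row("A", "C01", "2009-04-02 10:00"),
    rec_row("B", "C01", "2009-04-02 10:14"),
    rec_row("C", "C01", "2009-04-02 10:30"),   # 16 min after B
    rec_row("D", "C02", "2009-04-02 10:00"),   # other camera, simultaneous
    rec_row("E", "C03", "2009-04-05 08:00"),
    rec_row("F", "C03", "2009-04-05 08:15"))   # boundary, inclusive
  g <- build_codetection_graph(recs)
  pairs <- paste(g$edges$a, g$edges$b)
  expect_true("A B" %in% pairs)
  expect_false("B C" %in% pairs)
  expect_false("A D" %in% pairs)
  expect_true("E F" %in% pairs)
})

test_that("transitive closure joins indirectly co-captured individuals", {
  recs <- make_records(
    rec_row("A", "C01", "2009-04-02 10:00"),
    rec_row("B", "C01", "2009-04-02 10:10"),
    rec_row("B", "C02", "2009-05-02 09:00"),
    rec_row("C", "C02", "2009-05-02 09:05"),
    rec_row("D", "C03", "2009-06-01 12:00"))
  ga <- assign_groups(build_codetection_graph(recs))
  expect_equal(ga$groups[["G001"]], c("A", "B", "C"))
  expect_equal(ga$solitary, "D")

  empty <- build_codetection_graph(make_records(
    rec_row("A", "C01", "2009-04-02 10:00"),
    rec_row("B", "C02", "2009-04-02 10:00"),
    rec_row("C", "C03", "2009-04-02 10:00")))
  ga2 <- assign_groups(empty)
  expect_equal(length(ga2$groups), 3)
  expect_equal(length(ga2$solitary), 3)
})

test_that("union-find components equal BFS components on random graphs", {
  set.seed(99)
  for (rep in 1:25) {
    n <- 60
    nodes <- sprintf("N%03d", 1:n)
    ne <- rpois(1, 40)
    edges <- data.frame(a = sample(nodes, ne, TRUE),
                        b = sample(nodes, ne, TRUE),
                        stringsAsFactors = FALSE)
    edges <- edges[edges$a != edges$b, , drop = FALSE]
    g <- structure(list(nodes = nodes, edges = edges, window_minutes = 15),
                   class = "codetection_graph")
    got <- unname(assign_groups(g)$groups)
    want <- bfs_components(nodes, edges)
    expect_identical(lapply(got, sort), want)
  }
})

test_that("widening the co-detection window never shrinks components", {
  set.seed(123)
  cams <- tiny_cameras(3, 3)
  n <- 40
  recs <- data.frame(
    individual_id = sample(sprintf("I%02d", 1:15), n, TRUE),
    camera_id = sample(cams$camera_id, n, TRUE),
    timestamp = as.POSIXct("2009-04-01", tz = "UTC") +
      runif(n, 0, 5 * 86400),
    sex = "female", age_class = "adult", stringsAsFactors = FALSE)
  for (w in list(c(5, 15), c(15, 60))) {
    a1 <- assign_groups(build_codetection_graph(recs, w[1]))
    a2 <- assign_groups(build_codetection_graph(recs, w[2]))
    s1 <- sort(lengths(a1$groups), decreasing = TRUE)
    s2 <- sort(lengths(a2$groups), decreasing = TRUE)
    expect_lte(length(a2$groups), length(a1$groups))
    expect_gte(max(s2), max(s1))
  }
})

test_that("anchored composition takes per-class maxima across clips", {
  base <- as.POSIXct("2009-04-02 10:00", tz = "UTC")
  clip1 <- rbind(
    rec_row("SB", "C01", base, sex = "male"),
    rec_row("F1", "C01", base + 60, sex = "female"),
    rec_row("F2", "C01", base + 120, sex = "female"),
    rec_row("F3", "C01", base + 180, sex = "female"),
    rec_row("J1", "C01", base + 240, age = "juvenile"),
    rec_row("J2", "C01", base + 300, age = "juvenile"))
  comp1 <- group_composition(clip1, anchors = "SB")
  expect_equal(comp1$min_group_size, 6)
  expect_equal(comp1$adult_female, 3)

  clip2 <- rbind(
    rec_row("SB", "C02", base + 86400, sex = "male"),
    rec_row("F1", "C02", base + 86400 + 60, sex = "female"),
    rec_row("F4", "C02", base + 86400 + 120, sex = "female"),
    rec_row("UNID", "C02", base + 86400 + 180, sex = "female"),
    rec_row("UNID", "C02", base + 86400 + 240, sex = "female"))
  # clip1: 3F + 2J; clip2: 4F -> maxima 4F + 2J + anchor = 7
  comp <- group_composition(rbind(clip1, clip2), anchors = "SB")
  expect_equal(comp$adult_female, 4)
  expect_equal(comp$juvenile, 2)
  expect_equal(comp$min_group_size, 7)

  expect_warning(group_composition(clip1, anchors = "NOPE"), "no detections")
})

test_that("residency labels follow the waiting-time thresholds", {
  start <- as.Date("2009-11-01")
  mk <- function(id, periods) {
    do.call(rbind, lapply(periods, function(p) {
      rec_row(id, "C01", as.POSIXct(start, tz = "UTC") + ((p - 1) * 14 + 3) * 86400)
    }))
  }
  recs <- rbind(mk("RES", 1:26), mk("NON", c(1, 21)), mk("INT", c(1, 9, 17, 25)),
                mk("ONE", 13))
  r <- residency(recs, start)
  row <- function(id) r[r$individual_id == id, ]
  expect_equal(row("RES")$mean_waiting_biweeks, 1)
  expect_equal(row("RES")$label, "resident")
  expect_equal(row("NON")$mean_waiting_biweeks, 20)
  expect_equal(row("NON")$label, "nonresident")
  expect_equal(row("INT")$mean_waiting_biweeks, 8)
  expect_equal(row("INT")$label, "intermediate")
  expect_equal(row("ONE")$label, "unclassifiable")
  expect_error(residency(mk("X", 1), start + 800), "no detections")
})

test_that("known social groups are recovered from co-capture structure", {
  # cohesive-group scenario with high identification so that the social
  # signal, not identification failure, is what is tested
  sc <- default_scenarios()$gorilla
  sc$id_success <- 0.95
  ds <- simulate_dataset(sc, 77)
  ga <- assign_groups(build_codetection_graph(ds$records))
  truth <- ds$truth$individuals
  truth_group <- stats::setNames(truth$group_id, truth$individual_id)
  memb <- ga$membership
  memb$true <- truth_group[memb$individual_id]
  # each inferred component should be pure (one true group), and most
  # individuals should sit in a component matching their true group
  ok <- 0
  for (g in unique(memb$group_id)) {
    tg <- memb$true[memb$group_id == g]
    ok <- ok + max(table(tg))
  }
  expect_gte(ok / nrow(memb), 0.9)
})

test_that("components partition the individuals", {
  sc <- default_scenarios()$gorilla
  ds <- simulate_dataset(sc, 31)
  g <- build_codetection_graph(ds$records)
  ga <- assign_groups(g)
  expect_setequal(ga$membership$individual_id, g$nodes)
  expect_equal(sum(lengths(ga$groups)), length(g$nodes))
})
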