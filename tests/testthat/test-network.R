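test_that("build_network aggregates counts into weights", {
  rec <- visits_tbl(plant = c("p1", "p1"), insect = c("i1", "i2"),
                    year = 2016, week = c(1, 1), count = c(2, 1))
  net <- build_network(rec, year = 2016, week = 1)
  expect_equal(dim(net$weights), c(1L, 2L))
  expect_equal(unname(net$weights["p1", c("i1", "i2")]), c(2, 1))
})

test_that("period filters drop records outside the focal week", {
  rec <- visits_tbl(plant = c("p1", "p2"), insect = c("i1", "i1"),
                    year = 2016, week = c(1, 2), count = c(2, 5))
  net <- build_network(rec, year = 2016, week = 1)
  expect_equal(plants(net), "p1")
  expect_equal(sum(net$weights), 2)
})

test_that("network margins reproduce brute-force per-species tallies", {
  set.seed(21)
  rec <- visits_tbl(
    plant = sample(paste0("p", 1:6), 200, replace = TRUE),
    insect = sample(paste0("i", 1:10), 200, replace = TRUE),
    year = 2016, week = 1, count = sample(1:4, 200, replace = TRUE)
  )
  net <- build_network(rec, year = 2016, week = 1)
  for (p in plants(net)) {
    expect_equal(sum(net$weights[p, ]), sum(rec$count[rec$plant == p]))
  }
  for (i in insects(net)) {
    expect_equal(sum(net$weights[, i]), sum(rec$count[rec$insect == i]))
  }
})

test_that("an empty period signals a skippable condition", {
  rec <- visits_tbl(plant = "p1", insect = "i1", year = 2016, week = 1, count = 1)
  expect_error(build_network(rec, year = 2016, week = 9),
               class = "pollinet_empty_period")
})

test_that("pollen links add exactly one instance per distinct link", {
  net <- make_net(matrix(3, 1, 1, dimnames = list("Dryas", "A sp1")))
  # one individual carrying focal pollen: weight 3 -> 4
  p1 <- pollen_tbl("ind1", "A sp1", 2016, 0, "Dryas", 40)
  expect_equal(merge_pollen_links(net, p1)$weights["Dryas", "A sp1"], 4)
  # five individuals, same link: still +1 in total
  p5 <- pollen_tbl(paste0("ind", 1:5), rep("A sp1", 5), 2016, 0,
                   rep("Dryas", 5), c(40, 1, 7, 3, 99))
  expect_equal(merge_pollen_links(net, p5)$weights["Dryas", "A sp1"], 4)
  # one individual carrying two genera: two links, +1 each, new pair appended
  p2 <- pollen_tbl(c("ind1", "ind1"), "A sp1", 2016, 0,
                   c("Dryas", "Salix"), c(10, 20))
  m <- merge_pollen_links(net, p2)
  expect_equal(m$weights["Dryas", "A sp1"], 4)
  expect_equal(m$weights["Salix", "A sp1"], 1)
  expect_equal(m$provenance, "combined")
})

test_that("zero-grain rows and out-of-period captures contribute nothing", {
  net <- make_net(matrix(3, 1, 1, dimnames = list("Dryas", "A sp1")))
  p0 <- pollen_tbl("ind1", "A sp1", 2016, 0, "Dryas", 0)
  expect_equal(merge_pollen_links(net, p0)$weights["Dryas", "A sp1"], 3)
  plate <- pollen_tbl("ind1", "A sp1", 2016, 5, "Dryas", 10)
  expect_equal(merge_pollen_links(net, plate, year = 2016, week = 0)$weights["Dryas", "A sp1"], 3)
})

test_that("pollen merging never decreases weights nor adds more than 1", {
  set.seed(5)
  sim <- simulate_community(synthetic_config(seed = 5, n_years = 1,
                                             n_plants = 6, n_insects = 10))
  v <- harmonize(add_season_weeks(sim$visits), sim$taxonomy)
  p <- harmonize(add_season_weeks(sim$pollen), sim$taxonomy)
  wk <- sort(unique(v$week))[1:3]
  for (w in wk) {
    net <- tryCatch(build_network(v, year = sim$truth$pollen_year, week = w),
                    pollinet_empty_period = function(e) NULL)
    if (is.null(net)) next
    m <- merge_pollen_links(net, p, year = sim$truth$pollen_year, week = w)
    shared_p <- plants(net); shared_i <- insects(net)
    diff <- m$weights[shared_p, shared_i, drop = FALSE] - net$weights
    expect_true(all(diff >= 0))
    expect_true(all(diff <= 1))
  }
})

test_that("annual networks are the sum of their weekly networks", {
  sim <- simulate_community(synthetic_config(seed = 8, n_years = 2,
                                             n_plants = 8, n_insects = 15))
  v <- harmonize(add_season_weeks(sim$visits), sim$taxonomy)
  weekly <- build_weekly_networks(v)
  yr <- series_keys(weekly)$year[1]
  annual <- build_annual_network(weekly, yr)
  direct <- build_network(v, year = yr)
  expect_equal(sort(plants(annual)), sort(plants(direct)))
  expect_equal(sort(insects(annual)), sort(insects(direct)))
  expect_equal(annual$weights[plants(direct), insects(direct)], direct$weights)
})

test_that("metaweb weights count the weekly networks containing each link", {
  n1 <- make_net(matrix(c(2, 0, 0, 5), 2, 2,
                        dimnames = list(c("p1", "p2"), c("i1", "i2"))))
  n2 <- make_net(matrix(c(1, 0, 1, 1), 2, 2,
                        dimnames = list(c("p1", "p2"), c("i1", "i2"))))
  series <- network_series(list(n1, n2), year = c(2016, 2016), week = c(1, 2))
  mw <- build_metaweb(series)
  expect_equal(mw$weights["p1", "i1"], 2)  # in both weeks
  expect_equal(mw$weights["p2", "i2"], 2)
  expect_equal(mw$weights["p1", "i2"], 1)  # second week only
  expect_equal(mw$period, "metaweb")
  # never-present link absent
  expect_equal(mw$weights["p2", "i1"], 0)
})

test_that("metaweb link-frequency histogram matches a direct recount", {
  sim <- simulate_community(synthetic_config(seed = 13, n_plants = 8,
                                             n_insects = 15))
  v <- harmonize(add_season_weeks(sim$visits), sim$taxonomy)
  weekly <- build_weekly_networks(v)
  mw <- build_metaweb(weekly)
  # brute-force recount from the weekly record table
  counts <- v |>
    dplyr::distinct(.data$plant, .data$insect, .data$year, .data$week) |>
    dplyr::count(.data$plant, .data$insect)
  for (r in seq_len(nrow(counts))) {
    expect_equal(mw$weights[counts$plant[r], counts$insect[r]], counts$n[r])
  }
  expect_true(all(mw$weights <= length(weekly)))
  expect_equal(sum(mw$weights > 0), nrow(counts))
})

test_that("edge-list and incidence files round-trip losslessly", {
  net <- random_net(4, 6)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_edge_list(net, p1)
  back <- read_edge_list(p1)
  expect_equal(back$weights[plants(net), insects(net)], net$weights)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_incidence(net, p2)
  back2 <- read_incidence(p2)
  expect_equal(back2$weights, net$weights)
})

test_that("weekly series skip empty gap weeks and log them", {
  rec <- visits_tbl(plant = c("p1", "p1"), insect = c("i1", "i1"),
                    year = 2016, week = c(1, 3), count = c(1, 1))
  series <- build_weekly_networks(rec)
  expect_equal(length(series), 2)
  skipped <- attr(series, "skipped", exact = TRUE)
  expect_equal(skipped$week, 2L)
})
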