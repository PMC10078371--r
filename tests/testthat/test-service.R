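test_that("svd tables hold genus, family and control summaries", {
  obs <- svd_tbl(
    genus = c(rep("Spilogona", 3), rep("Drymeia", 2), rep("Rhamphomyia", 2)),
    family = c(rep("Muscidae", 5), rep("Empididae", 2)),
    grains = c(10, 20, 30, 5, 15, 100, 200)
  )
  tab <- svd_table(obs)
  expect_equal(tab$genus$mean[tab$genus$genus == "Spilogona"], 20)
  # family means include genus-resolved rows
  expect_equal(tab$family$mean[tab$family$family == "Muscidae"],
               mean(c(10, 20, 30, 5, 15)))
  expect_equal(tab$family$n[tab$family$family == "Muscidae"], 5)
})

test_that("a family with two equally sampled genera averages their means", {
  obs <- svd_tbl(
    genus = c(rep("A", 2), rep("B", 2)),
    family = rep("F", 4),
    grains = c(10, 10, 30, 30)
  )
  tab <- svd_table(obs)
  expect_equal(tab$family$mean[tab$family$family == "F"], 20)
})

test_that("control flowers are summarized but never subtracted", {
  obs <- dplyr::bind_rows(
    svd_tbl(genus = "A", family = "F", grains = c(50, 70)),
    svd_tbl(genus = NA_character_, family = NA_character_,
            grains = c(0, 0, 2, 2, 3, 1, 9, 4, 150), is_control = TRUE)
  )
  tab <- svd_table(obs)
  expect_equal(tab$control$median, 2)
  expect_equal(tab$control$mean, 19)
  expect_equal(tab$control$n, 9)
  expect_equal(tab$genus$mean, 60)  # untouched by controls
})

test_that("svd_table without trial rows is an error", {
  obs <- svd_tbl(genus = NA_character_, family = NA_character_,
                 grains = 1, is_control = TRUE)
  expect_error(svd_table(obs), class = "pollinet_svd_error")
})

make_service_fixture <- function() {
  # 3 taxa, 2 weeks of visits to the focal plant
  w1 <- matrix(c(10, 4, 2), 1, 3,
               dimnames = list("Dryas", c("A sp1", "B sp1", "C sp1")))
  w2 <- matrix(c(5, 1), 1, 2, dimnames = list("Dryas", c("A sp1", "C sp1")))
  series <- network_series(list(make_net(w1, prune = FALSE),
                                make_net(w2, prune = FALSE)),
                           year = 2016, week = c(1, 2))
  svd <- svd_table(svd_tbl(
    genus = c("A", "A", "B", NA),
    family = c("FamA", "FamA", "FamB", "FamC"),
    grains = c(40, 60, 30, 12)
  ))
  taxa <- tibble::tibble(taxon = c("A sp1", "B sp1", "C sp1"),
                         genus = c("A", "B", "C"),
                         family = c("FamA", "FamB", "FamC"))
  list(series = series, svd = svd, taxa = taxa)
}

test_that("service estimates are visits x SVD with genus-first fallback", {
  f <- make_service_fixture()
  est <- estimate_service(f$series, f$svd, "Dryas", f$taxa)
  # genus-level: A has mean 50 -> 10 visits = 500 grains
  a1 <- est[est$insect_taxon == "A sp1" & est$week == 1, ]
  expect_equal(a1$estimated_grains, 500)
  expect_equal(a1$svd_level, "genus")
  # family fallback: genus C unseen, family FamC mean 12, 2 visits -> 24
  c1 <- est[est$insect_taxon == "C sp1" & est$week == 1, ]
  expect_equal(c1$estimated_grains, 24)
  expect_equal(c1$svd_level, "family")
  # hand-summed community total over 3 taxa x 2 weeks:
  # A: (10+5)*50 = 750; B: 4*30 = 120; C: (2+1)*12 = 36
  expect_equal(sum(est$estimated_grains), 750 + 120 + 36)
})

test_that("annual estimates are exact sums of weekly estimates", {
  f <- make_service_fixture()
  est <- estimate_service(f$series, f$svd, "Dryas", f$taxa)
  ann <- service_annual(est)
  for (r in seq_len(nrow(ann))) {
    weekly_sum <- sum(est$estimated_grains[
      est$insect_taxon == ann$insect_taxon[r] & est$year == ann$year[r]])
    expect_identical(ann$estimated_grains[r], weekly_sum)
  }
  expect_identical(sum(service_total(est)$estimated_grains),
                   sum(est$estimated_grains))
})

test_that("estimate_service is linear in visits", {
  f <- make_service_fixture()
  est <- estimate_service(f$series, f$svd, "Dryas", f$taxa)
  doubled <- f$series
  for (k in seq_along(doubled)) doubled[[k]]$weights <- doubled[[k]]$weights * 2
  est2 <- estimate_service(doubled, f$svd, "Dryas", f$taxa)
  expect_equal(est2$estimated_grains, 2 * est$estimated_grains)
})

test_that("dropping a genus entry flips only that taxon to family level", {
  f <- make_service_fixture()
  before <- estimate_service(f$series, f$svd, "Dryas", f$taxa)
  svd2 <- f$svd
  svd2$genus <- svd2$genus[svd2$genus$genus != "A", ]
  after <- estimate_service(f$series, svd2, "Dryas", f$taxa)
  a <- after[after$insect_taxon == "A sp1", ]
  expect_true(all(a$svd_level == "family"))
  others_b <- before[before$insect_taxon != "A sp1", ]
  others_a <- after[after$insect_taxon != "A sp1", ]
  expect_equal(others_a$estimated_grains, others_b$estimated_grains)
})

test_that("taxa without genus or family estimates are excluded with warning", {
  f <- make_service_fixture()
  taxa <- f$taxa
  taxa$genus[3] <- "Unknown"; taxa$family[3] <- "Unknownidae"
  expect_warning(est <- estimate_service(f$series, f$svd, "Dryas", taxa),
                 "C sp1")
  expect_false("C sp1" %in% est$insect_taxon)
  expect_equal(attr(est, "excluded_taxa"), "C sp1")
})

test_that("a focal plant absent everywhere is an error", {
  f <- make_service_fixture()
  expect_error(estimate_service(f$series, f$svd, "Nosuchplant", f$taxa),
               class = "pollinet_service_error")
})

test_that("activity periods average distinct weeks over observed years", {
  rec <- visits_tbl(
    plant = "Dryas", insect = rep("A sp1", 5),
    year = c(2015, 2015, 2015, 2016, 2016),
    week = c(23, 24, 25, 24, 25), count = 1
  )
  act <- activity_periods(rec)
  expect_equal(act$activity_weeks, 2.5)
  one <- activity_periods(visits_tbl("Dryas", "B sp1", 2016, 4, 2))
  expect_equal(one$activity_weeks, 1)
})

test_that("transport estimates average loads over captured individuals", {
  pol <- pollen_tbl(c("i1", "i2"), "A sp1", 2016, 1, c("Dryas", "Dryas"),
                    c(100, 50))
  tr <- estimate_transport(pol)
  expect_equal(tr$mean_load, 75)
  expect_equal(tr$n_individuals, 2L)
  expect_equal(tr$estimated_removed, 150)
})

test_that("transport totals equal brute-force recomputation from raw rows", {
  sim <- simulate_community(synthetic_config(seed = 17, n_plants = 6,
                                             n_insects = 10))
  pol <- harmonize(add_season_weeks(sim$pollen), sim$taxonomy)
  tr <- estimate_transport(pol)
  # estimated_removed is mean_load scaled back by individuals: the total
  # grains actually recovered, per (taxon, plant, week)
  expect_equal(sum(tr$estimated_removed), sum(pol$grains))
  one <- tr[which.max(tr$estimated_removed), ]
  raw <- pol[pol$insect == one$insect_taxon & pol$week == one$week &
               pol$plant_genus == one$plant, ]
  expect_equal(one$estimated_removed, sum(raw$grains))
})

test_that("fit_line reproduces exact and closed-form answers", {
  x <- c(1, 2, 3, 4, 5)
  exact <- fit_line(x, 2 * x)
  expect_equal(exact$slope, 2)
  expect_equal(exact$r_squared, 1)
  flat <- fit_line(x, rep(3, 5))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  set.seed(14)
  xr <- rnorm(12); yr <- 1 + 0.5 * xr + rnorm(12)
  fit <- fit_line(xr, yr)
  ora <- oracle_ols(xr, yr)
  for (f in c("slope", "intercept", "r_squared", "adj_r_squared", "p_value")) {
    expect_equal(fit[[f]], ora[[f]], tolerance = 1e-10)
  }
  expect_error(fit_line(c(1, 1, 1), c(1, 2, 3)), class = "pollinet_lm_error")
  expect_error(fit_line(c(1, 2), c(1, 2)), class = "pollinet_lm_error")
})

test_that("stepwise simplification drops absent year effects", {
  sim <- simulate_community(scenario("no_year_effect", seed = 1))
  v <- harmonize(add_season_weeks(sim$visits), sim$taxonomy)
  weekly <- build_weekly_networks(v)
  svd <- svd_table(sim$svd)
  est <- suppressWarnings(estimate_service(weekly, svd, "Dryas", sim$taxa))
  res <- service_vs_activity(service_annual(est), activity_periods(v))
  expect_setequal(res$dropped, c("activity_weeks:year_c", "year_c"))
  expect_equal(res$final$formula, "estimated_grains ~ activity_weeks")
})

test_that("constant service yields a zero activity slope", {
  sa <- tibble::tibble(
    insect_taxon = rep(c("A", "B", "C", "D"), 2),
    year = rep(c(2015, 2016), each = 4),
    estimated_grains = 100
  )
  act <- tibble::tibble(insect_taxon = c("A", "B", "C", "D"),
                        activity_weeks = c(2, 4, 6, 8))
  res <- service_vs_activity(sa, act)
  expect_equal(res$final$slope, 0)
})
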