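test_that("binary connectance matches hand values", {
  expect_equal(connectance_binary(make_net(matrix(1, 2, 2))), 1)
  w <- matrix(c(1, 0, 1, 0, 0, 1), 2, 3)  # 2 plants x 3 insects, 3 links
  expect_equal(connectance_binary(make_net(w)), 0.5)
})

test_that("adding a link between existing species raises binary connectance", {
  set.seed(2)
  for (k in 1:10) {
    net <- random_net(4, 5)
    zero <- which(net$weights == 0, arr.ind = TRUE)
    if (nrow(zero) == 0) next
    before <- connectance_binary(net)
    net$weights[zero[1, 1], zero[1, 2]] <- 1
    expect_gt(connectance_binary(net), before)
  }
})

test_that("weighted connectance has its closed-form anchors", {
  # a single link: one effective partner each side, LD 1, C_w = 0.5
  expect_equal(connectance_weighted(make_net(matrix(4, 1, 1))), 0.5)
  # complete equal-weight networks of any shape sit at 0.5
  for (dims in list(c(2, 2), c(3, 5), c(4, 2))) {
    w <- matrix(2.5, dims[1], dims[2])
    expect_equal(connectance_weighted(make_net(w)), 0.5, tolerance = 1e-12)
  }
})

test_that("weighted connectance equals the step-by-step entropy oracle", {
  set.seed(31)
  for (k in 1:20) {
    net <- random_net(4, 5)
    expect_equal(connectance_weighted(net),
                 oracle_weighted_connectance(net$weights),
                 tolerance = 1e-12)
  }
})

test_that("NODF anchors: perfect nesting scores 100, checkerboard 0", {
  tri <- matrix(c(1, 1, 1,
                  1, 1, 0,
                  1, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(nodf_binary(make_net(tri)), 100)
  expect_equal(nodf_binary(make_net(diag(2) + 0)), 0)
  # weighted: strictly decreasing weights across the nested fill -> 100
  triw <- matrix(c(9, 8, 7,
                   5, 4, 0,
                   2, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(nodf_weighted(make_net(triw)), 100)
  # equal weights: no strict dominance anywhere -> 0
  expect_equal(nodf_weighted(make_net(tri * 3)), 0)
})

test_that("NODF matches the pair-enumeration oracle on random matrices", {
  set.seed(41)
  for (k in 1:30) {
    net <- random_net(5, 6, p_link = 0.45)
    expect_equal(nodf_binary(net), oracle_nodf_binary(net$weights),
                 tolerance = 1e-12)
    expect_equal(nodf_weighted(net), oracle_nodf_weighted(net$weights),
                 tolerance = 1e-12)
  }
})

test_that("binary NODF agrees with vegan's fill-sorted implementation", {
  skip_if_not_installed("vegan")
  set.seed(42)
  for (k in 1:20) {
    net <- random_net(5, 6, p_link = 0.5)
    b <- (net$weights > 0) * 1
    v <- unname(vegan::nestednodf(b, order = TRUE,
                                  weighted = FALSE)$statistic["NODF"])
    expect_equal(nodf_binary(net), v, tolerance = 1e-9)
  }
})

test_that("metrics are invariant under species permutations", {
  set.seed(51)
  net <- random_net(5, 7)
  perm <- net
  perm$weights <- net$weights[sample(5), sample(7)]
  expect_equal(connectance_binary(perm), connectance_binary(net))
  expect_equal(connectance_weighted(perm), connectance_weighted(net))
  expect_equal(nodf_binary(perm), nodf_binary(net))
  expect_equal(nodf_weighted(perm), nodf_weighted(net))
})

test_that("single-module partitions have zero modularity", {
  set.seed(61)
  net <- random_net(3, 4)
  labels <- rep(1L, 7)
  expect_equal(oracle_barber_q(net$weights, labels), 0, tolerance = 1e-12)
})

test_that("two disjoint blocks are recovered at the exhaustive optimum", {
  w <- matrix(0, 4, 4)
  w[1:2, 1:2] <- 3
  w[3:4, 3:4] <- 3
  net <- make_net(w)
  fit <- modularity(net, restarts = 10, seed = 1)
  expect_equal(fit$q, oracle_exhaustive_q(net$weights), tolerance = 1e-12)
  a <- fit$assignment
  expect_equal(a$module[a$node == "p1"], a$module[a$node == "i1"])
  expect_false(a$module[a$node == "p1"] == a$module[a$node == "p3"])
})

test_that("returned Q recomputes from its own partition", {
  set.seed(71)
  for (k in 1:5) {
    net <- random_net(4, 5)
    fit <- modularity(net, restarts = 10, seed = k)
    labels <- fit$assignment$module
    expect_equal(oracle_barber_q(net$weights, labels), fit$q,
                 tolerance = 1e-12)
  }
})

test_that("the heuristic never exceeds the exhaustive optimum", {
  set.seed(81)
  for (k in 1:10) {
    net <- random_net(3, 4, p_link = 0.5)
    h <- modularity(net, restarts = 10, seed = k)$q
    expect_lte(h, oracle_exhaustive_q(net$weights) + 1e-9)
  }
})

test_that("metric sets respect the binary-only rule for pollen networks", {
  net <- make_net(matrix(c(1, 1, 0, 1), 2, 2), provenance = "pollen")
  expect_warning(ms <- metric_set(net, mode = "full", seed = 1), "binary")
  expect_true(is.na(ms$connectance_wt))
  expect_true(is.na(ms$nodf_wt))
  expect_false(is.na(ms$nodf_bin))
})

test_that("metrics undefined on degenerate networks are NA, not zero", {
  tiny <- make_net(matrix(2, 1, 1))
  ms <- metric_set(tiny, seed = 1)
  expect_true(is.na(ms$nodf_bin))
  expect_equal(ms$n_links, 1L)
  expect_equal(ms$connectance_bin, 1)
})

test_that("NODF stays within [0, 100] across random networks", {
  set.seed(91)
  for (k in 1:20) {
    net <- random_net(sample(2:6, 1), sample(2:6, 1), p_link = 0.5)
    for (v in c(nodf_binary(net), nodf_weighted(net))) {
      expect_gte(v, 0)
      expect_lte(v, 100)
    }
  }
})

test_that("series metrics produce one row per non-empty week", {
  sim <- simulate_community(synthetic_config(seed = 3, n_years = 2,
                                             n_plants = 6, n_insects = 12))
  v <- harmonize(add_season_weeks(sim$visits), sim$taxonomy)
  weekly <- build_weekly_networks(v)
  ms <- series_metrics(weekly, restarts = 5, seed = 1)
  expect_equal(nrow(ms), length(weekly))
  expect_true(all(c("year", "week", "connectance_bin", "modularity_q") %in%
                    names(ms)))
  expect_false(any(is.na(ms$connectance_bin)))
})
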