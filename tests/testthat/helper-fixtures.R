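# Fixture builders used across the suite.

# Wrap a plain matrix as a network, adding names when missing.
make_net <- function(w, period = "test", provenance = "visitation",
                     prune = TRUE) {
  if (is.null(rownames(w))) rownames(w) <- paste0("p", seq_len(nrow(w)))
  if (is.null(colnames(w))) colnames(w) <- paste0("i", seq_len(ncol(w)))
  bipartite_network(w, period = period, provenance = provenance, prune = prune)
}

# Random pruned weighted network with every species linked.
random_net <- function(n_plants, n_insects, p_link = 0.5, max_w = 9) {
  repeat {
    w <- matrix(stats::rbinom(n_plants * n_insects, 1, p_link), n_plants, n_insects)
    if (all(rowSums(w) > 0) && all(colSums(w) > 0)) break
  }
  w <- w * matrix(sample(seq_len(max_w), n_plants * n_insects, replace = TRUE),
                  n_plants, n_insects)
  # re-check: sampling weights cannot zero a link, but keep the guard simple
  make_net(w)
}

# Minimal visits table (already harmonized, with weeks assigned).
visits_tbl <- function(plant, insect, year, week, count) {
  structure(
    tibble::tibble(plant = plant, insect = insect,
                   date = as.Date(paste0(year, "-06-01")) + 7L * week,
                   count = as.integer(count),
                   year = as.integer(year), week = as.integer(week),
                   evidence = "visit"),
    pollinet_schema = "visits"
  )
}

pollen_tbl <- function(individual, insect, year, week, plant_genus, grains) {
  structure(
    tibble::tibble(individual = individual, insect = insect,
                   date = as.Date(paste0(year, "-06-01")) + 7L * week,
                   plant_genus = plant_genus, grains = as.integer(grains),
                   year = as.integer(year), week = as.integer(week)),
    pollinet_schema = "pollen"
  )
}

svd_tbl <- function(genus, family, grains, is_control = FALSE) {
  structure(
    tibble::tibble(genus = genus, family = family,
                   grains = as.integer(grains),
                   is_control = rep_len(is_control, length(grains))),
    pollinet_schema = "svd"
  )
}

write_tmp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
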