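# Bipartite network container and constructors -------------------------------

#' Construct a bipartite plant-insect network
#'
#' Low-level constructor around a plants x insects weight matrix. Most
#' users build networks from records with [build_network()] instead.
#'
#' @param weights Numeric matrix, plants in rows, insects in columns,
#'   with row and column names. Weights must be non-negative.
#' @param period Label for the focal period, e.g. `"2016-w04"`, a year, or
#'   `"metaweb"`.
#' @param provenance One of `"visitation"`, `"pollen"`, `"combined"`.
#' @param prune Drop species with no interactions (all-zero rows/columns)?
#'   Networks describing an observed period always exclude such species;
#'   null-model replicates keep them as drawn.
#' @return A `bipartite_network` object.
#' @export
bipartite_network <- function(weights, period = "network",
                              provenance = c("visitation", "pollen", "combined"),
                              prune = TRUE) {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(weights), !is.null(rownames(weights)), !is.null(colnames(weights)))
  if (anyDuplicated(rownames(weights)) || anyDuplicated(colnames(weights))) {
    rlang::abort("Duplicate species names in network.", class = "pollinet_network_error")
  }
  if (any(weights < 0)) {
    rlang::abort("Negative interaction weights.", class = "pollinet_network_error")
  }
  if (prune) {
    weights <- weights[rowSums(weights) > 0, colSums(weights) > 0, drop = FALSE]
  }
  structure(
    list(weights = weights, period = period, provenance = provenance),
    class = "bipartite_network"
  )
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf(
    "<bipartite_network> %s (%s): %d plants x %d insects, %d links, total weight %g\n",
    x$period, x$provenance, n_plants(x), n_insects(x), n_links(x), sum(x$weights)
  ))
  invisible(x)
}

#' Network dimensions and species
#'
#' @param net A `bipartite_network`.
#' @return `n_plants()`, `n_insects()`, `n_links()` return integers;
#'   `plants()` and `insects()` the species name vectors.
#' @name network-accessors
#' @export
n_plants <- function(net) nrow(net$weights)

#' @rdname network-accessors
#' @export
n_insects <- function(net) ncol(net$weights)

#' @rdname network-accessors
#' @export
n_links <- function(net) sum(net$weights > 0)

#' @rdname network-accessors
#' @export
plants <- function(net) rownames(net$weights)

#' @rdname network-accessors
#' @export
insects <- function(net) colnames(net$weights)

# Drop species without links (used before metric computation so that
# "possible links" counts only temporally co-occurring species).
prune_network <- function(net) {
  w <- net$weights
  keep_p <- rowSums(w) > 0
  keep_i <- colSums(w) > 0
  if (all(keep_p) && all(keep_i)) return(net)
  net$weights <- w[keep_p, keep_i, drop = FALSE]
  net
}

#' Build a network from interaction records for one period
#'
#' Aggregates visit records into a weighted incidence matrix: the weight
#' of a plant x insect cell is the total number of times the interaction
#' was observed during the focal period. Species with no interactions in
#' the period do not appear at all — links absent because the species'
#' phenologies do not overlap ("forbidden links") are excluded from the
#' network, not zero-filled.
#'
#' @param records A harmonized `visits` record table with `year` and
#'   `week` columns (see [add_season_weeks()]).
#' @param year Focal year; `NULL` pools all years.
#' @param week Focal season week; `NULL` pools the whole year (annual
#'   network).
#' @param provenance Provenance label for the resulting network.
#' @return A `bipartite_network`. An empty period signals a condition of
#'   class `pollinet_empty_period` so that callers iterating over weeks
#'   can skip it.
#' @export
build_network <- function(records, year = NULL, week = NULL,
                          provenance = "visitation") {
  sel <- rep(TRUE, nrow(records))
  if (!is.null(year)) sel <- sel & records$year %in% year
  if (!is.null(week)) sel <- sel & records$week %in% week
  records <- records[sel, , drop = FALSE]
  if (nrow(records) == 0) {
    rlang::abort(
      paste0("No interaction records in period (year=",
             if (is.null(year)) "all" else paste(year, collapse = ","),
             ", week=", if (is.null(week)) "all" else paste(week, collapse = ","), ")."),
      class = "pollinet_empty_period"
    )
  }
  agg <- records |>
    dplyr::summarise(weight = sum(.data$count), .by = c("plant", "insect"))
  w <- .edges_to_matrix(agg$plant, agg$insect, agg$weight)
  label <- paste0(
    if (is.null(year)) "all-years" else paste(year, collapse = "+"),
    if (is.null(week)) "" else sprintf("-w%02d", week[1])
  )
  bipartite_network(w, period = label, provenance = provenance)
}

.edges_to_matrix <- function(plant, insect, weight) {
  ps <- sort(unique(plant))
  is <- sort(unique(insect))
  w <- matrix(0, length(ps), length(is), dimnames = list(ps, is))
  w[cbind(match(plant, ps), match(insect, is))] <- weight
  w
}

#' Add pollen-transport links to a visitation network
#'
#' The pollen load an insect carries proves at least one earlier visit to
#' each plant genus found on its body, so each distinct
#' (insect taxon, plant genus) pair with a positive grain count among the
#' period's pollen records adds exactly one visit instance — +1 to the
#' corresponding cell, regardless of how many individuals carried the
#' pollen or how many grains they bore. Pollen links are dated by the week
#' the insect was captured, so only records whose week falls in the
#' period contribute. Pairs not present in the visitation network are
#' appended as new links (weight 1).
#'
#' Pollen grains are identified to plant genus while visitation plants
#' may be species-level: a pollen genus is matched to the visitation
#' plant whose genus (first name component) equals it, when that match is
#' unique; otherwise the link attaches to a genus-level node.
#'
#' @param visit_net A visitation `bipartite_network`.
#' @param pollen A harmonized `pollen` record table with `year`/`week`.
#' @param year,week Focal period filter applied to capture weeks; `NULL`
#'   pools over that key.
#' @return A `bipartite_network` with provenance `"combined"`.
#' @export
merge_pollen_links <- function(visit_net, pollen, year = NULL, week = NULL) {
  sel <- rep(TRUE, nrow(pollen))
  if (!is.null(year)) sel <- sel & pollen$year %in% year
  if (!is.null(week)) sel <- sel & pollen$week %in% week
  pollen <- pollen[sel & pollen$grains > 0, , drop = FALSE]
  links <- dplyr::distinct(pollen, .data$insect, .data$plant_genus)
  if (nrow(links) == 0) {
    out <- visit_net
    out$provenance <- "combined"
    return(out)
  }
  genus_of <- function(x) vapply(strsplit(x, "[ _]"), `[[`, "", 1)
  vg <- genus_of(plants(visit_net))
  target <- vapply(links$plant_genus, function(g) {
    hits <- which(vg == g)
    if (length(hits) == 1) plants(visit_net)[hits] else g
  }, "")
  w <- visit_net$weights
  all_p <- union(rownames(w), target)
  all_i <- union(colnames(w), links$insect)
  out <- matrix(0, length(all_p), length(all_i), dimnames = list(all_p, all_i))
  out[rownames(w), colnames(w)] <- w
  idx <- cbind(match(target, all_p), match(links$insect, all_i))
  out[idx] <- out[idx] + 1
  bipartite_network(out, period = visit_net$period, provenance = "combined")
}

#' Build a network inferred from pollen loads alone
#'
#' A binary-by-construction network: each (insect, plant genus) pair with
#' grains recovered in the period contributes one link of weight 1.
#'
#' @inheritParams merge_pollen_links
#' @return A `bipartite_network` with provenance `"pollen"`.
#' @export
build_pollen_network <- function(pollen, year = NULL, week = NULL) {
  sel <- rep(TRUE, nrow(pollen))
  if (!is.null(year)) sel <- sel & pollen$year %in% year
  if (!is.null(week)) sel <- sel & pollen$week %in% week
  pollen <- pollen[sel & pollen$grains > 0, , drop = FALSE]
  if (nrow(pollen) == 0) {
    rlang::abort("No pollen records in period.", class = "pollinet_empty_period")
  }
  links <- dplyr::distinct(pollen, .data$insect, .data$plant_genus)
  w <- .edges_to_matrix(links$plant_genus, links$insect, 1)
  label <- paste0(
    if (is.null(year)) "all-years" else paste(year, collapse = "+"),
    if (is.null(week)) "" else sprintf("-w%02d", week[1])
  )
  bipartite_network(w, period = label, provenance = "pollen")
}

# Network series --------------------------------------------------------------

#' Build the series of weekly networks
#'
#' One network per (year, week) with at least one record. Weeks inside a
#' year's observed span that contain no records are skipped and listed in
#' the `skipped` attribute. When pollen records are supplied, each weekly
#' visitation network additionally receives the week's pollen links via
#' [merge_pollen_links()] (provenance `"combined"`).
#'
#' @param records Harmonized `visits` records with `year`/`week` columns.
#' @param pollen Optional harmonized `pollen` records.
#' @return A `network_series`: a list of `bipartite_network`s with a
#'   `keys` attribute (tibble of `year`, `week`, `label`).
#' @export
build_weekly_networks <- function(records, pollen = NULL) {
  keys <- records |>
    dplyr::distinct(.data$year, .data$week) |>
    dplyr::arrange(.data$year, .data$week)
  nets <- vector("list", nrow(keys))
  for (k in seq_len(nrow(keys))) {
    net <- build_network(records, year = keys$year[k], week = keys$week[k])
    net$period <- sprintf("%d-w%02d", keys$year[k], keys$week[k])
    if (!is.null(pollen)) {
      net <- merge_pollen_links(net, pollen, year = keys$year[k], week = keys$week[k])
    }
    nets[[k]] <- net
  }
  # weeks inside each year's span with no records at all
  spans <- records |>
    dplyr::summarise(first = min(.data$week), last = max(.data$week), .by = "year")
  expected <- tidyr::unnest(
    dplyr::mutate(spans, week = purrr::map2(.data$first, .data$last, seq)),
    "week"
  )[c("year", "week")]
  skipped <- dplyr::anti_join(expected, keys, by = c("year", "week"))
  network_series(nets, keys$year, keys$week, skipped = skipped)
}

#' Assemble a network series
#'
#' @param networks List of `bipartite_network`s.
#' @param year,week Integer vectors keying each network.
#' @param skipped Optional tibble of (year, week) periods skipped for
#'   lack of records.
#' @return A `network_series` object ordered chronologically.
#' @export
network_series <- function(networks, year, week, skipped = NULL) {
  year <- rep_len(year, length(networks))
  week <- rep_len(week, length(networks))
  keys <- tibble::tibble(year = as.integer(year), week = as.integer(week))
  if (anyDuplicated(keys)) {
    rlang::abort("Duplicate (year, week) keys in network series.",
                 class = "pollinet_network_error")
  }
  ord <- order(keys$year, keys$week)
  keys <- keys[ord, ]
  keys$label <- sprintf("%d-w%02d", keys$year, keys$week)
  structure(
    stats::setNames(networks[ord], keys$label),
    keys = keys,
    skipped = skipped,
    class = "network_series"
  )
}

#' @export
print.network_series <- function(x, ...) {
  k <- series_keys(x)
  cat(sprintf("<network_series> %d weekly networks, years %s\n",
              length(x), paste(unique(k$year), collapse = ", ")))
  invisible(x)
}

#' Keys of a network series
#' @param series A `network_series`.
#' @return Tibble with `year`, `week`, `label` per network.
#' @export
series_keys <- function(series) attr(series, "keys", exact = TRUE)

#' Subset a network series by year
#' @param series A `network_series`.
#' @param year Year(s) to keep.
#' @return A `network_series`.
#' @export
filter_series <- function(series, year) {
  k <- series_keys(series)
  keep <- k$year %in% year
  network_series(unclass(series)[keep], k$year[keep], k$week[keep],
                 skipped = attr(series, "skipped", exact = TRUE))
}

# Sum two networks over the union of their species (weights add).
add_networks <- function(a, b, period = a$period, provenance = a$provenance) {
  all_p <- union(plants(a), plants(b))
  all_i <- union(insects(a), insects(b))
  w <- matrix(0, length(all_p), length(all_i), dimnames = list(all_p, all_i))
  w[plants(a), insects(a)] <- a$weights
  w[plants(b), insects(b)] <- w[plants(b), insects(b)] + b$weights
  bipartite_network(w, period = period, provenance = provenance)
}

#' Annual network as the sum of a year's weekly networks
#'
#' Annual link sets are the union of the year's weekly link sets and
#' annual visit weights the sum of weekly weights. When weekly networks
#' are combined (visits + pollen), the one-instance-per-link pollen rule
#' is applied per week and the weekly increments then summed, matching
#' the weekly dating of pollen links.
#'
#' @param series A `network_series` of weekly networks.
#' @param year Focal year.
#' @return A `bipartite_network` labelled by the year.
#' @export
build_annual_network <- function(series, year) {
  k <- series_keys(series)
  idx <- which(k$year == year)
  if (length(idx) == 0) {
    rlang::abort(paste0("No weekly networks for year ", year, "."),
                 class = "pollinet_empty_period")
  }
  out <- Reduce(add_networks, unclass(series)[idx])
  out$period <- as.character(year)
  out
}

#' Multi-year metaweb of link persistence
#'
#' The metaweb's weight for a plant x insect link is the number of weekly
#' networks in which the link was observed (its temporal persistence);
#' its binary view is the union of all weekly link sets.
#'
#' @param series A `network_series` of weekly networks.
#' @return A `bipartite_network` with period `"metaweb"`.
#' @export
build_metaweb <- function(series) {
  if (length(series) == 0) {
    rlang::abort("Empty network series.", class = "pollinet_empty_period")
  }
  bin <- lapply(unclass(series), function(net) {
    net$weights <- (net$weights > 0) * 1
    net
  })
  out <- Reduce(add_networks, bin)
  out$period <- "metaweb"
  out$provenance <- bin[[1]]$provenance
  out
}

# Edge-list / incidence IO -----------------------------------------------------

#' Edge-list view of a network
#'
#' @param net A `bipartite_network`.
#' @return Tibble with one row per link: `plant`, `insect`, `weight`.
#' @export
as_edge_list <- function(net) {
  idx <- which(net$weights > 0, arr.ind = TRUE)
  tibble::tibble(
    plant = plants(net)[idx[, 1]],
    insect = insects(net)[idx[, 2]],
    weight = net$weights[idx]
  ) |>
    dplyr::arrange(.data$plant, .data$insect)
}

#' Write / read a network as an edge list
#'
#' Lossless round-trip: species carrying at least one link are fully
#' recoverable from the edge list (networks never contain linkless
#' species).
#'
#' @param net A `bipartite_network`.
#' @param path File path.
#' @param period,provenance Metadata to restore on reading.
#' @return `write_edge_list()` returns `path` invisibly;
#'   `read_edge_list()` a `bipartite_network`.
#' @export
write_edge_list <- function(net, path) {
  readr::write_csv(as_edge_list(net), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path, period = "network", provenance = "visitation") {
  el <- readr::read_csv(path, col_types = "ccd", progress = FALSE,
                        show_col_types = FALSE)
  bipartite_network(.edges_to_matrix(el$plant, el$insect, el$weight),
                    period = period, provenance = provenance)
}

#' Write / read a network as a dense incidence matrix
#'
#' @inheritParams write_edge_list
#' @export
write_incidence <- function(net, path) {
  df <- as.data.frame(net$weights)
  df <- cbind(plant = rownames(net$weights), df)
  readr::write_csv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_incidence
#' @export
read_incidence <- function(path, period = "network", provenance = "visitation") {
  df <- readr::read_csv(path, col_types = readr::cols(
    plant = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE, show_col_types = FALSE)
  w <- as.matrix(df[-1])
  rownames(w) <- df$plant
  bipartite_network(w, period = period, provenance = provenance)
}

#' @export
tidy.bipartite_network <- function(x, ...) as_edge_list(x)
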