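# End-to-end analysis pipeline -------------------------------------------------

#' Configuration of a full pipeline run
#'
#' Exactly one of `scenario` or `input` must be given: either a named
#' synthetic scenario (see [scenario()]) or a list of input file paths
#' (`visits`, `pollen`, `svd`, `taxonomy` — `pollen` and `svd` optional).
#' All randomness in the run flows from the single master `seed` through
#' fixed per-stage substreams, so any stage can be rerun reproducibly.
#'
#' @param scenario_name Synthetic scenario name, or `NULL`.
#' @param input Named list of file paths, or `NULL`.
#' @param seed Master seed for the whole run.
#' @param focal_plant Focal plant for service estimation.
#' @param origin_month_day Season origin (`"MM-DD"`) for week assignment.
#' @param null_R Null-model replicates per test.
#' @param null_metrics Metrics tested against the resampling nulls.
#' @param metric_restarts Modularity restarts for observed networks.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario_name = "baseline", input = NULL,
                            seed = 1, focal_plant = "Dryas",
                            origin_month_day = "06-01",
                            null_R = 200,
                            null_metrics = c("n_links", "connectance_bin",
                                             "nodf_bin"),
                            metric_restarts = 10,
                            out_dir = NULL) {
  if (is.null(scenario_name) == is.null(input)) {
    rlang::abort("Exactly one of scenario_name / input must be set.",
                 class = "pollinet_config_error")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis
#'
#' Orchestrates every stage: data acquisition (synthetic generation or
#' file reading), taxonomy harmonization and week assignment, weekly /
#' annual / metaweb network construction (plus pollen-transport and
#' combined networks when pollen data exist), structural metrics,
#' metaweb-resampling null tests (annual networks vs the metaweb, weekly
#' networks vs their annual network), cross-method metric correlations,
#' pollination-service and pollen-transport estimation with the
#' associated regressions, and a run manifest with seeds and row counts.
#' When `out_dir` is set, all tables are written as CSV, networks as edge
#' lists, and the manifest and regression summaries as JSON; reruns with
#' the same config produce byte-identical files.
#'
#' @param config A `pipeline_config`.
#' @return A named list with all stage outputs (`data`, `networks`,
#'   `metrics`, `nulls`, `correlations`, `service`, `regressions`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  # -- stage 1: data -----------------------------------------------------
  if (!is.null(config$scenario_name)) {
    sim <- simulate_community(scenario(config$scenario_name, seed = seed))
    visits <- sim$visits; pollen <- sim$pollen; svd_obs <- sim$svd
    taxonomy <- sim$taxonomy; taxa <- sim$taxa
  } else {
    visits <- read_records(config$input$visits, "visits")
    pollen <- if (!is.null(config$input$pollen))
      read_records(config$input$pollen, "pollen") else NULL
    svd_obs <- if (!is.null(config$input$svd))
      read_records(config$input$svd, "svd") else NULL
    taxonomy <- read_records(config$input$taxonomy, "taxonomy")
    taxa <- NULL
    sim <- NULL
  }
  visits <- add_season_weeks(visits, config$origin_month_day)
  visits <- harmonize(visits, taxonomy)
  if (!is.null(pollen) && nrow(pollen) > 0) {
    pollen <- add_season_weeks(pollen, config$origin_month_day)
    pollen <- harmonize(pollen, taxonomy)
  }
  if (is.null(taxa)) {
    # derive genus (first name component) and family from the taxonomy map
    ins <- sort(unique(visits$insect))
    fam <- taxonomy$family[match(ins, taxonomy$canonical)]
    taxa <- tibble::tibble(
      taxon = ins,
      genus = vapply(strsplit(ins, "[ _]"), `[[`, "", 1),
      family = fam
    )
  }

  # -- stage 2: networks -------------------------------------------------
  weekly <- build_weekly_networks(visits)
  years <- sort(unique(series_keys(weekly)$year))
  annuals <- stats::setNames(
    lapply(years, function(y) build_annual_network(weekly, y)),
    years
  )
  metaweb <- build_metaweb(weekly)
  pollen_nets <- NULL
  combined <- NULL
  if (!is.null(pollen) && nrow(pollen) > 0) {
    py <- sort(unique(pollen$year))
    pk <- dplyr::distinct(pollen[pollen$grains > 0, ], .data$year, .data$week) |>
      dplyr::arrange(.data$year, .data$week)
    pollen_nets <- network_series(
      purrr::map2(pk$year, pk$week,
                  function(y, w) build_pollen_network(pollen, y, w)),
      pk$year, pk$week
    )
    combined <- build_weekly_networks(
      visits[visits$year %in% py, , drop = FALSE], pollen
    )
  }

  # -- stage 3: metrics --------------------------------------------------
  weekly_metrics <- series_metrics(weekly, mode = "full",
                                   restarts = config$metric_restarts,
                                   seed = seed + 1000)
  annual_metrics <- dplyr::bind_rows(lapply(seq_along(annuals), function(i) {
    metric_set(annuals[[i]], mode = "full",
               restarts = config$metric_restarts, seed = seed + 2000 + i)
  }))
  metaweb_metrics <- metric_set(metaweb, mode = "full",
                                restarts = config$metric_restarts,
                                seed = seed + 3000)
  pollen_metrics <- if (!is.null(pollen_nets)) {
    series_metrics(pollen_nets, mode = "binary_only",
                   restarts = config$metric_restarts, seed = seed + 4000)
  }
  combined_metrics <- if (!is.null(combined)) {
    series_metrics(combined, mode = "full",
                   restarts = config$metric_restarts, seed = seed + 5000)
  }

  # -- stage 4: null models ----------------------------------------------
  annual_nulls <- dplyr::bind_rows(lapply(seq_along(annuals), function(i) {
    dplyr::mutate(
      null_test(annuals[[i]], metaweb, metrics = config$null_metrics,
                R = config$null_R, seed = seed + 6000 + i),
      year = years[i], .before = 1
    )
  }))
  weekly_nulls <- weekly_vs_annual(weekly, annuals,
                                   metrics = config$null_metrics,
                                   R = config$null_R, seed = seed + 7000)

  # -- stage 5: correlations ---------------------------------------------
  correlations <- NULL
  if (!is.null(pollen_metrics)) {
    corr_metrics <- intersect(
      c("n_plants", "n_insects", "n_links", "connectance_bin", "nodf_bin",
        "modularity_q"),
      names(pollen_metrics)
    )
    correlations <- dplyr::bind_rows(lapply(corr_metrics, function(mname) {
      tryCatch(
        correlate_metrics(weekly_metrics, pollen_metrics, mname),
        pollinet_correlation_error = function(e) NULL
      )
    }))
  }

  # -- stage 6: pollination service --------------------------------------
  service <- NULL; regressions <- list(); transport <- NULL
  if (!is.null(svd_obs) && nrow(svd_obs) > 0) {
    svd <- svd_table(svd_obs)
    service <- suppressWarnings(
      estimate_service(weekly, svd, config$focal_plant, taxa)
    )
    sa <- service_annual(service)
    activity <- activity_periods(visits)
    regressions$service_vs_activity <-
      service_vs_activity(sa, activity)$final
    if (!is.null(pollen) && nrow(pollen) > 0) {
      transport <- estimate_transport(pollen)
      body <- pollen |>
        dplyr::summarise(total = sum(.data$grains), .by = "individual") |>
        dplyr::inner_join(
          dplyr::distinct(pollen, .data$individual, .data$insect),
          by = "individual"
        ) |>
        dplyr::inner_join(taxa, by = c(insect = "taxon")) |>
        dplyr::summarise(mean_body_load = mean(.data$total), .by = "genus")
      gvis <- sa |>
        dplyr::inner_join(taxa, by = c(insect_taxon = "taxon")) |>
        dplyr::summarise(visits = sum(.data$visits), .by = c("genus", "year")) |>
        dplyr::summarise(mean_annual_visits = mean(.data$visits), .by = "genus")
      gdat <- svd$genus |>
        dplyr::inner_join(body, by = "genus") |>
        dplyr::inner_join(gvis, by = "genus")
      regressions$svd_vs_body_load <- tryCatch(
        glance(fit_line(gdat$mean_body_load, gdat$mean)),
        pollinet_lm_error = function(e) NULL
      )
      regressions$svd_vs_visits <- tryCatch(
        glance(fit_line(gdat$mean_annual_visits, gdat$mean)),
        pollinet_lm_error = function(e) NULL
      )
    }
  }

  # -- manifest ----------------------------------------------------------
  manifest <- list(
    seed = seed,
    scenario = config$scenario_name,
    focal_plant = config$focal_plant,
    null_R = config$null_R,
    n_visit_records = nrow(visits),
    n_pollen_records = if (is.null(pollen)) 0L else nrow(pollen),
    n_svd_rows = if (is.null(svd_obs)) 0L else nrow(svd_obs),
    n_weekly_networks = length(weekly),
    n_years = length(years),
    skipped_weeks = {
      sk <- attr(weekly, "skipped", exact = TRUE)
      if (is.null(sk)) 0L else nrow(sk)
    },
    total_visits = sum(visits$count)
  )

  out <- list(
    data = list(visits = visits, pollen = pollen, svd = svd_obs,
                taxa = taxa, sim = sim),
    networks = list(weekly = weekly, annuals = annuals, metaweb = metaweb,
                    pollen = pollen_nets, combined = combined),
    metrics = list(weekly = weekly_metrics, annual = annual_metrics,
                   metaweb = metaweb_metrics, pollen = pollen_metrics,
                   combined = combined_metrics),
    nulls = list(annual_vs_metaweb = annual_nulls,
                 weekly_vs_annual = weekly_nulls),
    correlations = correlations,
    service = if (!is.null(service)) {
      list(weekly = service, annual = service_annual(service),
           total = service_total(service), transport = transport)
    },
    regressions = regressions,
    manifest = manifest
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

#' Write pipeline outputs to a directory
#'
#' @param result The list returned by [run_pipeline()].
#' @param out_dir Directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name) {
    if (!is.null(x)) readr::write_csv(x, file.path(out_dir, name), progress = FALSE)
  }
  wcsv(result$metrics$weekly, "metrics_weekly.csv")
  wcsv(result$metrics$annual, "metrics_annual.csv")
  wcsv(result$metrics$metaweb, "metrics_metaweb.csv")
  wcsv(result$metrics$pollen, "metrics_pollen.csv")
  wcsv(result$metrics$combined, "metrics_combined.csv")
  wcsv(result$nulls$annual_vs_metaweb, "nulls_annual_vs_metaweb.csv")
  wcsv(result$nulls$weekly_vs_annual, "nulls_weekly_vs_annual.csv")
  wcsv(result$correlations, "correlations.csv")
  if (!is.null(result$service)) {
    wcsv(result$service$weekly, "service_weekly.csv")
    wcsv(result$service$annual, "service_annual.csv")
    wcsv(result$service$total, "service_total.csv")
    wcsv(result$service$transport, "transport.csv")
  }
  write_edge_list(result$networks$metaweb, file.path(out_dir, "metaweb_edges.csv"))
  for (y in names(result$networks$annuals)) {
    write_edge_list(result$networks$annuals[[y]],
                    file.path(out_dir, paste0("annual_", y, "_edges.csv")))
  }
  jsonlite::write_json(
    result$regressions, file.path(out_dir, "regressions.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "columns"
  )
  jsonlite::write_json(
    result$manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}
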