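# Synthetic phenology-structured community ------------------------------------
#
# The generator emulates the statistical shape of a high-Arctic
# plant-pollinator season: a short (~13-week) snow-free season, species
# whose activity windows cluster midseason, one super-generalist plant
# (the focal "Dryas"-like taxon) attracting almost all visits, pollinator
# contributions dominated by a few abundant long-flying taxa,
# overdispersed pollen loads, and near-clean control stigmas. It emits
# tables in the exact schemas read by read_records(), plus the ground
# truth needed to score parameter recovery.

#' Configuration of a synthetic community
#'
#' All rates and sizes of the generator, with defaults chosen to mimic a
#' multi-year Arctic monitoring campaign. The same config and seed always
#' yield bit-identical tables.
#'
#' @param seed Integer master seed.
#' @param n_years Number of seasons (consecutive years).
#' @param weeks_per_season Season length in 7-day bins (weeks `0 ..
#'   weeks_per_season - 1` from the June 1 origin).
#' @param n_plants,n_insects Community sizes. Plant 1 is the dominant
#'   focal plant (`"Dryas"`), flowering all season.
#' @param dominant_share Expected share of all visits received by the
#'   dominant plant (must be in (0, 1)).
#' @param center_sd SD (weeks) of species' activity-window centers around
#'   midseason.
#' @param width_meanlog,width_sdlog Log-normal parameters of
#'   activity-window widths (weeks).
#' @param abundance_sdlog Log-normal SD of insect abundances.
#' @param width_abundance_cor Correlation between an insect's (log)
#'   window width and (log) abundance; positive values make a few
#'   long-flying taxa dominate visitation.
#' @param visit_rate Expected visits per active insect per week at unit
#'   abundance.
#' @param year_effect_sd Log-normal SD of multiplicative year-to-year
#'   rate variation (0 switches year effects off).
#' @param diet_breadth `NULL` for unrestricted generalists, or a function
#'   of the absolute distance (weeks) between an insect's window center
#'   and midseason returning the number of non-dominant plants in its
#'   diet (used by the `midseason_specialists` scenario).
#' @param n_genera Number of insect genera; taxa are assigned
#'   round-robin. Genera are assigned to `families`.
#' @param families Character vector of family names.
#' @param svd_mean_range Range of true per-genus single-visit deposition
#'   means (grains per visit).
#' @param n_svd Single-visit deposition trials per genus.
#' @param svd_size Negative-binomial size (overdispersion) of trial
#'   counts.
#' @param n_family_only_svd Additional family-only trial rows per family
#'   (visitors unresolved below family), exercising the family fallback.
#' @param n_controls Control (unvisited) flowers scored for
#'   contamination.
#' @param control_zero_prob,control_size,control_mu Zero-inflated
#'   negative-binomial contamination model for control flowers; the
#'   defaults target a low-contamination summary (median ~2, mean ~19,
#'   SD ~45) typical of virgin-stigma controls.
#' @param capture_rate Expected captured individuals per active insect
#'   taxon per week at unit abundance (pollen washing, final year only).
#' @param load_mu Scale (grains) of body pollen loads.
#' @param load_size Negative-binomial size of body loads (small values =
#'   strongly overdispersed).
#' @param first_year First calendar year of the study.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             n_years = 5,
                             weeks_per_season = 13,
                             n_plants = 20,
                             n_insects = 65,
                             dominant_share = 0.97,
                             center_sd = 2,
                             width_meanlog = log(5),
                             width_sdlog = 0.35,
                             abundance_sdlog = 1,
                             width_abundance_cor = 0.6,
                             visit_rate = 2,
                             year_effect_sd = 0.2,
                             diet_breadth = NULL,
                             n_genera = 18,
                             families = c("Muscidae", "Empididae", "Chironomidae",
                                          "Culicidae", "Syrphidae", "Nymphalidae"),
                             svd_mean_range = c(10, 300),
                             n_svd = 40,
                             svd_size = 2,
                             n_family_only_svd = 4,
                             n_controls = 9,
                             control_zero_prob = 0.2,
                             control_size = 0.25,
                             control_mu = 23.75,
                             capture_rate = 1.5,
                             load_mu = 150,
                             load_size = 0.6,
                             first_year = 2012) {
  cfg <- as.list(environment())
  if (!(dominant_share > 0 && dominant_share < 1)) {
    rlang::abort("dominant_share must lie strictly in (0, 1).",
                 class = "pollinet_config_error")
  }
  counts <- c(n_years = n_years, weeks_per_season = weeks_per_season,
              n_plants = n_plants, n_insects = n_insects, n_genera = n_genera,
              n_svd = n_svd, n_controls = n_controls)
  if (any(counts < 1)) {
    rlang::abort(paste0("Counts must be positive: ",
                        paste(names(counts)[counts < 1], collapse = ", ")),
                 class = "pollinet_config_error")
  }
  if (n_plants < 2) {
    rlang::abort("Need at least 2 plants (one dominant, one other).",
                 class = "pollinet_config_error")
  }
  if (!is.null(diet_breadth) && !is.function(diet_breadth)) {
    rlang::abort("diet_breadth must be NULL or a function.",
                 class = "pollinet_config_error")
  }
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> seed %d: %d years x %d weeks, %d plants, %d insects, dominant share %.2f\n",
    x$seed, x$n_years, x$weeks_per_season, x$n_plants, x$n_insects,
    x$dominant_share
  ))
  invisible(x)
}

#' Named scenario presets
#'
#' Documented configurations used throughout the test-suite and
#' calibration studies:
#' \describe{
#'   \item{baseline}{The defaults of [synthetic_config()].}
#'   \item{no_year_effect}{Baseline with `year_effect_sd = 0`; annual
#'     deposition then depends on activity period only, so the stepwise
#'     model simplification should drop the year terms.}
#'   \item{strong_activity_effect}{A small, fully SVD-covered community
#'     (8 taxa, 6 plants, one genus per taxon) whose abundances are
#'     strongly tied to window width, producing a steep positive
#'     relationship between activity period and annual deposition
#'     (40 taxon-years over 5 years).}
#'   \item{midseason_specialists}{Insects whose windows center midseason
#'     have narrow diets (few non-dominant host plants), while shoulder
#'     species are broad generalists — reproducing the field pattern of
#'     midseason richness peaks coinciding with the lowest weekly
#'     connectance.}
#' }
#'
#' @param name Scenario name.
#' @param seed Master seed to embed in the config.
#' @return A `synthetic_config`.
#' @export
scenario <- function(name = c("baseline", "no_year_effect",
                              "strong_activity_effect",
                              "midseason_specialists"),
                     seed = 1) {
  name <- rlang::arg_match(name)
  switch(
    name,
    baseline = synthetic_config(seed = seed),
    no_year_effect = synthetic_config(seed = seed, year_effect_sd = 0),
    strong_activity_effect = synthetic_config(
      seed = seed, n_plants = 6, n_insects = 8, n_genera = 8,
      width_meanlog = log(6), width_sdlog = 0.6,
      width_abundance_cor = 0.9, abundance_sdlog = 0.8,
      visit_rate = 8, year_effect_sd = 0,
      svd_mean_range = c(80, 120)
    ),
    midseason_specialists = synthetic_config(
      seed = seed,
      diet_breadth = function(dist) pmax(1, round(1 + 3 * dist))
    )
  )
}

# window helper: integer week span of an activity window, clipped to season
.window_weeks <- function(center, width, n_weeks) {
  first <- pmax(0, round(center - width / 2))
  last <- pmin(n_weeks - 1, round(center + width / 2))
  first <- pmin(first, n_weeks - 1)
  last <- pmax(last, 0)
  list(first = pmin(first, last), last = pmax(first, last))
}

#' Generate a synthetic community data set
#'
#' Draws species traits (activity windows, abundances, attractiveness,
#' diets, true deposition means) once, then simulates every season:
#' weekly visit counts are Poisson with rates proportional to insect
#' abundance and plant attractiveness among the week's active species,
#' with the dominant plant receiving a fixed expected share of each
#' insect's visits; body pollen loads (final year only, mirroring a
#' single pollen-washing campaign) are negative-binomial; single-visit
#' deposition trials are negative-binomial around the true genus means;
#' control flowers follow a zero-inflated contamination model.
#'
#' @param config A `synthetic_config`.
#' @return A list with elements `visits`, `pollen`, `svd` (record tables
#'   in the [read_records()] schemas), `taxonomy` (a self-mapping
#'   taxonomy table over all names), `taxa` (insect taxon to genus and
#'   family), and `truth` (ground truth: `windows`, `svd_mu`,
#'   `family_mu`, `expected_focal_visits`, `expected_deposition`,
#'   `dominant_share`, `pollen_year`).
#' @export
simulate_community <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, .simulate_impl(config))
}

.simulate_impl <- function(cfg) {
  W <- cfg$weeks_per_season
  mid <- (W - 1) / 2
  years <- seq(cfg$first_year, length.out = cfg$n_years)

  plant_names <- c("Dryas", sprintf("Plantgen%02d", seq_len(cfg$n_plants - 1) + 1))
  genus_names <- sprintf("Insgen%02d", seq_len(cfg$n_genera))
  genus_of_taxon <- rep(genus_names, length.out = cfg$n_insects)
  within_idx <- stats::ave(seq_len(cfg$n_insects), genus_of_taxon, FUN = seq_along)
  insect_names <- paste0(genus_of_taxon, " sp", within_idx)
  family_of_genus <- stats::setNames(
    rep(cfg$families, length.out = cfg$n_genera), genus_names)
  taxa <- tibble::tibble(
    taxon = insect_names,
    genus = genus_of_taxon,
    family = unname(family_of_genus[genus_of_taxon])
  )

  # --- species traits ---------------------------------------------------
  # plants: dominant flowers all season; others have midseason windows
  p_center <- c(mid, stats::rnorm(cfg$n_plants - 1, mid, cfg$center_sd))
  p_width <- c(W, stats::rlnorm(cfg$n_plants - 1, cfg$width_meanlog, cfg$width_sdlog))
  pw <- .window_weeks(p_center, p_width, W)
  pw$first[1] <- 0; pw$last[1] <- W - 1
  attractiveness <- c(NA, stats::rlnorm(cfg$n_plants - 1, 0, 0.8))

  # insects: window width and abundance share a latent factor
  z <- stats::rnorm(cfg$n_insects)
  e <- stats::rnorm(cfg$n_insects)
  rho <- cfg$width_abundance_cor
  i_width <- exp(cfg$width_meanlog +
                   cfg$width_sdlog * (rho * z + sqrt(1 - rho^2) * e))
  abundance <- exp(cfg$abundance_sdlog * z)
  i_center <- stats::rnorm(cfg$n_insects, mid, cfg$center_sd)
  iw <- .window_weeks(i_center, i_width, W)

  # diets: dominant plant always included; optional midseason narrowing
  diets <- lapply(seq_len(cfg$n_insects), function(i) {
    if (is.null(cfg$diet_breadth)) return(seq_len(cfg$n_plants)[-1])
    k <- min(cfg$n_plants - 1, cfg$diet_breadth(abs(i_center[i] - mid)))
    sort(sample(seq_len(cfg$n_plants)[-1], k))
  })

  year_factor <- if (cfg$year_effect_sd > 0) {
    exp(stats::rnorm(cfg$n_years, 0, cfg$year_effect_sd) - cfg$year_effect_sd^2 / 2)
  } else rep(1, cfg$n_years)

  true_svd_mu <- stats::setNames(
    stats::runif(cfg$n_genera, cfg$svd_mean_range[1], cfg$svd_mean_range[2]),
    genus_names
  )
  family_mu <- tapply(true_svd_mu, family_of_genus, mean)

  # --- weekly visitation ------------------------------------------------
  visit_rows <- list()
  lambda_focal <- list()
  rowi <- 0L
  for (y in seq_len(cfg$n_years)) {
    origin <- as.Date(sprintf("%d-06-01", years[y]))
    for (w in seq_len(W) - 1L) {
      active_i <- which(iw$first <= w & w <= iw$last)
      if (length(active_i) == 0) next
      active_p <- which(pw$first <= w & w <= pw$last)
      for (i in active_i) {
        lam_total <- cfg$visit_rate * abundance[i] * year_factor[y]
        others <- intersect(intersect(active_p, diets[[i]]), seq_len(cfg$n_plants)[-1])
        if (length(others) > 0) {
          lam_dom <- cfg$dominant_share * lam_total
          a <- attractiveness[others]
          lam_oth <- (1 - cfg$dominant_share) * lam_total * a / sum(a)
          lam <- c(lam_dom, lam_oth)
          pl <- c(1L, others)
        } else {
          lam <- lam_total
          pl <- 1L
        }
        counts <- stats::rpois(length(lam), lam)
        keep <- counts > 0
        rowi <- rowi + 1L
        lambda_focal[[rowi]] <- tibble::tibble(
          insect = insect_names[i], year = years[y], week = w, lambda = lam[1]
        )
        if (any(keep)) {
          visit_rows[[rowi]] <- tibble::tibble(
            plant = plant_names[pl[keep]],
            insect = insect_names[i],
            date = origin + 7L * w + 3L,
            count = counts[keep]
          )
        }
      }
    }
  }
  visits <- dplyr::bind_rows(visit_rows) |>
    dplyr::arrange(.data$date, .data$plant, .data$insect)
  visits$count <- as.integer(visits$count)
  visits <- .set_schema(visits, "visits")
  lambda_focal <- dplyr::bind_rows(lambda_focal)

  # --- pollen loads, final year ----------------------------------------
  pollen_year <- years[cfg$n_years]
  origin <- as.Date(sprintf("%d-06-01", pollen_year))
  yf <- year_factor[cfg$n_years]
  pollen_rows <- list()
  ind_counter <- 0L
  for (w in seq_len(W) - 1L) {
    active_i <- which(iw$first <= w & w <= iw$last)
    active_p <- which(pw$first <= w & w <= pw$last)
    for (i in active_i) {
      n_ind <- stats::rpois(1, cfg$capture_rate * abundance[i] * yf)
      if (n_ind == 0) next
      others <- intersect(intersect(active_p, diets[[i]]), seq_len(cfg$n_plants)[-1])
      pl <- c(1L, others)
      share <- if (length(others) > 0) {
        a <- attractiveness[others]
        c(cfg$dominant_share, (1 - cfg$dominant_share) * a / sum(a))
      } else 1
      mu <- cfg$load_mu * sqrt(share)
      for (k in seq_len(n_ind)) {
        ind_counter <- ind_counter + 1L
        grains <- stats::rnbinom(length(pl), size = cfg$load_size, mu = mu)
        keep <- grains > 0
        if (!any(keep)) next
        pollen_rows[[length(pollen_rows) + 1L]] <- tibble::tibble(
          individual = sprintf("ind%05d", ind_counter),
          insect = insect_names[i],
          date = origin + 7L * w + 3L,
          plant_genus = plant_names[pl[keep]],
          grains = as.integer(grains[keep])
        )
      }
    }
  }
  pollen <- dplyr::bind_rows(pollen_rows)
  pollen <- .set_schema(pollen, "pollen")

  # --- single-visit deposition trials ----------------------------------
  svd_trials <- tidyr::expand_grid(genus = genus_names,
                                   rep = seq_len(cfg$n_svd)) |>
    dplyr::mutate(
      family = unname(family_of_genus[.data$genus]),
      grains = as.integer(stats::rnbinom(dplyr::n(), size = cfg$svd_size,
                                         mu = true_svd_mu[.data$genus])),
      is_control = FALSE
    ) |>
    dplyr::select("genus", "family", "grains", "is_control")
  fam_only <- tidyr::expand_grid(family = unique(unname(family_of_genus)),
                                 rep = seq_len(cfg$n_family_only_svd)) |>
    dplyr::mutate(
      genus = NA_character_,
      grains = as.integer(stats::rnbinom(dplyr::n(), size = cfg$svd_size,
                                         mu = family_mu[.data$family])),
      is_control = FALSE
    ) |>
    dplyr::select("genus", "family", "grains", "is_control")
  controls <- tibble::tibble(
    genus = NA_character_, family = NA_character_,
    grains = as.integer(
      ifelse(stats::runif(cfg$n_controls) < cfg$control_zero_prob, 0L,
             stats::rnbinom(cfg$n_controls, size = cfg$control_size,
                            mu = cfg$control_mu))
    ),
    is_control = TRUE
  )
  svd <- .set_schema(dplyr::bind_rows(svd_trials, fam_only, controls), "svd")

  # --- taxonomy (already canonical: self-mapping) -----------------------
  taxonomy <- taxonomy_map(
    raw = c(plant_names, insect_names),
    canonical = c(plant_names, insect_names),
    rank = c(rep("genus", length(plant_names)),
             rep("species", length(insect_names))),
    family = c(rep(NA_character_, length(plant_names)), taxa$family)
  )

  truth <- list(
    windows = dplyr::bind_rows(
      tibble::tibble(taxon = plant_names, side = "plant",
                     center = p_center, width = p_width,
                     first_week = pw$first, last_week = pw$last),
      tibble::tibble(taxon = insect_names, side = "insect",
                     center = i_center, width = i_width,
                     first_week = iw$first, last_week = iw$last,
                     abundance = abundance)
    ),
    svd_mu = tibble::tibble(genus = genus_names, mu = unname(true_svd_mu)),
    family_mu = tibble::tibble(family = names(family_mu), mu = unname(family_mu)),
    expected_focal_visits = lambda_focal,
    expected_deposition = sum(lambda_focal$lambda *
                                true_svd_mu[taxa$genus[match(lambda_focal$insect,
                                                             taxa$taxon)]]),
    dominant_share = cfg$dominant_share,
    pollen_year = pollen_year
  )

  list(visits = visits, pollen = pollen, svd = svd, taxonomy = taxonomy,
       taxa = taxa, truth = truth, config = cfg)
}
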