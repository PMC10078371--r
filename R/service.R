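# Pollination-service estimation ----------------------------------------------
#
# Visits tell how often an insect taxon arrives at a flower; single-visit
# deposition (SVD) trials tell how many conspecific grains one visit
# leaves on a virgin stigma. Their product, summed over taxa and weeks,
# estimates total pollination service delivered to the focal plant.

#' Summarize single-visit deposition trials
#'
#' Computes per-genus mean deposition (over genus-resolved trial rows),
#' per-family mean deposition (over all trial rows of the family,
#' including genus-resolved ones, so the family mean is the best
#' available estimate when a visitor is only resolved to family), and
#' the control summary over unvisited flowers. Control deposition is
#' reported alongside the means but never subtracted from them.
#'
#' @param obs An `svd` record table (see [read_records()]).
#' @return An object of class `svd_table`: list of tibbles `genus`
#'   (`genus`, `family`, `n`, `mean`, `sd`), `family` (`family`, `n`,
#'   `mean`, `sd`), and `control` (`n`, `mean`, `median`, `sd`).
#' @export
svd_table <- function(obs) {
  trials <- obs[!obs$is_control, , drop = FALSE]
  controls <- obs[obs$is_control, , drop = FALSE]
  if (nrow(trials) == 0) {
    rlang::abort("No non-control single-visit deposition observations.",
                 class = "pollinet_svd_error")
  }
  genus <- trials |>
    dplyr::filter(!is.na(.data$genus)) |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(.data$grains), sd = stats::sd(.data$grains),
      .by = c("genus", "family")
    )
  family <- trials |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(.data$grains), sd = stats::sd(.data$grains),
      .by = "family"
    )
  control <- tibble::tibble(
    n = nrow(controls),
    mean = if (nrow(controls)) mean(controls$grains) else NA_real_,
    median = if (nrow(controls)) stats::median(controls$grains) else NA_real_,
    sd = if (nrow(controls) > 1) stats::sd(controls$grains) else NA_real_
  )
  structure(list(genus = genus, family = family, control = control),
            class = "svd_table")
}

#' @export
print.svd_table <- function(x, ...) {
  cat(sprintf("<svd_table> %d genera, %d families; control: n=%d, mean=%.3g, median=%.3g\n",
              nrow(x$genus), nrow(x$family), x$control$n, x$control$mean,
              x$control$median))
  invisible(x)
}

#' @export
tidy.svd_table <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$genus, level = "genus", .before = 1),
    dplyr::mutate(dplyr::rename(x$family, genus = "family"), level = "family",
                  .before = 1)
  )
}

# SVD mean for one insect taxon: genus level preferred, family fallback.
.svd_lookup <- function(genus, family, svd) {
  gi <- match(genus, svd$genus$genus)
  if (!is.na(gi)) {
    return(list(mean = svd$genus$mean[gi], level = "genus"))
  }
  fi <- match(family, svd$family$family)
  if (!is.na(fi)) {
    return(list(mean = svd$family$mean[fi], level = "family"))
  }
  list(mean = NA_real_, level = NA_character_)
}

#' Estimate pollination service to a focal plant
#'
#' Multiplies the number of visits each insect taxon made to the focal
#' plant per week (weights of the weekly visitation networks) by the
#' taxon's mean single-visit deposition — genus-level mean where
#' available, family-level mean otherwise. Taxa with neither estimate
#' are excluded with a warning. Annual and community totals are sums of
#' the weekly estimates.
#'
#' @param nets A `network_series` of weekly visitation networks.
#' @param svd An `svd_table`.
#' @param focal_plant Name of the focal plant as it appears in the
#'   networks.
#' @param taxa A tibble mapping insect taxa to `genus` and `family`
#'   (columns `taxon`, `genus`, `family`).
#' @return A tibble of weekly estimates: `insect_taxon`, `year`, `week`,
#'   `visits`, `svd_mean`, `svd_level`, `estimated_grains`. Taxa dropped
#'   for lack of any SVD estimate are listed in the `excluded_taxa`
#'   attribute.
#' @export
estimate_service <- function(nets, svd, focal_plant, taxa) {
  k <- series_keys(nets)
  rows <- purrr::map(seq_len(nrow(k)), function(i) {
    net <- nets[[k$label[i]]]
    if (!focal_plant %in% plants(net)) return(NULL)
    v <- net$weights[focal_plant, ]
    v <- v[v > 0]
    if (length(v) == 0) return(NULL)
    tibble::tibble(insect_taxon = names(v), year = k$year[i], week = k$week[i],
                   visits = as.numeric(v))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    rlang::abort(paste0("Focal plant '", focal_plant,
                        "' absent from every network."),
                 class = "pollinet_service_error")
  }
  idx <- match(out$insect_taxon, taxa$taxon)
  lk <- purrr::map2(taxa$genus[idx], taxa$family[idx], .svd_lookup, svd = svd)
  out$svd_mean <- purrr::map_dbl(lk, "mean")
  out$svd_level <- purrr::map_chr(lk, "level")
  dropped <- sort(unique(out$insect_taxon[is.na(out$svd_mean)]))
  if (length(dropped) > 0) {
    rlang::warn(paste0("No SVD estimate at genus or family level for: ",
                       paste(dropped, collapse = ", "), "; excluded."))
  }
  out <- out[!is.na(out$svd_mean), , drop = FALSE]
  out$estimated_grains <- out$visits * out$svd_mean
  attr(out, "excluded_taxa") <- dropped
  out
}

#' Annual and community totals of service estimates
#'
#' @param service Weekly estimates from [estimate_service()].
#' @return `service_annual()`: one row per insect taxon x year with
#'   summed visits and grains. `service_total()`: one row per year with
#'   the community-total deposition.
#' @export
service_annual <- function(service) {
  service |>
    dplyr::summarise(
      visits = sum(.data$visits),
      estimated_grains = sum(.data$estimated_grains),
      svd_level = .data$svd_level[1],
      .by = c("insect_taxon", "year")
    )
}

#' @rdname service_annual
#' @export
service_total <- function(service) {
  service |>
    dplyr::summarise(estimated_grains = sum(.data$estimated_grains),
                     .by = "year") |>
    dplyr::arrange(.data$year)
}

#' Activity periods of insect taxa
#'
#' A taxon's activity (flight) period is the average, over the years in
#' which it was observed at all, of the number of distinct season-weeks
#' with an observation — robust to missing the exact start or end of
#' flight in any one year.
#'
#' @param records A harmonized `visits` record table with `year`/`week`.
#' @return A tibble: `insect_taxon`, `activity_weeks` (>= 1 for any
#'   observed taxon), `n_years`.
#' @export
activity_periods <- function(records) {
  records |>
    dplyr::summarise(weeks = dplyr::n_distinct(.data$week),
                     .by = c("insect", "year")) |>
    dplyr::summarise(activity_weeks = mean(.data$weeks),
                     n_years = dplyr::n(), .by = "insect") |>
    dplyr::rename(insect_taxon = "insect")
}

#' Estimate pollen transport from body loads
#'
#' Per insect taxon, plant and week: the mean pollen load over all of
#' the taxon's individuals captured that week (individuals carrying no
#' pollen of the plant count as zeros), and the estimated total removed,
#' `mean_load x n_individuals` — i.e. the grain total scaled to the
#' captured sample. The per-individual scaling is a documented choice
#' recorded in the `scaling` attribute.
#'
#' @param pollen A harmonized `pollen` record table with `year`/`week`.
#' @return A tibble: `insect_taxon`, `plant`, `year`, `week`,
#'   `mean_load`, `n_individuals`, `estimated_removed`.
#' @export
estimate_transport <- function(pollen) {
  if (nrow(pollen) == 0) {
    rlang::abort("No pollen records.", class = "pollinet_service_error")
  }
  caught <- pollen |>
    dplyr::summarise(n_individuals = dplyr::n_distinct(.data$individual),
                     .by = c("insect", "year", "week"))
  out <- pollen |>
    dplyr::summarise(total_grains = sum(.data$grains),
                     .by = c("insect", "year", "week", "plant_genus")) |>
    dplyr::inner_join(caught, by = c("insect", "year", "week")) |>
    dplyr::mutate(
      mean_load = .data$total_grains / .data$n_individuals,
      estimated_removed = .data$mean_load * .data$n_individuals
    ) |>
    dplyr::select(insect_taxon = "insect", plant = "plant_genus",
                  "year", "week", "mean_load", "n_individuals",
                  "estimated_removed")
  attr(out, "scaling") <- "per_individual"
  out
}

# Simple linear regression -----------------------------------------------------

#' Ordinary least-squares line fit
#'
#' Wraps a straight-line `lm()` fit, reporting the slope, intercept,
#' multiple and adjusted R-squared, and the two-sided slope p-value from
#' a t statistic on n - 2 degrees of freedom. Both R-squared variants
#' are reported because an adjusted value can be negative while the
#' multiple one cannot.
#'
#' @param x,y Numeric vectors of equal length, n >= 3; `x` must vary.
#' @return An object of class `pollinet_lm` (the underlying `lm` fit is
#'   in `$model`). Use [tidy()]/[glance()] for tabular views.
#' @export
fit_line <- function(x, y) {
  if (length(x) != length(y)) {
    rlang::abort("x and y lengths differ.", class = "pollinet_lm_error")
  }
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    rlang::abort("Need at least 3 complete observations.",
                 class = "pollinet_lm_error")
  }
  if (stats::sd(x) == 0) {
    rlang::abort("x has zero variance.", class = "pollinet_lm_error")
  }
  if (stats::sd(y) == 0) {
    # a flat response: slope and explained variance are exactly zero
    return(structure(
      list(model = stats::lm(y ~ x), slope = 0, intercept = y[1],
           r_squared = 0, adj_r_squared = 0, p_value = NA_real_,
           n = length(x)),
      class = "pollinet_lm"
    ))
  }
  fit <- stats::lm(y ~ x)
  s <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
  co <- s$coefficients
  slope_p <- if (nrow(co) >= 2) co["x", "Pr(>|t|)"] else NA_real_
  structure(
    list(
      model = fit,
      slope = unname(stats::coef(fit)["x"]),
      intercept = unname(stats::coef(fit)["(Intercept)"]),
      r_squared = s$r.squared,
      adj_r_squared = s$adj.r.squared,
      p_value = unname(slope_p),
      n = length(x)
    ),
    class = "pollinet_lm"
  )
}

#' @export
print.pollinet_lm <- function(x, ...) {
  cat(sprintf(
    "<pollinet_lm> slope = %.4g (p = %.3g), intercept = %.4g, R2 = %.3f (adj %.3f), n = %d\n",
    x$slope, x$p_value, x$intercept, x$r_squared, x$adj_r_squared, x$n
  ))
  invisible(x)
}

#' @export
tidy.pollinet_lm <- function(x, ...) {
  co <- summary(x$model)$coefficients
  tibble::tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    std_error = co[, "Std. Error"],
    statistic = co[, "t value"],
    p_value = co[, "Pr(>|t|)"]
  )
}

#' @export
glance.pollinet_lm <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
    adj_r_squared = x$adj_r_squared, p_value = x$p_value, n = x$n
  )
}

#' Regress annual deposition on activity period, simplifying stepwise
#'
#' Fits estimated annual deposition per taxon against the taxon's
#' activity period, year, and their interaction, then simplifies: the
#' interaction term is dropped if its p-value exceeds 0.05 and the model
#' refit; the year main effect is then dropped on the same rule. The
#' final model is activity-only when both are dropped. Year enters as a
#' centered numeric covariate (a trend term with a single slope).
#'
#' @param service_annual Annual estimates from [service_annual()].
#' @param activity Activity periods from [activity_periods()].
#' @param alpha Retention threshold for term p-values.
#' @return A list: `fit` (the final model, `lm`), `final` (a
#'   `pollinet_lm`-style glance of the activity slope), `dropped`
#'   (character vector of dropped terms), `steps` (tibble of term
#'   p-values at each step).
#' @export
service_vs_activity <- function(service_annual, activity, alpha = 0.05) {
  dat <- dplyr::inner_join(service_annual, activity, by = "insect_taxon")
  if (nrow(dat) < 3) {
    rlang::abort("Need at least 3 taxon-year rows.", class = "pollinet_lm_error")
  }
  dat$year_c <- dat$year - mean(dat$year)
  dropped <- character()
  steps <- list()
  term_p <- function(fit, term) {
    co <- suppressWarnings(summary(fit))$coefficients
    if (!term %in% rownames(co)) return(NA_real_)
    co[term, "Pr(>|t|)"]
  }
  fit <- stats::lm(estimated_grains ~ activity_weeks * year_c, data = dat)
  p_int <- term_p(fit, "activity_weeks:year_c")
  steps$full <- tibble::tibble(step = "full", term = "activity_weeks:year_c",
                               p_value = p_int)
  if (is.na(p_int) || p_int > alpha) {
    dropped <- c(dropped, "activity_weeks:year_c")
    fit <- stats::lm(estimated_grains ~ activity_weeks + year_c, data = dat)
    p_year <- term_p(fit, "year_c")
    steps$main <- tibble::tibble(step = "additive", term = "year_c",
                                 p_value = p_year)
    if (is.na(p_year) || p_year > alpha) {
      dropped <- c(dropped, "year_c")
      fit <- stats::lm(estimated_grains ~ activity_weeks, data = dat)
    }
  }
  s <- suppressWarnings(summary(fit))
  final <- tibble::tibble(
    slope = unname(stats::coef(fit)["activity_weeks"]),
    p_value = s$coefficients["activity_weeks", "Pr(>|t|)"],
    r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared,
    n = nrow(dat),
    formula = deparse(stats::formula(fit))
  )
  list(fit = fit, final = final, dropped = dropped,
       steps = dplyr::bind_rows(steps))
}
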