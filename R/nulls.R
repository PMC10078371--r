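# Metaweb-resampling null models ----------------------------------------------
#
# A null replicate for an observed network keeps the observed numbers of
# plants and insects, draws that many species uniformly without
# replacement from a source pool (the metaweb, or an annual network),
# inherits the induced link set — a pair interacts in the replicate iff
# it interacted in the source — and redraws each link's strength from a
# continuous uniform distribution spanning the range of the source's
# observed strengths. The number of links therefore varies with the
# species drawn, exactly as in a re-sampled field season.

.metric_engines <- list(
  n_plants        = function(w) nrow(w),
  n_insects       = function(w) ncol(w),
  n_links         = function(w) sum(w > 0),
  connectance_bin = .connectance_bin,
  connectance_wt  = .connectance_wt,
  nodf_bin        = .nodf_bin,
  nodf_wt         = .nodf_wt
)

# Evaluate a named metric on a (possibly unpruned) weight matrix.
.eval_metric <- function(name, w, restarts = 5) {
  w <- w[rowSums(w) > 0, colSums(w) > 0, drop = FALSE]
  if (length(w) == 0) return(NA_real_)
  if (name == "modularity_q") {
    net <- bipartite_network(w, prune = FALSE)
    return(modularity(net, restarts = restarts)$q)
  }
  fn <- .metric_engines[[name]]
  if (is.null(fn)) {
    rlang::abort(paste0("Unknown metric: ", name), class = "pollinet_metric_error")
  }
  fn(w)
}

# Core sampler on matrices; returns list(w = replicate matrix, discards).
.sample_null_matrix <- function(srcw, n_plants, n_insects, wmin, wmax,
                                max_tries) {
  discards <- 0L
  repeat {
    rows <- sample.int(nrow(srcw), n_plants)
    cols <- sample.int(ncol(srcw), n_insects)
    sub <- srcw[rows, cols, drop = FALSE]
    pos <- sub > 0
    if (any(pos)) break
    discards <- discards + 1L
    if (discards >= max_tries) {
      rlang::abort(
        sprintf("%d consecutive all-empty null draws; source too sparse for %d x %d replicates.",
                discards, n_plants, n_insects),
        class = "pollinet_null_error"
      )
    }
  }
  sub[pos] <- stats::runif(sum(pos), wmin, wmax)
  sub[!pos] <- 0
  list(w = sub, discards = discards)
}

#' Draw one same-size random network from a source network
#'
#' @param source A `bipartite_network` acting as the species and link
#'   pool (a metaweb or an annual network).
#' @param n_plants,n_insects Size of the replicate; must not exceed the
#'   source pools.
#' @param weight_law `"uniform"` draws each present link's weight from
#'   continuous Uniform(min, max) over the source's positive weights;
#'   `"observed"` resamples the source's observed weight values with
#'   replacement.
#' @param max_tries Abort after this many consecutive draws with no links
#'   at all (such draws are discarded and redrawn, and counted in the
#'   `discards` attribute). Species that happen to be isolated in a
#'   replicate are kept as drawn; metrics prune them exactly as they
#'   prune observed networks.
#' @return A `bipartite_network` (unpruned) with attribute `discards`.
#' @export
sample_same_size <- function(source, n_plants, n_insects,
                             weight_law = c("uniform", "observed"),
                             max_tries = 10000) {
  weight_law <- match.arg(weight_law)
  if (n_plants > nrow(source$weights) || n_insects > ncol(source$weights)) {
    rlang::abort("Replicate size exceeds the source species pools.",
                 class = "pollinet_null_error")
  }
  pos <- source$weights[source$weights > 0]
  rep <- .sample_null_matrix(source$weights, n_plants, n_insects,
                             min(pos), max(pos), max_tries)
  w <- rep$w
  if (weight_law == "observed") {
    mask <- w > 0
    w[mask] <- sample(pos, sum(mask), replace = TRUE)
  }
  out <- bipartite_network(w, period = paste0(source$period, "-null"),
                           provenance = source$provenance, prune = FALSE)
  attr(out, "discards") <- rep$discards
  out
}

.order_stat_quantiles <- function(values) {
  v <- sort(values)
  n <- length(v)
  c(q025 = v[max(1L, ceiling(0.025 * n))], q975 = v[ceiling(0.975 * n)])
}

.verdict <- function(observed, q) {
  if (is.na(observed)) return("undefined")
  if (observed < q[["q025"]]) return("low")
  if (observed > q[["q975"]]) return("high")
  "ns"
}

#' Null distribution of one metric for one observed network
#'
#' Draws `R` seeded same-size replicates from `source`, evaluates the
#' metric on each (after pruning isolated species, as for observed
#' networks), and compares the observed value to the empirical 0.025 and
#' 0.975 order-statistic quantiles. The verdict is `"low"` if the
#' observed value lies strictly below the 0.025 quantile, `"high"` if
#' strictly above the 0.975 quantile, `"ns"` otherwise, and
#' `"undefined"` when the metric cannot be computed on the observed
#' network. Replicates on which the metric is undefined are excluded
#' from the quantiles and counted.
#'
#' @param observed A `bipartite_network`.
#' @param source Source pool network (metaweb or annual network); must
#'   contain at least as many plants and insects as `observed`.
#' @param metric Metric name: one of `n_plants`, `n_insects`, `n_links`,
#'   `connectance_bin`, `connectance_wt`, `nodf_bin`, `nodf_wt`,
#'   `modularity_q`.
#' @param R Number of replicates.
#' @param seed Optional integer seed; fixed seed gives bit-identical
#'   replicate vectors.
#' @param weight_law,max_tries Passed to [sample_same_size()].
#' @param restarts Modularity restarts used on replicates.
#' @return A `null_distribution` object: list with `metric`, `observed`,
#'   `replicates`, `q025`, `q975`, `verdict`, `n_replicates`,
#'   `n_undefined`, `n_discarded`, `seed`, `source_label`.
#' @export
null_distribution <- function(observed, source, metric, R = 1000, seed = NULL,
                              weight_law = "uniform", max_tries = NULL,
                              restarts = 5) {
  res <- null_test(observed, source, metrics = metric, R = R, seed = seed,
                   weight_law = weight_law, max_tries = max_tries,
                   restarts = restarts, keep_replicates = TRUE)
  structure(
    list(
      metric = metric,
      source_label = source$period,
      observed = res$observed[1],
      replicates = attr(res, "replicates")[[metric]],
      q025 = res$q025[1], q975 = res$q975[1],
      verdict = res$verdict[1],
      n_replicates = res$n_replicates[1],
      n_undefined = res$n_undefined[1],
      n_discarded = res$n_discarded[1],
      seed = seed
    ),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> %s vs %s: observed %.4g, null [%.4g, %.4g] (R=%d) -> %s\n",
    x$metric, x$source_label, x$observed, x$q025, x$q975, x$n_replicates, x$verdict
  ))
  invisible(x)
}

#' @export
glance.null_distribution <- function(x, ...) {
  tibble::tibble(
    metric = x$metric, observed = x$observed, q025 = x$q025, q975 = x$q975,
    verdict = x$verdict, n_replicates = x$n_replicates,
    n_undefined = x$n_undefined, n_discarded = x$n_discarded
  )
}

#' Null-model test of several metrics for one observed network
#'
#' Same mechanism as [null_distribution()], evaluating all requested
#' metrics on one shared set of replicate draws.
#'
#' @inheritParams null_distribution
#' @param metrics Character vector of metric names.
#' @param keep_replicates Attach the replicate value vectors as an
#'   attribute?
#' @return A tibble with one row per metric: `metric`, `observed`,
#'   `q025`, `q975`, `verdict`, `n_replicates`, `n_undefined`,
#'   `n_discarded`, `seed`.
#' @export
null_test <- function(observed, source, metrics, R = 1000, seed = NULL,
                      weight_law = "uniform", max_tries = NULL,
                      restarts = 5, keep_replicates = FALSE) {
  weight_law <- match.arg(weight_law, c("uniform", "observed"))
  if (is.null(max_tries)) max_tries <- 10 * R
  np <- nrow(observed$weights)
  na <- ncol(observed$weights)
  missing_p <- setdiff(plants(observed), plants(source))
  missing_i <- setdiff(insects(observed), insects(source))
  if (length(missing_p) + length(missing_i) > 0) {
    rlang::abort(
      paste0("Observed species absent from the source pool: ",
             paste(c(missing_p, missing_i), collapse = ", ")),
      class = "pollinet_null_error"
    )
  }
  srcw <- source$weights
  pos <- srcw[srcw > 0]
  wmin <- min(pos); wmax <- max(pos)
  obs_vals <- vapply(metrics, .eval_metric, 0, w = observed$weights,
                     restarts = restarts)

  run <- function() {
    vals <- matrix(NA_real_, nrow = R, ncol = length(metrics),
                   dimnames = list(NULL, metrics))
    discards <- 0L
    for (r in seq_len(R)) {
      draw <- .sample_null_matrix(srcw, np, na, wmin, wmax, max_tries)
      discards <- discards + draw$discards
      w <- draw$w
      if (weight_law == "observed") {
        mask <- w > 0
        w[mask] <- sample(pos, sum(mask), replace = TRUE)
      }
      for (k in seq_along(metrics)) {
        vals[r, k] <- .eval_metric(metrics[k], w, restarts = restarts)
      }
    }
    list(vals = vals, discards = discards)
  }
  sim <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  rows <- purrr::map(seq_along(metrics), function(k) {
    v <- sim$vals[, k]
    ok <- !is.na(v)
    q <- if (any(ok)) .order_stat_quantiles(v[ok]) else c(q025 = NA_real_, q975 = NA_real_)
    tibble::tibble(
      metric = metrics[k],
      observed = obs_vals[k],
      q025 = q[["q025"]], q975 = q[["q975"]],
      verdict = if (is.na(obs_vals[k]) || !any(ok)) "undefined"
                else .verdict(obs_vals[k], q),
      n_replicates = sum(ok),
      n_undefined = sum(!ok),
      n_discarded = sim$discards,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (keep_replicates) {
    attr(out, "replicates") <- stats::setNames(
      purrr::map(seq_along(metrics), ~ sim$vals[, .x]), metrics
    )
  }
  out
}

#' Compare weekly networks to random draws from their annual network
#'
#' For every weekly network, draws `R` same-size replicates from the
#' corresponding annual network and scores each requested metric against
#' the replicate distribution, asking whether within-year structure
#' differs from a random slice of the year's interactions. Weeks whose
#' species are not all contained in the annual source are an error;
#' empty weeks never occur in a `network_series` (they are skipped, with
#' a log entry, at construction).
#'
#' @param weekly A `network_series` of weekly networks.
#' @param annuals Named list of annual `bipartite_network`s, one per year
#'   (names are years), e.g. from [build_annual_network()].
#' @param metrics Character vector of metric names (see [null_test()]).
#' @param R,seed,weight_law,restarts As in [null_test()]; each week uses
#'   a distinct sub-seed derived from `seed`.
#' @return A tibble with one row per week x metric, keyed by `year` and
#'   `week`.
#' @export
weekly_vs_annual <- function(weekly, annuals, metrics, R = 1000, seed = NULL,
                             weight_law = "uniform", restarts = 5) {
  k <- series_keys(weekly)
  rows <- purrr::map(seq_len(nrow(k)), function(i) {
    net <- weekly[[k$label[i]]]
    src <- annuals[[as.character(k$year[i])]]
    if (is.null(src)) {
      rlang::abort(paste0("No annual source network for year ", k$year[i], "."),
                   class = "pollinet_null_error")
    }
    res <- null_test(net, src, metrics = metrics, R = R,
                     seed = if (is.null(seed)) NULL else seed + i,
                     weight_law = weight_law, restarts = restarts)
    dplyr::bind_cols(k[i, c("year", "week")], res)
  })
  dplyr::bind_rows(rows)
}

#' Correlation of a metric between two network types
#'
#' Pearson and Spearman correlations of one structural metric across the
#' weeks at which both network types exist (e.g. visitation vs.
#' pollen-transport weekly networks), asking whether the two data types
#' paint a consistent picture of seasonal structure.
#'
#' @param a,b Metric tables from [series_metrics()] with `year`/`week`
#'   keys.
#' @param metric Metric column name present in both tables.
#' @return A one-row tibble: `metric`, `n_weeks`, `pearson_r`,
#'   `spearman_rho`; coefficients are `NA` (with a warning) when either
#'   series has zero variance.
#' @export
correlate_metrics <- function(a, b, metric) {
  joined <- dplyr::inner_join(
    a[c("year", "week", metric)], b[c("year", "week", metric)],
    by = c("year", "week"), suffix = c("_a", "_b")
  )
  joined <- joined[stats::complete.cases(joined), ]
  if (nrow(joined) < 3) {
    rlang::abort(paste0("Only ", nrow(joined),
                        " shared weeks; need at least 3 to correlate."),
                 class = "pollinet_correlation_error")
  }
  x <- joined[[paste0(metric, "_a")]]
  y <- joined[[paste0(metric, "_b")]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::warn("Zero variance in a metric series; correlation undefined.")
    r <- NA_real_; rho <- NA_real_
  } else {
    r <- stats::cor(x, y, method = "pearson")
    rho <- stats::cor(x, y, method = "spearman")
  }
  tibble::tibble(metric = metric, n_weeks = nrow(joined),
                 pearson_r = r, spearman_rho = rho)
}
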