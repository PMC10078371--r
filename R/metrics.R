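# Structural metrics of bipartite networks ------------------------------------
#
# All metrics are computed on the species actually present in the focal
# period: networks are pruned of linkless species first, so "possible
# links" never count plant-insect pairs whose phenologies do not overlap.

# -- engines on plain weight matrices (fast paths for the null models) --------

.connectance_bin <- function(w) {
  if (length(w) == 0) return(NA_real_)
  sum(w > 0) / length(w)
}

.connectance_wt <- function(w) {
  m <- sum(w)
  if (m <= 0 || length(w) == 0) return(NA_real_)
  xlogx <- w * log(w)
  xlogx[w == 0] <- 0
  mj <- colSums(w)
  mi <- rowSums(w)
  # Shannon entropy of each species' weight distribution, natural log
  Hj <- ifelse(mj > 0, log(mj) - colSums(xlogx) / mj, NA_real_)
  Hi <- ifelse(mi > 0, log(mi) - rowSums(xlogx) / mi, NA_real_)
  ld <- 0.5 * (sum((mj / m) * exp(Hj), na.rm = TRUE) +
                 sum((mi / m) * exp(Hi), na.rm = TRUE))
  ld / (nrow(w) + ncol(w))
}

# Mean pairwise overlap with decreasing fill, one side (rows) of a binary
# matrix; returns per-pair contributions for all unordered row pairs.
.nodf_side_bin <- function(b) {
  n <- nrow(b)
  if (n < 2) return(numeric(0))
  fills <- rowSums(b)
  shared <- tcrossprod(b)
  pairs <- utils::combn(n, 2)
  i <- pairs[1, ]; j <- pairs[2, ]
  poorer <- pmin(fills[i], fills[j])
  out <- numeric(length(i))
  ok <- fills[i] != fills[j] & poorer > 0
  out[ok] <- 100 * shared[cbind(i, j)][ok] / poorer[ok]
  out
}

.nodf_bin <- function(w) {
  b <- (w > 0) * 1
  contrib <- c(.nodf_side_bin(b), .nodf_side_bin(t(b)))
  if (length(contrib) == 0) return(NA_real_)
  mean(contrib)
}

.nodf_side_wt <- function(w) {
  n <- nrow(w)
  if (n < 2) return(numeric(0))
  mt <- rowSums(w)
  fills <- rowSums(w > 0)
  pairs <- utils::combn(n, 2)
  out <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    if (mt[i] == mt[j]) next
    if (mt[i] > mt[j]) { rich <- i; poor <- j } else { rich <- j; poor <- i }
    if (fills[poor] == 0) next
    dominated <- sum(w[poor, ] > 0 & w[poor, ] < w[rich, ])
    out[k] <- 100 * dominated / fills[poor]
  }
  out
}

.nodf_wt <- function(w) {
  contrib <- c(.nodf_side_wt(w), .nodf_side_wt(t(w)))
  if (length(contrib) == 0) return(NA_real_)
  mean(contrib)
}

# -- exported metric functions -------------------------------------------------

#' Binary connectance
#'
#' Fraction of possible links realized, L / (P x A), over the species
#' present in the network. Because every listed species carries at least
#' one link, a two-plant network can never have connectance below 0.5.
#'
#' @param net A `bipartite_network`.
#' @return A number in (0, 1], or `NA` for an empty network.
#' @export
connectance_binary <- function(net) .connectance_bin(prune_network(net)$weights)

#' Weighted connectance (linkage density based)
#'
#' Weighted linkage density is the weight-averaged effective number of
#' partners per species,
#' \deqn{LD = \frac12\Big[\sum_j \frac{m_{\cdot j}}{m} e^{H_j}
#'   + \sum_i \frac{m_{i\cdot}}{m} e^{H_i}\Big],}
#' where \eqn{H} is the Shannon entropy (natural log) of a species'
#' interaction-weight distribution and \eqn{e^H} its effective partner
#' count. Weighted connectance is \eqn{LD / (P + A)}. A single link gives
#' 0.5, as does any complete network with equal weights.
#'
#' @param net A `bipartite_network`.
#' @return A number in (0, 1], or `NA` if total weight is zero.
#' @export
connectance_weighted <- function(net) .connectance_wt(prune_network(net)$weights)

#' Nestedness (NODF), binary and weighted
#'
#' NODF (nestedness by overlap and decreasing fill) scores every
#' unordered pair of species within a side. In the binary version a pair
#' contributes `100 * |shared partners| / fill(poorer)` when the two
#' fills differ (and the poorer fill is positive), and 0 otherwise; NODF
#' is the mean contribution over all row pairs and column pairs, ranging
#' 0-100. The weighted version replaces overlap by strict weight
#' dominance: a pair with strictly unequal marginal totals contributes
#' the percentage of the poorer species' partners at which its weight is
#' positive yet strictly below the richer species' weight. Ties (equal
#' fills, equal marginal totals, equal weights) contribute zero.
#'
#' @param net A `bipartite_network`; needs at least one side with two or
#'   more species, otherwise `NA` is returned.
#' @return A number in \[0, 100\] or `NA`.
#' @export
nodf_binary <- function(net) .nodf_bin(prune_network(net)$weights)

#' @rdname nodf_binary
#' @export
nodf_weighted <- function(net) .nodf_wt(prune_network(net)$weights)

# -- Barber bipartite modularity ----------------------------------------------

# Q for a labelled partition; labels = integer vector over c(plants, insects).
.barber_q <- function(w, labels) {
  m <- sum(w)
  if (m <= 0) return(0)
  P <- nrow(w)
  gp <- labels[seq_len(P)]
  gi <- labels[P + seq_len(ncol(w))]
  mods <- sort(unique(labels))
  s <- rowSums(w)
  t <- colSums(w)
  q <- 0
  for (c in mods) {
    ip <- gp == c
    ii <- gi == c
    if (!any(ip) || !any(ii)) next
    q <- q + sum(w[ip, ii, drop = FALSE]) - sum(s[ip]) * sum(t[ii]) / m
  }
  q / m
}

# One greedy optimization pass from an initial labelling: repeated
# best-gain single-node moves (including moves to a fresh module),
# followed by module merges, until neither improves Q.
.modularity_local <- function(w, labels) {
  m <- sum(w)
  P <- nrow(w); A <- ncol(w)
  n <- P + A
  s <- rowSums(w); t <- colSums(w)
  repeat {
    moved <- FALSE
    for (u in sample.int(n)) {
      is_plant <- u <= P
      mods <- unique(labels)
      free <- setdiff(seq_len(n + 1), mods)[1]
      cand <- c(mods, free)
      if (is_plant) {
        # links from plant u into each candidate module's insects
        k <- vapply(cand, function(c) sum(w[u, labels[P + seq_len(A)] == c]), 0)
        Tmod <- vapply(cand, function(c) sum(t[labels[P + seq_len(A)] == c]), 0)
        score <- k - s[u] * Tmod / m
      } else {
        j <- u - P
        k <- vapply(cand, function(c) sum(w[labels[seq_len(P)] == c, j]), 0)
        Smod <- vapply(cand, function(c) sum(s[labels[seq_len(P)] == c]), 0)
        score <- k - t[j] * Smod / m
      }
      best <- cand[which.max(score)]
      if (best != labels[u] && score[cand == best] > score[cand == labels[u]] + 1e-12) {
        labels[u] <- best
        moved <- TRUE
      }
    }
    # merge phase
    mods <- unique(labels)
    merged <- FALSE
    if (length(mods) > 1) {
      prs <- utils::combn(length(mods), 2)
      for (k in seq_len(ncol(prs))) {
        a <- mods[prs[1, k]]; b <- mods[prs[2, k]]
        pa <- labels[seq_len(P)] == a; pb <- labels[seq_len(P)] == b
        ia <- labels[P + seq_len(A)] == a; ib <- labels[P + seq_len(A)] == b
        gain <- sum(w[pa, ib, drop = FALSE]) + sum(w[pb, ia, drop = FALSE]) -
          (sum(s[pa]) * sum(t[ib]) + sum(s[pb]) * sum(t[ia])) / m
        if (gain > 1e-12) {
          labels[labels == b] <- a
          merged <- TRUE
          break
        }
      }
    }
    if (!moved && !merged) break
  }
  labels
}

#' Barber bipartite modularity
#'
#' Maximizes Barber's bipartite modularity
#' \deqn{Q = \frac{1}{m}\sum_{i,j}\Big(w_{ij} - \frac{s_i t_j}{m}\Big)
#'   \delta(g_i, g_j)}
#' (with \eqn{s, t} the plant and insect marginal totals and \eqn{m} the
#' total weight) over partitions of the species into modules, using a
#' seeded multi-restart greedy label-moving heuristic with a module-merge
#' refinement. The heuristic's best partition is returned together with
#' its Q; like all stochastic module detection, the result is a lower
#' bound on the true optimum and can vary between seeds on hard
#' instances.
#'
#' @param net A `bipartite_network`.
#' @param restarts Number of random restarts (the first start is the
#'   all-singletons partition).
#' @param seed Optional integer; when given, results are reproducible.
#' @return An object of class `modularity_fit`: list with `q` (the best
#'   modularity found) and `assignment`, a tibble of `node`, `side`,
#'   `module`.
#' @export
modularity <- function(net, restarts = 20, seed = NULL) {
  run <- function() {
    net <- prune_network(net)
    w <- net$weights
    P <- nrow(w); A <- ncol(w); n <- P + A
    best_labels <- .modularity_local(w, seq_len(n))
    best_q <- .barber_q(w, best_labels)
    for (r in seq_len(max(0, restarts - 1))) {
      k <- sample.int(n, 1)
      init <- sample.int(k, n, replace = TRUE)
      labels <- .modularity_local(w, init)
      q <- .barber_q(w, labels)
      if (q > best_q + 1e-15) {
        best_q <- q
        best_labels <- labels
      }
    }
    assignment <- tibble::tibble(
      node = c(plants(net), insects(net)),
      side = rep(c("plant", "insect"), c(P, A)),
      module = match(best_labels, unique(best_labels))
    )
    structure(list(q = best_q, assignment = assignment),
              class = "modularity_fit")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.modularity_fit <- function(x, ...) {
  cat(sprintf("<modularity_fit> Q = %.4f, %d modules\n",
              x$q, max(x$assignment$module)))
  invisible(x)
}

#' @export
tidy.modularity_fit <- function(x, ...) x$assignment

#' @export
glance.modularity_fit <- function(x, ...) {
  tibble::tibble(q = x$q, n_modules = max(x$assignment$module))
}

# -- metric sets ---------------------------------------------------------------

#' All structural metrics of one network
#'
#' Computes network size (plants, insects, links), binary and weighted
#' connectance, binary and weighted NODF, and Barber modularity. Because
#' the meaning of interaction strength differs between network types,
#' weighted metrics are meaningful only for visitation-based networks:
#' pollen-transport networks are always scored `binary_only` (requesting
#' `full` triggers a warning and coercion). Metrics that are undefined on
#' a network (e.g. NODF when both sides are singletons) are reported as
#' `NA`, never as 0.
#'
#' @param net A `bipartite_network`.
#' @param mode `"full"` (all metrics) or `"binary_only"` (weighted
#'   connectance and weighted NODF omitted).
#' @param restarts,seed Passed to [modularity()].
#' @return A one-row tibble (`period`, `provenance`, `n_plants`,
#'   `n_insects`, `n_links`, `connectance_bin`, `connectance_wt`,
#'   `nodf_bin`, `nodf_wt`, `modularity_q`) with the module assignment
#'   attached as attribute `module_assignment`.
#' @export
metric_set <- function(net, mode = c("full", "binary_only"),
                       restarts = 20, seed = NULL) {
  mode <- match.arg(mode)
  if (net$provenance == "pollen" && mode == "full") {
    rlang::warn("Pollen-transport networks are scored with binary metrics only; coercing mode to 'binary_only'.")
    mode <- "binary_only"
  }
  net <- prune_network(net)
  w <- net$weights
  fit <- modularity(net, restarts = restarts, seed = seed)
  out <- tibble::tibble(
    period = net$period,
    provenance = net$provenance,
    n_plants = nrow(w),
    n_insects = ncol(w),
    n_links = sum(w > 0),
    connectance_bin = .connectance_bin(w),
    connectance_wt = if (mode == "full") .connectance_wt(w) else NA_real_,
    nodf_bin = .nodf_bin(w),
    nodf_wt = if (mode == "full") .nodf_wt(w) else NA_real_,
    modularity_q = fit$q
  )
  attr(out, "module_assignment") <- fit$assignment
  out
}

#' Metrics for every network in a series
#'
#' @param series A `network_series`.
#' @param mode,restarts,seed Passed to [metric_set()] (each network gets
#'   a distinct sub-seed derived from `seed`).
#' @return A tibble with one row per network, keyed by `year` and `week`.
#' @export
series_metrics <- function(series, mode = "full", restarts = 20, seed = NULL) {
  k <- series_keys(series)
  rows <- purrr::imap(unclass(series), function(net, i) {
    idx <- match(i, k$label)
    sub_seed <- if (is.null(seed)) NULL else seed + idx
    metric_set(net, mode = mode, restarts = restarts, seed = sub_seed)
  })
  dplyr::bind_cols(k[c("year", "week")], dplyr::bind_rows(rows))
}
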