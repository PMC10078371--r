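# Independent brute-force oracles, deliberately written with different
# algorithms than the package (explicit loops and set operations, no
# shared code paths).

# NODF by direct pair enumeration: loop over every unordered pair within
# a side, count shared partners with intersect().
oracle_nodf_binary <- function(w) {
  side <- function(m) {
    n <- nrow(m)
    if (n < 2) return(numeric(0))
    vals <- c()
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        pi <- which(m[i, ] > 0)
        pj <- which(m[j, ] > 0)
        fi <- length(pi); fj <- length(pj)
        if (fi == fj || min(fi, fj) == 0) {
          vals <- c(vals, 0)
        } else {
          poorer <- if (fi < fj) pi else pj
          richer <- if (fi < fj) pj else pi
          vals <- c(vals, 100 * length(intersect(poorer, richer)) / length(poorer))
        }
      }
    }
    vals
  }
  contrib <- c(side(w), side(t(w)))
  if (length(contrib) == 0) NA_real_ else mean(contrib)
}

oracle_nodf_weighted <- function(w) {
  side <- function(m) {
    n <- nrow(m)
    if (n < 2) return(numeric(0))
    vals <- c()
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        mti <- sum(m[i, ]); mtj <- sum(m[j, ])
        if (mti == mtj) { vals <- c(vals, 0); next }
        poor <- if (mti < mtj) i else j
        rich <- if (mti < mtj) j else i
        fill_poor <- sum(m[poor, ] > 0)
        if (fill_poor == 0) { vals <- c(vals, 0); next }
        cnt <- 0
        for (c in seq_len(ncol(m))) {
          if (m[poor, c] > 0 && m[poor, c] < m[rich, c]) cnt <- cnt + 1
        }
        vals <- c(vals, 100 * cnt / fill_poor)
      }
    }
    vals
  }
  contrib <- c(side(w), side(t(w)))
  if (length(contrib) == 0) NA_real_ else mean(contrib)
}

# All set partitions of n elements as restricted-growth label vectors.
oracle_partitions <- function(n) {
  out <- list()
  rec <- function(labels, k) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (c in seq_len(k + 1L)) rec(c(labels, c), max(k, c))
  }
  rec(integer(0), 0L)
  out
}

# Barber bipartite modularity of one labelled partition, from the
# definition (per-module weight excess over the degree expectation).
oracle_barber_q <- function(w, labels) {
  m <- sum(w)
  P <- nrow(w)
  gp <- labels[seq_len(P)]
  gi <- labels[P + seq_len(ncol(w))]
  s <- rowSums(w)
  t <- colSums(w)
  q <- 0
  for (c in unique(labels)) {
    ip <- gp == c
    ii <- gi == c
    if (!any(ip) || !any(ii)) next
    q <- q + sum(w[ip, ii, drop = FALSE]) - sum(s[ip]) * sum(t[ii]) / m
  }
  q / m
}

# Exhaustive maximum of Barber Q over all partitions (feasible for
# networks with at most ~9 species).
oracle_exhaustive_q <- function(w) {
  parts <- oracle_partitions(nrow(w) + ncol(w))
  max(vapply(parts, function(g) oracle_barber_q(w, g), 0))
}

# Ordinary least squares from the closed-form normal equations.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  beta <- sxy / sxx
  alpha <- mean(y) - beta * mean(x)
  yhat <- alpha + beta * x
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  se <- sqrt(ss_res / (n - 2) / sxx)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(slope = beta, intercept = alpha, r_squared = r2, adj_r_squared = adj,
       p_value = p, n = n)
}

# Weighted linkage density computed step by step from the entropy
# definition (independent of the matrix-vectorized implementation).
oracle_weighted_connectance <- function(w) {
  m <- sum(w)
  ld <- 0
  for (j in seq_len(ncol(w))) {
    col <- w[, j][w[, j] > 0]
    p <- col / sum(col)
    H <- -sum(p * log(p))
    ld <- ld + (sum(col) / m) * exp(H)
  }
  for (i in seq_len(nrow(w))) {
    row <- w[i, ][w[i, ] > 0]
    p <- row / sum(row)
    H <- -sum(p * log(p))
    ld <- ld + (sum(row) / m) * exp(H)
  }
  (ld / 2) / (nrow(w) + ncol(w))
}
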