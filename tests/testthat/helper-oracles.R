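# Independent brute-force reference implementations. These deliberately use
# plain loops and the textbook definitions so they share no code path with
# the package functions they check.

# Running-sum enrichment score by literal enumeration of the walk.
oracle_ssgsea <- function(x, sig_genes, exponent) {
  genes <- names(x)
  G <- length(x)
  m <- length(intersect(sig_genes, genes))
  r <- rank(-x, ties.method = "average")
  walk <- genes[order(r, genes)]
  w_raw <- numeric(G)
  for (i in seq_len(G)) {
    w_raw[i] <- (G - r[walk[i]] + 1)^exponent
  }
  score <- 0
  cum_in <- 0
  cum_out <- 0
  total_in <- sum(w_raw[walk %in% sig_genes])
  for (i in seq_len(G)) {
    if (walk[i] %in% sig_genes) {
      cum_in <- cum_in + w_raw[i] / total_in
    } else {
      cum_out <- cum_out + 1 / (G - m)
    }
    score <- score + (cum_in - cum_out)
  }
  score
}

# Welch statistic straight from the formula.
oracle_welch <- function(a, b) {
  m1 <- mean(a); m2 <- mean(b)
  v1 <- var(a); v2 <- var(b)
  n1 <- length(a); n2 <- length(b)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# BH step-up from the definition: q_i = min_{j: p_(j) >= p_i} p_(j) * n / j.
oracle_bh <- function(p) {
  n <- length(p)
  ps <- sort(p)
  vapply(p, function(pi) {
    cand <- vapply(seq_len(n), function(j) {
      if (ps[j] >= pi) ps[j] * n / j else Inf
    }, numeric(1))
    min(1, min(cand))
  }, numeric(1))
}

# Pearson correlation from covariance over variances.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Naive Ward.D2 agglomeration: squared dissimilarities with the
# Lance-Williams update, scanning all pairs each step, ties broken by the
# lowest pair indices. Returns merge heights in merge order.
oracle_ward2 <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  d2 <- d^2
  active <- seq_len(n)
  sizes <- rep(1, n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA)
    best_val <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        a <- active[ii]; b <- active[jj]
        if (d2[a, b] < best_val - 1e-12) {
          best_val <- d2[a, b]
          best <- c(a, b)
        }
      }
    }
    a <- best[1]; b <- best[2]
    heights <- c(heights, sqrt(best_val))
    # merged cluster replaces `a`; update d2 to every other active cluster
    for (k in setdiff(active, c(a, b))) {
      na <- sizes[a]; nb <- sizes[b]; nk <- sizes[k]
      tot <- na + nb + nk
      upd <- ((na + nk) * d2[a, k] + (nb + nk) * d2[b, k] -
                nk * d2[a, b]) / tot
      d2[a, k] <- upd
      d2[k, a] <- upd
    }
    sizes[a] <- sizes[a] + sizes[b]
    active <- setdiff(active, b)
  }
  heights
}

# Exact two-sided binomial p by minimum-likelihood enumeration. The small
# relative slack when comparing probabilities mirrors the convention of
# standard implementations so ties at the observed likelihood are included.
oracle_binom_two_sided <- function(k, n, p0) {
  probs <- dbinom(0:n, n, p0)
  obs <- probs[k + 1]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Two-tailed Fisher exact p on a 2x2 table by full hypergeometric
# enumeration over all tables with the observed margins.
oracle_fisher_2x2 <- function(x) {
  r1 <- sum(x[1, ]); c1 <- sum(x[, 1]); n <- sum(x)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(ks, r1, n - r1, c1)
  obs <- dhyper(x[1, 1], r1, n - r1, c1)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}
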