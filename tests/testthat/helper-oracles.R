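# Independent brute-force oracles used to validate the statistical
# primitives. Deliberately naive implementations: full enumeration and
# literal definitions, sharing no code with the package internals.

# Two-sided exact Wilcoxon rank-sum p by enumerating every assignment of
# the pooled ranks to group A (doubled smaller tail, capped at 1).
oracle_wilcoxon_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  stopifnot(!any(duplicated(pooled)))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  u_all <- apply(sets, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  lo <- mean(u_all <= u_obs)
  hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Two-sided Fisher p by full hypergeometric enumeration with the
# point-probability rule (tables at most as probable as the observed one).
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(ks, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Literal Benjamini-Hochberg step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    j_range <- i:m
    adj[ord[i]] <- min(1, min(p[ord[j_range]] * m / j_range))
  }
  adj
}

# Exhaustive least-squares segmentation with at most max_bkps breakpoints
# and a minimum segment length; returns the breakpoint set (indices of the
# last probe of each non-final segment) minimizing total RSS.
oracle_segment <- function(x, max_bkps = 2, min_len = 1) {
  n <- length(x)
  rss <- function(v) sum((v - mean(v))^2)
  seg_rss <- function(bkps) {
    bounds <- c(0, bkps, n)
    if (any(diff(bounds) < min_len)) return(Inf)
    sum(vapply(seq_len(length(bounds) - 1), function(i)
      rss(x[(bounds[i] + 1):bounds[i + 1]]), numeric(1)))
  }
  best <- list(bkps = integer(0), rss = seg_rss(integer(0)))
  if (max_bkps >= 1) {
    for (k in seq_len(n - 1)) {
      r <- seg_rss(k)
      if (r < best$rss - 1e-12) best <- list(bkps = k, rss = r)
    }
  }
  if (max_bkps >= 2 && n >= 3) {
    for (k1 in seq_len(n - 2)) for (k2 in (k1 + 1):(n - 1)) {
      r <- seg_rss(c(k1, k2))
      if (r < best$rss - 1e-12) best <- list(bkps = c(k1, k2), rss = r)
    }
  }
  best
}

# Quick single-chromosome probe panel for unit tests.
toy_panel <- function(n, chrom = "1", spacing = 1e5) {
  probe_panel(sprintf("p%03d", seq_len(n)), rep(chrom, n),
              seq(1e6, by = spacing, length.out = n))
}

# Marker call matrix realizing given per-marker AI frequencies over
# n fully informative samples (AI counts rounded to the nearest sample).
calls_with_frequencies <- function(freqs, n = 20) {
  m <- length(freqs)
  calls <- matrix("retained", n, m,
                  dimnames = list(sprintf("s%02d", 1:n),
                                  sprintf("M%02d", 1:m)))
  for (j in seq_len(m)) {
    k <- round(n * freqs[j])
    if (k > 0) calls[seq_len(k), j] <- "AI"
  }
  calls
}
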