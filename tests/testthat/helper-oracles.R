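# Independent oracles and small fixtures used across the suite.

# exact Poisson upper tail by direct summation of the mass function over the
# upper side (summing the lower side and subtracting from 1 would lose all
# precision in far tails)
poisson_tail_oracle <- function(k, lam) {
  if (k == 0) return(1)
  hi <- max(k, ceiling(lam)) + 1000   # remainder beyond is < 1e-300 here
  sum(stats::dpois(k:hi, lam))
}

# Fisher 2x2 by full enumeration over the hypergeometric support
fisher_oracle <- function(a, b, c, d, sided = "two") {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  if (sided == "two") sum(probs[probs <= p_obs * (1 + 1e-7)])
  else sum(probs[support >= a])
}

# exact binomial two-sided (2 * min tail, capped at 1) by explicit summation
projection_oracle <- function(k, n, p0) {
  upper <- sum(stats::dbinom(k:n, n, p0))
  lower <- sum(stats::dbinom(0:k, n, p0))
  min(1, 2 * min(upper, lower))
}

# BH step-up computed by hand
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# reciprocal-overlap recovery of planted truth by called regions
recovery_fraction <- function(called, truth, min_recip = 0.8) {
  ov <- GenomicRanges::findOverlaps(truth, called)
  if (!length(ov)) return(0)
  w <- GenomicRanges::width(GenomicRanges::pintersect(
    truth[S4Vectors::queryHits(ov)], called[S4Vectors::subjectHits(ov)]))
  r <- pmin(w / GenomicRanges::width(truth)[S4Vectors::queryHits(ov)],
            w / GenomicRanges::width(called)[S4Vectors::subjectHits(ov)])
  best <- rep(0, length(truth))
  agg <- tapply(r, S4Vectors::queryHits(ov), max)
  best[as.integer(names(agg))] <- agg
  mean(best >= min_recip)
}

# uniform fragment set on a genome (deterministic helper fixture)
uniform_fragments <- function(n, genome, len = 300, seed = 1) {
  withr::with_seed(seed, {
    clen <- unclass(genome)
    ch <- sample(names(clen), n, TRUE, prob = clen)
    s0 <- floor(stats::runif(n) * (clen[ch] - len))
    region_set(ch, s0, s0 + len, genome)
  })
}

# tiny genome used by several files
tiny_genome <- genome_spec(c("chr1", "chr2"), c(1e5, 5e4))
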