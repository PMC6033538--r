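## Brute-force enumeration oracles, independent of the package internals.

## KS D by direct sup over all sample points
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1L))))
}

## two-sided binomial p, minimum-likelihood enumeration
oracle_binom_two_sided <- function(x, n, p0) {
  d <- stats::dbinom(0:n, n, p0)
  sum(d[d <= d[x + 1L] * (1 + 1e-7)])
}

## two-sided Fisher p for the 2x2 table [[a, b], [c, d]], hypergeometric
## enumeration over all tables with the same margins
oracle_fisher_two_sided <- function(a, b, c_, d) {
  m <- a + b; n_ <- c_ + d; k <- a + c_
  lo <- max(0L, k - n_); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n_, k)
  obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

## running-sum enrichment score, one explicit step at a time
oracle_es <- function(scores, hit, p = 1) {
  n <- length(scores); nh <- sum(hit)
  denom <- sum(abs(scores[hit])^p)
  rs <- 0; best <- 0
  for (i in seq_len(n)) {
    rs <- rs + if (hit[i]) {
      if (denom > 0) abs(scores[i])^p / denom else 1 / nh
    } else -1 / (n - nh)
    if (abs(rs) > abs(best)) best <- rs
  }
  unname(best)
}

## adjusted Rand index between two partitions
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab)); si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab))); n2 <- comb2(sum(tab))
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
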