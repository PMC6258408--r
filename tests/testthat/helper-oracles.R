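# Independent oracles used across tests. These deliberately use brute-force
# enumeration or closed forms, never the implementation under test.

# Exact one-tailed (cases greater) permutation p-value of the rank-sum
# statistic: enumerate every assignment of m of the pooled values to the
# case group. Feasible up to ~12 observations.
exactWilcoxonP <- function(x, y) {
  m <- length(x); n <- length(y)
  pool <- c(x, y)
  rk <- rank(pool)
  Uobs <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  sets <- utils::combn(m + n, m)
  Us <- apply(sets, 2, function(ix) sum(rk[ix]) - m * (m + 1) / 2)
  mean(Us >= Uobs)
}

# Closed-form chi-square (4 d.f.) survival function.
chisq4Survival <- function(x) exp(-x / 2) * (1 + x / 2)

# Brute-force recessive gene score: maximum over all pairs of the pairwise
# sum (0 with fewer than two scores).
bruteRecessive <- function(scores) {
  if (length(scores) < 2) return(0)
  best <- 0
  for (i in seq_len(length(scores) - 1))
    for (j in (i + 1):length(scores))
      best <- max(best, scores[i] + scores[j])
  best
}

# Brute-force coverage-cis collapse for <= 4 variants of one individual and
# gene: classify every pair with coverageCisTest, take the transitive
# closure of cis relations, keep the top-scoring member per component.
bruteCisCollapse <- function(calls, window = 100, cisP = 0.4) {
  n <- nrow(calls)
  if (n < 2) return(calls)
  adj <- diag(TRUE, n)
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (key[i] == key[j]) next
      v <- coverageCisTest(calls$pos[i], calls$alt_cov[i], calls$ref_cov[i],
                           calls$pos[j], calls$alt_cov[j], calls$ref_cov[j],
                           window = window, cisP = cisP)
      if (v == "cis") adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  for (k in seq_len(n))  # Floyd-Warshall transitive closure
    adj <- adj | (adj[, k] %o% adj[k, ])
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (is.na(comp[i])) { cid <- cid + 1; comp[which(adj[i, ])] <- cid }
  }
  keep <- vapply(unique(comp), function(cc) {
    members <- which(comp == cc)
    members[which.max(calls$score[members])]
  }, integer(1))
  calls[sort(keep), , drop = FALSE]
}
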