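# Brute-force oracles, independent of the package's implementations.

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, r1, r2, c1)
  obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Pearson chi-square from the textbook formula
chisq_oracle <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - E)^2 / E)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

# exact two-sided rank-sum p by enumerating all group assignments
wilcox_oracle <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- combn(n, n1)
  ws <- apply(sets, 2, function(s) sum(r[s])) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# exact two-sided binomial p by point-probability summation
binom_oracle <- function(k, n, p = 0.5) {
  probs <- dbinom(0:n, n, p)
  sum(probs[probs <= dbinom(k, n, p) * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# order scores by enumerating nested pattern chains 0 c S1 c S2 c {1..k}
score_oracle <- function(freq_by_level, k) {
  ords <- splicord::canonical_orders(k)
  subsets <- function(L) combn(k, L, simplify = FALSE)
  chains <- list(list(integer(0)))
  for (L in seq_len(k - 1)) {
    chains <- unlist(lapply(chains, function(ch) {
      prev <- ch[[length(ch)]]
      lapply(Filter(function(s) all(prev %in% s), subsets(L)),
             function(s) c(ch, list(s)))
    }), recursive = FALSE)
  }
  P <- setNames(numeric(length(ords)), names(ords))
  for (ch in chains) {
    chain_sets <- c(ch, list(seq_len(k)))
    added <- unlist(lapply(seq_len(k), function(L)
      setdiff(chain_sets[[L + 1]], chain_sets[[L]])))
    nm <- paste(added, collapse = "->")
    prod_f <- 1
    for (L in seq_len(k - 1)) {
      pat <- splicord::pattern_string(chain_sets[[L + 1]], k)
      f <- freq_by_level[[L]]
      prod_f <- prod_f * (if (pat %in% names(f)) f[[pat]] else 0)
    }
    P[nm] <- prod_f
  }
  P <- P[names(ords)]
  if (sum(P) > 0) P / sum(P) else P * NA
}
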