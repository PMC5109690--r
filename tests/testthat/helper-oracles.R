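# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the code paths they check: table probabilities
# come from log-binomial coefficients (not dhyper), rank-sum p-values from
# enumerating rank assignments, AUC from the pairwise U-statistic.

# Two-sided Fisher p for [[a,b],[c,d]] by exhaustive enumeration of all
# tables with the observed margins, summing probabilities <= observed.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  if (m == 0 || n2 == 0 || k == 0 || k == m + n2) return(1)
  xs <- max(0, k - n2):min(k, m)
  logp <- lchoose(m, xs) + lchoose(n2, k - xs) - lchoose(m + n2, k)
  p <- exp(logp)
  pobs <- exp(lchoose(m, a) + lchoose(n2, k - a) - lchoose(m + n2, k))
  min(1, sum(p[p <= pobs * (1 + 1e-7)]))
}

# Exact two-sided rank-sum p by enumerating every assignment of the pooled
# ranks to the first sample: p = 2 * min tail of the U distribution.
oracle_ranksum_p <- function(xs, ys) {
  n1 <- length(xs); n2 <- length(ys)
  r <- rank(c(xs, ys))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  picks <- utils::combn(n1 + n2, n1)
  us <- apply(picks, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

oracle_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# IG of a discrete feature by direct entropy arithmetic over value groups
oracle_ig_discrete <- function(x, labels) {
  n <- length(x)
  h <- oracle_entropy(as.vector(table(labels)) / n)
  cond <- 0
  for (v in unique(x)) {
    sel <- x == v
    cond <- cond + sum(sel) / n *
      oracle_entropy(as.vector(table(labels[sel])) / sum(sel))
  }
  h - cond
}

# IG of a numeric feature under best binary threshold, by trying every
# possible cut directly
oracle_ig_threshold <- function(x, labels) {
  cuts <- sort(unique(x))
  if (length(cuts) < 2) return(0)
  mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
  max(vapply(mids, function(m) oracle_ig_discrete(x <= m, labels), 0))
}

# ROC AUC as the normalized Mann-Whitney U statistic over all pos/neg pairs
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

oracle_kappa <- function(m) {
  n <- sum(m)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  (po - pe) / (1 - pe)
}
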