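#' Two-sided Fisher's exact test for 2x2 tables, vectorized
#'
#' Computes the two-sided Fisher's exact p-value for the table
#' \code{[[a, b], [c, d]]} by summing hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed that of
#' the observed table (the same two-sided convention as
#' \code{stats::fisher.test}, with its relative tolerance of 1e-7 on the
#' probability comparison). Vectorized over the four counts, which keeps
#' per-candidate somatic and strand-bias testing fast.
#'
#' Degenerate tables with an empty row or column admit a single table and
#' return p = 1.
#'
#' @param a,b,c,d Non-negative integer counts; recycled to a common length.
#' @return Numeric vector of p-values in (0, 1].
#' @export
fisher_test_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  p <- numeric(n)
  for (i in seq_len(n)) {
    m <- a[i] + b[i]          # row 1 margin
    nn <- c[i] + d[i]         # row 2 margin
    k <- a[i] + c[i]          # column 1 margin
    if (m + nn == 0) stop("all-zero 2x2 table")
    if (m == 0 || nn == 0 || k == 0 || k == m + nn) { p[i] <- 1; next }
    x <- max(0, k - nn):min(k, m)
    dens <- stats::dhyper(x, m, nn, k)
    pobs <- stats::dhyper(a[i], m, nn, k)
    p[i] <- min(1, sum(dens[dens <= pobs * (1 + 1e-7)]))
  }
  p
}

#' Fisher somatic test on tumor vs normal allele counts
#'
#' Tests whether reads supporting the reference and the alternative allele
#' are distributed differently between the tumor and its matched normal, the
#' Varscan2-style somatic significance test. Two-sided.
#'
#' @param tumor_counts,normal_counts Length-2 vectors `(ref_reads, alt_reads)`.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_somatic_test <- function(tumor_counts, normal_counts) {
  stopifnot(length(tumor_counts) == 2, length(normal_counts) == 2)
  if (sum(tumor_counts, normal_counts) == 0)
    stop("all-zero 2x2 table: no reads in either sample")
  fisher_test_2x2(tumor_counts[1], tumor_counts[2],
                  normal_counts[1], normal_counts[2])
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midranks are used for ties. Below the small-sample cutoff (both samples
#' \eqn{< 50}, no ties) the exact null distribution of the Mann-Whitney U
#' statistic is used; otherwise the normal approximation with tie-corrected
#' variance and continuity correction. Used for the alt-versus-ref
#' quality-bias and read-position features.
#'
#' @param xs,ys Non-empty numeric vectors.
#' @param exact_max Largest per-sample size for the exact path (default 49).
#' @return Two-sided p-value in (0, 1].
#' @export
rank_sum_test <- function(xs, ys, exact_max = 49) {
  if (length(xs) == 0 || length(ys) == 0)
    stop("rank_sum_test requires non-empty samples")
  n1 <- length(xs); n2 <- length(ys)
  r <- rank(c(xs, ys))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- tabulate(as.integer(2 * r))  # midranks are half-integers
  ties <- ties[ties > 0]
  if (!any(ties > 1) && n1 <= exact_max && n2 <= exact_max) {
    if (U > n1 * n2 / 2) {
      p <- 2 * stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    } else {
      p <- 2 * stats::pwilcox(U, n1, n2)
    }
    return(min(1, p))
  }
  N <- n1 + n2
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)  # everything tied
  z <- U - n1 * n2 / 2
  z <- z - sign(z) * 0.5      # continuity correction
  min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
}

entropy_bits <- function(w) {
  w <- w[w > 0]
  W <- sum(w)
  if (W <= 0) return(0)
  p <- w / W
  -sum(p * log2(p))
}

#' Information gain of a feature with respect to the class
#'
#' IG is the reduction in class entropy (bits) after conditioning on the
#' feature: \eqn{IG = H(class) - H(class | feature)}. Discrete features
#' (factor/character/logical) condition on their values directly; numeric
#' features are discretized by a supervised binary-threshold search that
#' maximizes IG over deterministic midpoints between consecutive distinct
#' values. Optional instance weights make the measure consistent with
#' cost-sensitive training.
#'
#' @param x Feature values (numeric or discrete), one per instance.
#' @param labels Class labels (two or more classes; a single class gives 0).
#' @param weights Optional positive instance weights.
#' @return Information gain in bits, `>= 0` and bounded by `H(labels)`.
#' @export
information_gain <- function(x, labels, weights = NULL) {
  stopifnot(length(x) == length(labels), length(x) >= 2)
  w <- if (is.null(weights)) rep(1, length(x)) else as.numeric(weights)
  stopifnot(length(w) == length(x), all(w > 0))
  labels <- as.character(labels)
  H <- entropy_bits(tapply(w, labels, sum, default = 0))
  if (H == 0) return(0)
  W <- sum(w)
  if (!is.numeric(x)) {
    cond <- 0
    for (v in unique(x)) {
      sel <- x == v
      cond <- cond + sum(w[sel]) / W * entropy_bits(tapply(w[sel], labels[sel], sum, default = 0))
    }
    return(max(0, H - cond))
  }
  ord <- order(x)
  xo <- x[ord]; lo <- labels[ord]; wo <- w[ord]
  classes <- unique(labels)
  wmat <- vapply(classes, function(cl) cumsum(wo * (lo == cl)),
                 numeric(length(xo)))
  if (is.null(dim(wmat))) wmat <- matrix(wmat, nrow = length(xo))
  splits <- which(diff(xo) > 0)
  if (length(splits) == 0) return(0)
  tot <- wmat[length(xo), ]
  wl <- wmat[splits, , drop = FALSE]
  wr <- sweep(-wl, 2, tot, `+`)
  xlogx <- function(m) ifelse(m > 0, m * log2(m), 0)
  ent_rows <- function(m) {           # weighted entropy * total weight
    tw <- rowSums(m)
    tw * log2(ifelse(tw > 0, tw, 1)) - rowSums(xlogx(m))
  }
  cond <- (ent_rows(wl) + ent_rows(wr)) / W
  max(0, H - min(cond))
}

#' Rank features by information gain
#'
#' @param x Data frame or matrix of features (columns) by instances (rows).
#' @param labels Class labels, one per row.
#' @param weights Optional instance weights.
#' @return `data.frame` with columns `feature` and `ig`, in descending IG
#'   order; ties broken alphabetically by feature name.
#' @export
rank_features <- function(x, labels, weights = NULL) {
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(labels))
  ig <- vapply(x, information_gain, numeric(1), labels = labels, weights = weights)
  ord <- order(-ig, names(ig))
  data.frame(feature = names(ig)[ord], ig = unname(ig)[ord],
             stringsAsFactors = FALSE)
}
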