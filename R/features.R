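#' Names of the 15 candidate features
#'
#' The feature set instantiates five groups: (i) quality bias of alternative
#' bases -- `mean_alt_bqv_vs_med`, `mean_alt_mqv_vs_med`, `bqv_rank_sum_p`,
#' `mqv_rank_sum_p`; (ii) coverage and VAF -- `tumor_depth_vs_med`,
#' `normal_depth_vs_med`, `tumor_vaf`, `normal_vaf`; (iii) location along the
#' read -- `alt_mean_rel_read_pos`, `read_pos_rank_sum_p`,
#' `alt_near_end_frac`; (iv) strand bias -- `strand_bias_fisher_p`,
#' `alt_majority_strand_frac`; (v) others -- `somatic_fisher_p`,
#' `n_alt_alleles`. `_vs_med` features are ratios to background medians
#' sampled from the input pileups; `_rank_sum_p` and `_fisher_p` features
#' compare alt-supporting against ref-supporting observations at the same
#' locus (`vs_ref`).
#'
#' @return Character vector of the 15 feature names, in group order.
#' @export
feature_names <- function() {
  c("mean_alt_bqv_vs_med", "mean_alt_mqv_vs_med", "bqv_rank_sum_p",
    "mqv_rank_sum_p",
    "tumor_depth_vs_med", "normal_depth_vs_med", "tumor_vaf", "normal_vaf",
    "alt_mean_rel_read_pos", "read_pos_rank_sum_p", "alt_near_end_frac",
    "strand_bias_fisher_p", "alt_majority_strand_frac",
    "somatic_fisher_p", "n_alt_alleles")
}

#' Estimate background medians from randomly sampled pileup positions
#'
#' Samples `n_positions` paired loci (uniformly, without replacement when
#' possible) and records the median of the raw, pre-normalization values that
#' the `_vs_med` features are divided by: per-site mean base quality and mean
#' mapping quality of the tumor observations, and tumor/normal declared
#' depth. Deterministic given `seed`.
#'
#' @param pair A `paired_pileup`.
#' @param n_positions Number of loci to sample (>= 100; if fewer usable loci
#'   exist, all are used with a warning).
#' @param seed Integer seed recorded in the result.
#' @return A `background_medians` list with elements `bqv`, `mqv`,
#'   `tumor_depth`, `normal_depth`, `n`, `seed`.
#' @export
sample_background <- function(pair, n_positions = 10000, seed = 1) {
  stopifnot(inherits(pair, "paired_pileup"))
  if (n_positions < 100) stop("n_positions must be >= 100")
  usable <- which(pair$tumor$sites$n_obs[pair$t_idx] > 0)
  if (length(usable) == 0) stop("no usable paired positions with observations")
  n_take <- n_positions
  if (length(usable) < n_positions) {
    warning(sprintf("only %d usable positions available (%d requested); using all",
                    length(usable), n_positions))
    n_take <- length(usable)
  }
  sel <- withr_seed(seed, sample(usable, n_take, replace = FALSE))
  t_idx <- pair$t_idx[sel]
  n_idx <- pair$n_idx[sel]
  o <- pair$tumor$obs[site %in% t_idx]
  mb <- o[, .(bqv = mean(bqv), mqv = mean(mqv)), by = site]
  structure(list(
    bqv = stats::median(mb$bqv),
    mqv = stats::median(mb$mqv),
    tumor_depth = stats::median(as.numeric(pair$tumor$sites$depth[t_idx])),
    normal_depth = stats::median(as.numeric(pair$normal$sites$depth[n_idx])),
    n = n_take, seed = seed
  ), class = "background_medians")
}

# evaluate expr under a local RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Normalize a raw feature value by its background median
#'
#' Returns `raw / max(bg_median, eps)`; the guard constant `eps` keeps the
#' ratio finite when the background median is zero.
#'
#' @param raw Raw feature value(s).
#' @param bg_median Background median from [sample_background()].
#' @param eps Guard constant (default 1e-6).
#' @return `raw / max(bg_median, eps)`.
#' @export
median_normalize <- function(raw, bg_median, eps = 1e-6) {
  raw / max(bg_median, eps)
}

#' Compute the 15-feature matrix for screened candidates
#'
#' For each candidate, alternative-supporting observations (all tumor reads
#' carrying the candidate allele) are compared against reference-supporting
#' observations at the same locus for the quality, read-position and strand
#' features; depth and mean-quality features are normalized by the background
#' medians. Rank tests with an empty reference side return the neutral value
#' 1 (absence of evidence of bias). The read length at a locus is proxied by
#' the maximum observed within-read position there.
#'
#' @param candidates A `candidate_table` from [screen_candidates()].
#' @param pair The `paired_pileup` the candidates came from.
#' @param bg A `background_medians` from [sample_background()].
#' @param end_window Distance (bp) from a read end within which an alt base
#'   counts as near-end (default 5).
#' @return `data.frame` with one row per candidate and the 15 columns of
#'   [feature_names()], all finite.
#' @export
extract_features <- function(candidates, pair, bg, end_window = 5) {
  stopifnot(inherits(bg, "background_medians"))
  n <- nrow(candidates)
  if (n == 0) {
    out <- matrix(numeric(0), 0, 15, dimnames = list(NULL, feature_names()))
    return(as.data.frame(out))
  }

  t_obs <- pair$tumor$obs
  n_obs <- pair$normal$obs
  # positional site -> observation-row index (unnamed: O(1) access by site id)
  t_split <- unname(split(seq_len(nrow(t_obs)),
                          factor(t_obs$site, levels = seq_len(nrow(pair$tumor$sites)))))
  n_split <- unname(split(seq_len(nrow(n_obs)),
                          factor(n_obs$site, levels = seq_len(nrow(pair$normal$sites)))))

  t_allele <- t_obs$allele; t_bqv <- t_obs$bqv; t_mqv <- t_obs$mqv
  t_rpos <- t_obs$read_pos; t_fwd <- t_obs$fwd
  na_allele <- n_obs$allele
  c_tsite <- candidates$t_site
  c_nsite <- candidates$n_site
  c_alt <- candidates$alt; c_ref <- candidates$ref

  v <- lapply(feature_names(), function(x) numeric(n))
  names(v) <- feature_names()
  bqv_med <- max(bg$bqv, 1e-6); mqv_med <- max(bg$mqv, 1e-6)
  td_med <- max(bg$tumor_depth, 1e-6); nd_med <- max(bg$normal_depth, 1e-6)

  for (i in seq_len(n)) {
    idx <- t_split[[c_tsite[i]]]
    al <- t_allele[idx]
    ai <- idx[al == c_alt[i]]
    ri <- idx[al == c_ref[i]]
    has_ref <- length(ri) > 0
    a_rpos <- t_rpos[ai]

    # (i) quality bias of alternative bases
    v$mean_alt_bqv_vs_med[i] <- mean(t_bqv[ai]) / bqv_med
    v$mean_alt_mqv_vs_med[i] <- mean(t_mqv[ai]) / mqv_med
    v$bqv_rank_sum_p[i] <- if (has_ref) rank_sum_test(t_bqv[ai], t_bqv[ri]) else 1
    v$mqv_rank_sum_p[i] <- if (has_ref) rank_sum_test(t_mqv[ai], t_mqv[ri]) else 1
    v$read_pos_rank_sum_p[i] <- if (has_ref) rank_sum_test(a_rpos, t_rpos[ri]) else 1

    # (ii) coverage and VAF
    v$tumor_vaf[i] <- length(ai) / length(idx)
    nidx <- n_split[[c_nsite[i]]]
    v$normal_vaf[i] <-
      if (length(nidx) > 0) sum(na_allele[nidx] == c_alt[i]) / length(nidx) else 0

    # (iii) location along the read
    len_proxy <- max(t_rpos[idx])
    v$alt_mean_rel_read_pos[i] <- mean(a_rpos) / len_proxy
    v$alt_near_end_frac[i] <-
      mean(a_rpos <= end_window | a_rpos > len_proxy - end_window)

    # (iv) strand bias
    af <- sum(t_fwd[ai]); ar <- length(ai) - af
    rf <- sum(t_fwd[ri]); rr <- length(ri) - rf
    v$strand_bias_fisher_p[i] <-
      if (has_ref) fisher_test_2x2(af, ar, rf, rr) else 1
    v$alt_majority_strand_frac[i] <- max(af, ar) / length(ai)

    # (v) others
    v$n_alt_alleles[i] <-
      length(unique(al[al != c_ref[i] & al != "N"]))
  }
  v$tumor_depth_vs_med <- candidates$t_depth / td_med
  v$normal_depth_vs_med <- candidates$n_depth / nd_med
  v$somatic_fisher_p <- candidates$somatic_p
  out <- as.data.frame(v)[feature_names()]
  out
}

#' Write / read the candidate feature table as headered TSV
#'
#' The exchange format between training and calling: locus and allele
#' columns, the 15 features, and an optional `label` column (`TP`/`FP`).
#'
#' @param features Data frame with candidate columns (`chrom`, `pos`, `ref`,
#'   `alt`), the 15 feature columns, and optionally `label`.
#' @param path Output TSV path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the data frame.
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
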