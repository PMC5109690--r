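#' Quality and coverage filter configuration for candidate screening
#'
#' Defaults follow the screening rule for low-pass tumor-normal data: a site
#' is considered only when both samples reach 8X declared coverage and the
#' tumor holds at least one read supporting an alternative allele with base
#' quality >= 20 on a read mapped with quality >= 10.
#'
#' @param min_alt_bqv Minimum phred base quality for an alt-supporting read
#'   to count (default 20).
#' @param min_alt_mqv Minimum phred mapping quality for an alt-supporting
#'   read to count (default 10).
#' @param min_coverage Minimum declared depth required in both tumor and
#'   normal (default 8).
#' @param min_alt_reads Minimum number of quality-passing alt reads in the
#'   tumor (default 1).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_alt_bqv = 20, min_alt_mqv = 10,
                          min_coverage = 8, min_alt_reads = 1) {
  cfg <- list(min_alt_bqv = min_alt_bqv, min_alt_mqv = min_alt_mqv,
              min_coverage = min_coverage, min_alt_reads = min_alt_reads)
  if (any(unlist(cfg) < 0)) stop("filter thresholds must be >= 0")
  structure(cfg, class = "filter_config")
}

#' Screen paired loci for candidate somatic variants
#'
#' Applies the coverage filter (declared depth in both samples), nominates
#' one candidate per distinct tumor alternative allele with at least
#' `min_alt_reads` quality-passing supporting reads, and annotates each
#' candidate with tumor/normal ref and alt read counts and the two-sided
#' Fisher somatic p-value on the 2x2 table
#' `[[tumor_ref, tumor_alt], [normal_ref, normal_alt]]`.
#'
#' Coverage is tested on raw declared depth; the base/mapping-quality
#' thresholds apply only to the reads counted as alternative-allele support.
#' Allele counts for the Fisher test and VAFs use all decoded observations.
#' Sites with reference base `N` are skipped with a warning; `N` base calls
#' never count as alternative alleles.
#'
#' @param pair A `paired_pileup` from [pair_pileups()].
#' @param cfg A [filter_config()].
#' @return A `candidate_table` (data.table): one row per candidate with
#'   `chrom`, `pos`, `ref`, `alt`, tumor/normal counts and depths, `t_site` /
#'   `n_site` indices into the paired pileups, and `somatic_p`.
#' @export
screen_candidates <- function(pair, cfg = filter_config()) {
  stopifnot(inherits(pair, "paired_pileup"), inherits(cfg, "filter_config"))
  ts <- pair$tumor$sites[pair$t_idx]
  ns <- pair$normal$sites[pair$n_idx]

  ok <- ts$depth >= cfg$min_coverage & ns$depth >= cfg$min_coverage
  is_n <- ts$ref == "N"
  if (any(is_n & ok))
    warning(sum(is_n & ok), " site(s) with reference base N skipped")
  ok <- ok & !is_n
  t_sites <- pair$t_idx[ok]
  if (length(t_sites) == 0) return(empty_candidate_table())
  n_of_t <- integer(nrow(pair$tumor$sites))
  n_of_t[pair$t_idx] <- pair$n_idx

  to <- pair$tumor$obs[site %in% t_sites]
  ref_of <- pair$tumor$sites$ref
  to_ref <- ref_of[to$site]
  alt_obs <- to[to$allele != to_ref & to$allele != "N"]
  if (nrow(alt_obs) == 0) return(empty_candidate_table())
  sup <- alt_obs[, .(
    t_alt = .N,
    n_pass = sum(bqv >= cfg$min_alt_bqv & mqv >= cfg$min_alt_mqv)
  ), by = .(site, allele)]
  cand <- sup[n_pass >= cfg$min_alt_reads]
  if (nrow(cand) == 0) return(empty_candidate_table())
  data.table::setorder(cand, site, allele)

  t_ref_n <- to[to$allele == to_ref, .N, by = site]
  cand[, t_ref := 0L]
  cand[t_ref_n, t_ref := i.N, on = "site"]

  n_idx_vec <- n_of_t[cand$site]
  no <- pair$normal$obs[site %in% unique(n_idx_vec)]
  no_ref <- pair$normal$sites$ref[no$site]
  n_ref_n <- no[no$allele == no_ref, .N, by = site]
  cand[, n_site := n_idx_vec]
  cand[, n_ref := 0L]
  cand[n_ref_n, n_ref := i.N, on = c(n_site = "site")]
  n_alt_n <- no[, .N, by = .(site, allele)]
  cand[, n_alt := 0L]
  cand[n_alt_n, n_alt := i.N, on = c(n_site = "site", allele = "allele")]

  out <- data.table::data.table(
    chrom = pair$tumor$sites$chrom[cand$site],
    pos = pair$tumor$sites$pos[cand$site],
    ref = ref_of[cand$site],
    alt = cand$allele,
    t_ref = cand$t_ref, t_alt = cand$t_alt,
    n_ref = cand$n_ref, n_alt = cand$n_alt,
    t_depth = pair$tumor$sites$depth[cand$site],
    n_depth = pair$normal$sites$depth[cand$n_site],
    t_site = cand$site, n_site = cand$n_site
  )
  out[, somatic_p := fisher_test_2x2(t_ref, t_alt, n_ref, n_alt)]
  data.table::setattr(out, "class", c("candidate_table", class(out)))
  out[]
}

empty_candidate_table <- function() {
  out <- data.table::data.table(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    t_ref = integer(), t_alt = integer(), n_ref = integer(), n_alt = integer(),
    t_depth = integer(), n_depth = integer(), t_site = integer(),
    n_site = integer(), somatic_p = numeric()
  )
  data.table::setattr(out, "class", c("candidate_table", class(out)))
  out[]
}

#' Screen a single matched tumor/normal site
#'
#' Convenience wrapper over [screen_candidates()] for one locus.
#'
#' @param tumor,normal `pileup_record`s for the same locus (see
#'   [parse_mpileup_line()]); they must agree on chrom, pos and ref.
#' @param cfg A [filter_config()].
#' @return A `candidate_table` with zero or more rows (one per distinct
#'   passing alternative allele).
#' @export
screen_site <- function(tumor, normal, cfg = filter_config()) {
  stopifnot(inherits(tumor, "pileup_record"), inherits(normal, "pileup_record"))
  as_pileup <- function(r) {
    obs <- data.table::copy(r$observations)
    obs[, site := 1L]
    data.table::setcolorder(obs, "site")
    structure(list(
      sites = data.table::data.table(chrom = r$chrom, pos = r$pos, ref = r$ref,
                                     depth = r$depth, n_obs = nrow(obs),
                                     n_skip = r$depth - nrow(obs)),
      obs = obs
    ), class = "pileup")
  }
  screen_candidates(pair_pileups(as_pileup(tumor), as_pileup(normal)), cfg)
}

#' Read a BED track of regions to exclude
#'
#' BED intervals are 0-based half-open. Only the first three columns are
#' used; malformed lines raise an error naming the line number.
#'
#' @param path Path to a BED file.
#' @return A [GenomicRanges::GRanges] in 1-based inclusive coordinates.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")
  lines <- lines[keep]
  ln <- which(keep)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3)
      stop(sprintf("BED parse error at line %d: expected >= 3 columns", ln[i]))
    s <- suppressWarnings(as.numeric(p[2])); e <- suppressWarnings(as.numeric(p[3]))
    if (is.na(s) || is.na(e) || s < 0 || e < s)
      stop(sprintf("BED parse error at line %d: bad interval [%s, %s)", ln[i], p[2], p[3]))
  }
  chrom <- vapply(parts, `[`, "", 1)
  start0 <- as.numeric(vapply(parts, `[`, "", 2))
  end0 <- as.numeric(vapply(parts, `[`, "", 3))
  nonempty <- end0 > start0
  GenomicRanges::GRanges(chrom[nonempty],
                         IRanges::IRanges(start = start0[nonempty] + 1,
                                          end = end0[nonempty]))
}

#' Drop candidates overlapping exclusion tracks
#'
#' Removes candidates whose 1-based position falls inside any interval of
#' the supplied BED tracks (germline variant sets, blacklisted regions).
#' A candidate at position p overlaps a 0-based half-open interval
#' `[start, end)` iff `start < p <= end`. Drop counts are reported per track
#' via `message()`.
#'
#' @param candidates A `candidate_table`.
#' @param exclude_tracks A list of BED file paths and/or `GRanges` objects
#'   (as from [read_bed()]). An empty list is a no-op.
#' @return The filtered `candidate_table`.
#' @export
region_filter <- function(candidates, exclude_tracks = list()) {
  if (length(exclude_tracks) == 0 || nrow(candidates) == 0) return(candidates)
  gr_cand <- GenomicRanges::GRanges(candidates$chrom,
                                    IRanges::IRanges(candidates$pos, candidates$pos))
  keep <- rep(TRUE, nrow(candidates))
  for (i in seq_along(exclude_tracks)) {
    trk <- exclude_tracks[[i]]
    if (is.character(trk)) trk <- read_bed(trk)
    hit <- GenomicRanges::countOverlaps(gr_cand, trk) > 0
    name <- names(exclude_tracks)[i] %||% as.character(i)
    if (!nzchar(name)) name <- as.character(i)
    message(sprintf("region_filter: track %s drops %d candidate(s)", name,
                    sum(hit & keep)))
    keep <- keep & !hit
  }
  candidates[keep]
}
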