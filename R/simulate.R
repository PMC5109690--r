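#' Configuration for the matched-pileup simulator
#'
#' Describes a matched tumor/normal sequencing scenario: site count,
#' negative-binomial depth per sample, per-base error rate, quality-score
#' distributions of correctly sequenced versus erroneous bases, strand-bias
#' contamination, read geometry, and planted variants. Defaults emulate a
#' low-pass 30X targeted regime with subclonal-to-clonal somatic VAFs in
#' 0.10-0.58.
#'
#' Planted somatic sites carry the alternative allele at the given VAF in
#' the tumor only; planted germline heterozygous sites carry it in both
#' samples at VAF ~0.5. Alt reads at planted sites are real bases and draw
#' their qualities from the true-base distributions; background errors draw
#' from the error distributions, a fraction of error-prone sites place all
#' their error reads on a single strand, and a fraction of error reads is
#' biased towards the read ends.
#'
#' @param n_sites Number of simulated loci.
#' @param depth_mean_tumor,depth_mean_normal Mean depth per sample.
#' @param depth_dispersion Negative-binomial size parameter (larger = less
#'   overdispersed).
#' @param error_rate Per-base probability of a sequencing error.
#' @param bqv_true,bqv_error,mqv_true,mqv_error Length-2 `c(mean, sd)` of the
#'   (normal, rounded, clipped) phred quality distributions.
#' @param strand_bias_frac Fraction of sites whose error reads are confined
#'   to one strand.
#' @param error_end_bias Fraction of error reads placed within 5 bp of a
#'   read end.
#' @param read_length Simulated read length (bp).
#' @param n_somatic,n_germline Number of planted somatic / germline-het sites.
#' @param somatic_vaf Length-2 range (uniform draw) or one VAF per planted
#'   somatic site.
#' @param germline_vaf Expected VAF of germline hets (default 0.5).
#' @param chrom Contig name used in the output.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_sites = 10000,
                              depth_mean_tumor = 30, depth_mean_normal = 30,
                              depth_dispersion = 8,
                              error_rate = 0.01,
                              bqv_true = c(36, 3), bqv_error = c(22, 8),
                              mqv_true = c(55, 5), mqv_error = c(30, 12),
                              strand_bias_frac = 0.3,
                              error_end_bias = 0.4,
                              read_length = 100,
                              n_somatic = 0, n_germline = 0,
                              somatic_vaf = c(0.10, 0.58),
                              germline_vaf = 0.5,
                              chrom = "chr1", seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_sites >= 1, error_rate >= 0, error_rate <= 1,
            strand_bias_frac >= 0, strand_bias_frac <= 1,
            error_end_bias >= 0, error_end_bias <= 1,
            read_length >= 10, n_somatic >= 0, n_germline >= 0,
            all(somatic_vaf > 0), all(somatic_vaf < 1),
            germline_vaf > 0, germline_vaf < 1)
  if (n_somatic + n_germline > n_sites)
    stop("more planted sites than simulated sites")
  structure(cfg, class = "simulation_config")
}

#' Scenario presets for the simulator
#'
#' Presets are shipped as JSON config files under
#' `system.file("extdata/presets", package = "somaticRF")`:
#' `lowpass30x` (30X targeted regime), `wgs90x` (90X whole-genome regime) and
#' `imbalanced-test` (100,000 sites at 30X with 50 planted somatics,
#' VAF 0.10-0.60, 1% error rate -- a severely class-imbalanced calling
#' scenario).
#'
#' @param name Preset name.
#' @param ... Overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
sim_preset <- function(name = c("lowpass30x", "wgs90x", "imbalanced-test"),
                       ...) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".json"),
                      package = "somaticRF", mustWork = TRUE)
  base <- jsonlite::read_json(path, simplifyVector = TRUE)
  base$preset <- NULL
  over <- list(...)
  base[names(over)] <- over
  do.call(simulation_config, base)
}

qdraw <- function(n, ms, lo = 0, hi = 60) {
  pmin(hi, pmax(lo, round(stats::rnorm(n, ms[1], ms[2]))))
}

#' Simulate a matched tumor/normal mpileup pair with known truth
#'
#' Draws per-site depths from a negative binomial, per-read alleles
#' binomially (alt with probability VAF at planted sites, error allele with
#' probability `error_rate` elsewhere), qualities from the configured
#' true/error distributions, strands fairly except at strand-bias
#' contaminated sites, and read positions uniformly with optional end bias
#' for errors. Deterministic given `cfg$seed`: identical configurations
#' produce byte-identical mpileup files.
#'
#' @param cfg A [simulation_config()].
#' @param tumor_path,normal_path Optional output mpileup paths; when given
#'   the serialized pileups are written there.
#' @param truth_path Optional output TSV path for the truth table.
#' @return List with `tumor` and `normal` (`pileup` objects) and `truth`
#'   (data.frame: `chrom`, `pos`, `type` somatic|germline, `vaf`, `ref`,
#'   `alt`).
#' @export
simulate_pair <- function(cfg, tumor_path = NULL, normal_path = NULL,
                          truth_path = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n <- cfg$n_sites
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  pos <- seq_len(n)

  planted <- sample.int(n, cfg$n_somatic + cfg$n_germline)
  som_sites <- utils::head(planted, cfg$n_somatic)
  germ_sites <- utils::tail(planted, cfg$n_germline)
  vaf <- numeric(n)
  if (cfg$n_somatic > 0) {
    sv <- cfg$somatic_vaf
    vaf[som_sites] <- if (length(sv) == cfg$n_somatic && cfg$n_somatic != 2) {
      sv
    } else if (length(sv) == 2) {
      stats::runif(cfg$n_somatic, sv[1], sv[2])
    } else {
      rep_len(sv, cfg$n_somatic)
    }
  }
  vaf[germ_sites] <- cfg$germline_vaf
  biased <- stats::runif(n) < cfg$strand_bias_frac
  biased_fwd <- stats::runif(n) < 0.5

  truth <- data.frame(
    chrom = rep(cfg$chrom, length(planted)), pos = pos[planted],
    type = c(rep("somatic", cfg$n_somatic), rep("germline", cfg$n_germline)),
    vaf = vaf[planted], ref = ref[planted], alt = alt[planted],
    stringsAsFactors = FALSE
  )
  truth <- truth[order(truth$pos), , drop = FALSE]

  sim_sample <- function(depth_mean, carries_variant) {
    depth <- stats::rnbinom(n, size = cfg$depth_dispersion, mu = depth_mean)
    m <- sum(depth)
    site <- rep.int(seq_len(n), depth)
    p_alt <- ifelse(carries_variant, vaf, 0)[site]
    is_alt <- stats::runif(m) < p_alt
    is_err <- !is_alt & stats::runif(m) < cfg$error_rate
    allele <- ref[site]
    allele[is_alt] <- alt[site[is_alt]]
    if (any(is_err)) {
      shift <- sample.int(3, sum(is_err), replace = TRUE)
      allele[is_err] <- bases[(match(ref[site[is_err]], bases) - 1 + shift) %% 4 + 1]
    }
    true_base <- !is_err
    bqv <- integer(m); mqv <- integer(m)
    bqv[true_base] <- qdraw(sum(true_base), cfg$bqv_true, lo = 2)
    bqv[is_err] <- qdraw(sum(is_err), cfg$bqv_error, lo = 2)
    mqv[true_base] <- qdraw(sum(true_base), cfg$mqv_true)
    mqv[is_err] <- qdraw(sum(is_err), cfg$mqv_error)
    fwd <- stats::runif(m) < 0.5
    sel <- is_err & biased[site]
    fwd[sel] <- biased_fwd[site[sel]]
    L <- cfg$read_length
    read_pos <- sample.int(L, m, replace = TRUE)
    end_sel <- is_err & stats::runif(m) < cfg$error_end_bias
    if (any(end_sel)) {
      ends <- c(1:5, (L - 4):L)
      read_pos[end_sel] <- ends[sample.int(10, sum(end_sel), replace = TRUE)]
    }
    structure(list(
      sites = data.table::data.table(chrom = cfg$chrom, pos = pos, ref = ref,
                                     depth = depth, n_obs = depth,
                                     n_skip = 0L),
      obs = data.table::data.table(site = site, allele = allele, fwd = fwd,
                                   bqv = bqv, mqv = mqv, read_pos = read_pos,
                                   is_start = read_pos == 1L,
                                   is_end = read_pos == as.integer(L))
    ), class = "pileup")
  }

  carries_t <- logical(n); carries_t[c(som_sites, germ_sites)] <- TRUE
  carries_n <- logical(n); carries_n[germ_sites] <- TRUE
  tumor <- sim_sample(cfg$depth_mean_tumor, carries_t)
  normal <- sim_sample(cfg$depth_mean_normal, carries_n)

  if (!is.null(tumor_path)) write_mpileup(tumor, tumor_path)
  if (!is.null(normal_path)) write_mpileup(normal, normal_path)
  if (!is.null(truth_path))
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(tumor = tumor, normal = normal, truth = truth)
}

#' Label screened candidates against a simulation truth table
#'
#' A candidate is `TP` when its locus and alternative allele match a planted
#' somatic site; anything else (errors, germline hets, wrong-allele calls at
#' planted loci) is `FP`.
#'
#' @param candidates A `candidate_table`.
#' @param truth Truth table from [simulate_pair()].
#' @return Character vector of `"TP"` / `"FP"`, one per candidate.
#' @export
label_candidates <- function(candidates, truth) {
  som <- truth[truth$type == "somatic", , drop = FALSE]
  key <- paste(candidates$chrom, candidates$pos, candidates$alt)
  ifelse(key %in% paste(som$chrom, som$pos, som$alt), "TP", "FP")
}

#' Randomly thin the coverage of a pileup
#'
#' Keeps every observation independently with probability `keep_fraction`
#' and updates the declared depth to the retained observation count,
#' emulating coverage-reduction experiments (e.g. thinning a 90X dataset to
#' 45X with `keep_fraction = 0.5`). Deterministic given `seed`.
#' `keep_fraction` must lie in (0, 1]; 0 is rejected rather than returning
#' an empty pileup.
#'
#' @param pileup A `pileup` object.
#' @param keep_fraction Probability of retaining each observation.
#' @param seed Integer seed.
#' @return The thinned `pileup` (site list unchanged, depths updated).
#' @export
subsample_coverage <- function(pileup, keep_fraction, seed = 1) {
  stopifnot(inherits(pileup, "pileup"))
  if (!(keep_fraction > 0 && keep_fraction <= 1))
    stop("keep_fraction must be in (0, 1]")
  if (keep_fraction == 1) return(pileup)
  keep <- withr_seed(seed, stats::runif(nrow(pileup$obs)) < keep_fraction)
  obs <- pileup$obs[keep]
  cnt <- tabulate(obs$site, nbins = nrow(pileup$sites))
  sites <- data.table::copy(pileup$sites)
  sites[, `:=`(depth = cnt, n_obs = cnt, n_skip = 0L)]
  structure(list(sites = sites, obs = obs), class = "pileup")
}
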