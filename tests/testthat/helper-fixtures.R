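# Builders for small hand-specified pileup fixtures.

phred_chr <- function(q) intToUtf8(q + 33, multiple = FALSE)

# one mpileup line from per-observation vectors
mk_line <- function(chrom = "chr1", pos = 100, ref = "A",
                    alleles = "A", fwd = TRUE, bqv = 40, mqv = 60,
                    read_pos = NULL, depth = NULL) {
  n <- max(length(alleles), length(fwd), length(bqv), length(mqv))
  alleles <- rep_len(alleles, n); fwd <- rep_len(fwd, n)
  bqv <- rep_len(bqv, n); mqv <- rep_len(mqv, n)
  read_pos <- rep_len(read_pos %||% seq_len(n), n)
  base <- ifelse(alleles == ref,
                 ifelse(fwd, ".", ","),
                 ifelse(fwd, alleles, tolower(alleles)))
  paste(chrom, pos, ref, depth %||% n, paste0(base, collapse = ""),
        phred_chr(bqv), phred_chr(mqv), paste(read_pos, collapse = ","),
        sep = "\t")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a paired pileup built from two vectors of mpileup lines
mk_pair <- function(tumor_lines, normal_lines) {
  pair_pileups(parse_mpileup_lines(tumor_lines),
               parse_mpileup_lines(normal_lines))
}

# separable two-class toy instances: feature "sig" differs by class
mk_toy_instances <- function(n_tp = 20, n_fp = 20, seed = 1, p_extra = 2) {
  set.seed(seed)
  n <- n_tp + n_fp
  label <- c(rep("TP", n_tp), rep("FP", n_fp))
  x <- data.frame(sig = c(rnorm(n_tp, 3), rnorm(n_fp, -3)))
  for (j in seq_len(p_extra)) x[[paste0("noise", j)]] <- rnorm(n)
  training_instances(x, label)
}

# labeled instance table straight from a simulation
sim_instances <- function(cfg, bg_n = 500, bg_seed = 1) {
  sim <- simulate_pair(cfg)
  pair <- pair_pileups(sim$tumor, sim$normal)
  cand <- screen_candidates(pair)
  bg <- sample_background(pair, bg_n, seed = bg_seed)
  feats <- extract_features(cand, pair, bg)
  inst <- training_instances(feats, label_candidates(cand, sim$truth))
  list(instances = inst, candidates = cand, pair = pair, sim = sim, bg = bg)
}
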