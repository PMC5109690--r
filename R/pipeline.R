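#' End-to-end training: screen, featurize, label, train, cross-validate
#'
#' Loads matched mpileups, screens candidates ([screen_candidates()] after
#' optional [region_filter()]), extracts features against background medians
#' sampled from the inputs, joins the orthogonal-validation labels, applies
#' the cost and VAF-interval options, estimates performance by stratified
#' k-fold cross-validation and trains the final forest on all labeled
#' instances. When `out_dir` is given, the model archive (`model.json`),
#' the training curves and the labeled feature table are persisted there.
#'
#' @param tumor,normal mpileup file paths or `pileup` objects.
#' @param labels Label table (data.frame or TSV path) with columns `chrom`,
#'   `pos`, optional `alt`, and `label` (`TP`/`FP`). Candidates without a
#'   label are excluded (count reported); labels at loci absent from the
#'   screened candidates raise a warning.
#' @param out_dir Optional output directory.
#' @param filter A [filter_config()].
#' @param exclude_tracks Optional list of BED paths / `GRanges` for
#'   [region_filter()].
#' @param n_trees,costs,top_k,vaf_interval,k Training options (see
#'   [train_forest()], [filter_vaf_interval()], [cross_validate()]).
#' @param cv Set `FALSE` to skip cross-validation and only fit the final
#'   forest (`report` is then `NULL`).
#' @param bg_positions,seed Background sampling size and master seed.
#' @return List with `model` (`forest_model`), `report`
#'   (`evaluation_report` from cross-validation), and `instances` (the
#'   labeled training table).
#' @export
run_training <- function(tumor, normal, labels, out_dir = NULL,
                         filter = filter_config(), exclude_tracks = list(),
                         n_trees = 300, costs = c(cost_fp = 1, cost_fn = 1),
                         top_k = NULL, vaf_interval = NULL, k = 10,
                         cv = TRUE, bg_positions = 10000, seed = 1) {
  prep <- prepare_candidates(tumor, normal, filter, exclude_tracks,
                             bg_positions, seed)
  if (is.character(labels)) labels <- read_feature_table(labels)
  stopifnot(all(c("chrom", "pos", "label") %in% names(labels)))

  cand <- prep$candidates
  key_c <- if ("alt" %in% names(labels)) {
    paste(cand$chrom, cand$pos, cand$alt)
  } else {
    paste(cand$chrom, cand$pos)
  }
  key_l <- if ("alt" %in% names(labels)) {
    paste(labels$chrom, labels$pos, labels$alt)
  } else {
    paste(labels$chrom, labels$pos)
  }
  hit <- match(key_c, key_l)
  n_unlabeled <- sum(is.na(hit))
  message(sprintf("run_training: %d candidate(s) without a label excluded",
                  n_unlabeled))
  if (any(!(key_l %in% key_c)))
    warning(sum(!(key_l %in% key_c)),
            " labeled locus/loci absent from the screened candidates")
  keep <- !is.na(hit)
  if (!any(keep)) stop("no labeled candidates to train on")
  lab <- labels$label[hit[keep]]
  if (!any(lab == "TP")) stop("no labeled true positives in the training set")
  if (!any(lab == "FP")) stop("no labeled false positives in the training set")

  instances <- training_instances(
    cbind(cand[keep, c("chrom", "pos", "ref", "alt")],
          prep$features[keep, , drop = FALSE]),
    lab)
  if (!is.null(vaf_interval))
    instances <- filter_vaf_interval(instances, vaf_interval[1], vaf_interval[2])

  report <- NULL
  if (isTRUE(cv)) {
    report <- cross_validate(instances, k = k, seed = seed, n_trees = n_trees,
                             costs = costs, top_k = top_k)$report
  }
  model <- train_forest(instances, n_trees = n_trees, seed = seed,
                        costs = costs, top_k = top_k,
                        background = prep$background)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_model(model, file.path(out_dir, "model.json"))
    if (!is.null(report)) write_curves(report, out_dir)
    write_feature_table(instances[setdiff(names(instances), "weight")],
                        file.path(out_dir, "training_features.tsv"))
  }
  list(model = model, report = report, instances = instances)
}

#' End-to-end calling: screen, featurize, classify, write VCF
#'
#' Screens candidates from new matched mpileups, extracts the model's
#' features (background medians are re-sampled from the inputs so `_vs_med`
#' normalization reflects the dataset being called), classifies each
#' candidate with the forest, and writes a VCF 4.2 file with the somatic
#' Fisher p-value, a PASS/REJ prediction and the class probability.
#' Rejected candidates are retained in the output with their probabilities
#' so downstream numeric filtering remains possible.
#'
#' @param model A `forest_model` or the path to a model archive.
#' @param tumor,normal mpileup file paths or `pileup` objects.
#' @param vcf_path Output VCF path (optional).
#' @param filter A [filter_config()].
#' @param exclude_tracks Optional BED exclusion tracks.
#' @param bg_positions Background sampling size.
#' @param seed Seed for background sampling (defaults to the model's).
#' @return The calls data.frame (one row per candidate, sorted by chrom and
#'   position): locus, alleles, counts, VAFs, `somatic_p`, `filter`
#'   (PASS/REJ) and `class_prob` in `[0.5, 1]`.
#' @export
run_calling <- function(model, tumor, normal, vcf_path = NULL,
                        filter = filter_config(), exclude_tracks = list(),
                        bg_positions = 10000, seed = NULL) {
  if (is.character(model)) model <- read_model(model)
  stopifnot(inherits(model, "forest_model"))
  seed <- seed %||% model$seed
  prep <- prepare_candidates(tumor, normal, filter, exclude_tracks,
                             bg_positions, seed)
  cand <- prep$candidates
  if (nrow(cand) == 0) {
    calls <- empty_calls_table()
  } else {
    pred <- predict(model, prep$features)
    calls <- data.frame(
      chrom = cand$chrom, pos = cand$pos, ref = cand$ref, alt = cand$alt,
      t_depth = cand$t_depth, t_ref = cand$t_ref, t_alt = cand$t_alt,
      n_depth = cand$n_depth, n_ref = cand$n_ref, n_alt = cand$n_alt,
      t_vaf = prep$features$tumor_vaf, n_vaf = prep$features$normal_vaf,
      somatic_p = cand$somatic_p,
      filter = ifelse(pred$label == "TP", "PASS", "REJ"),
      class_prob = pred$probability,
      stringsAsFactors = FALSE
    )
    calls <- calls[order(calls$chrom, calls$pos, calls$alt), , drop = FALSE]
    rownames(calls) <- NULL
  }
  if (!is.null(vcf_path)) write_vcf(calls, vcf_path)
  calls
}

empty_calls_table <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), t_depth = integer(), t_ref = integer(),
             t_alt = integer(), n_depth = integer(), n_ref = integer(),
             n_alt = integer(), t_vaf = numeric(), n_vaf = numeric(),
             somatic_p = numeric(), filter = character(),
             class_prob = numeric(), stringsAsFactors = FALSE)
}

# shared front half of training and calling
prepare_candidates <- function(tumor, normal, filter, exclude_tracks,
                               bg_positions, seed) {
  if (is.character(tumor)) tumor <- read_mpileup(tumor)
  if (is.character(normal)) normal <- read_mpileup(normal)
  pair <- pair_pileups(tumor, normal)
  cand <- screen_candidates(pair, filter)
  cand <- region_filter(cand, exclude_tracks)
  if (nrow(cand) == 0) {
    return(list(pair = pair, candidates = cand, features = NULL,
                background = NULL))
  }
  bg <- sample_background(pair, n_positions = bg_positions, seed = seed)
  feats <- extract_features(cand, pair, bg)
  list(pair = pair, candidates = cand, features = feats, background = bg)
}

#' Write somatic calls as VCF 4.2
#'
#' One record per candidate; the FILTER column carries the forest prediction
#' (`PASS` for predicted somatic variants, `REJ` for predicted errors), INFO
#' carries `SPV` (two-sided Fisher somatic p-value) and `CP` (class
#' probability, 0.5-1), and per-sample FORMAT fields are `DP:AD:VAF` with
#' `AD` as ref,alt counts for the TUMOR and NORMAL columns. Output is
#' byte-deterministic for identical calls.
#'
#' @param calls Calls data.frame from [run_calling()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path) {
  fmt_num <- function(x) sprintf("%.6g", x)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=somaticRF",
    "##INFO=<ID=SPV,Number=1,Type=Float,Description=\"Two-sided Fisher exact somatic p-value (tumor vs normal ref/alt counts)\">",
    "##INFO=<ID=CP,Number=1,Type=Float,Description=\"Random Forest class probability of the assigned label (0.5-1)\">",
    "##FILTER=<ID=REJ,Description=\"Candidate classified as sequencing error by the Random Forest\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Declared read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read counts for the ref and alt alleles\">",
    "##FORMAT=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency over decoded observations\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "TUMOR", "NORMAL", sep = "\t")
  )
  if (nrow(calls) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  body <- paste(
    calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
    calls$filter,
    paste0("SPV=", fmt_num(calls$somatic_p), ";CP=", fmt_num(calls$class_prob)),
    "DP:AD:VAF",
    paste0(calls$t_depth, ":", calls$t_ref, ",", calls$t_alt, ":",
           fmt_num(calls$t_vaf)),
    paste0(calls$n_depth, ":", calls$n_ref, ",", calls$n_alt, ":",
           fmt_num(calls$n_vaf)),
    sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
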