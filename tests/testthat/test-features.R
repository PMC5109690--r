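test_that("rank_sum_test handles identity, separation and invariances", {
  expect_equal(rank_sum_test(c(3, 1, 2), c(2, 1, 3)), 1.0)
  expect_equal(rank_sum_test(c(1, 2, 3), c(10, 11, 12)),
               oracle_ranksum_p(c(1, 2, 3), c(10, 11, 12)), tolerance = 1e-12)
  xs <- c(1.5, 2.2, 9); ys <- c(0.3, 4.4)
  expect_equal(rank_sum_test(xs, ys), rank_sum_test(xs + 100, ys + 100))
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("exact rank-sum p matches enumeration on small tie-free samples", {
  set.seed(11)
  for (i in 1:15) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    v <- sample(1000, n1 + n2)           # distinct -> tie-free
    xs <- v[seq_len(n1)]; ys <- v[-seq_len(n1)]
    expect_equal(rank_sum_test(xs, ys), oracle_ranksum_p(xs, ys),
                 tolerance = 1e-12, info = paste("case", i))
  }
})

test_that("tied samples fall back to the midrank normal approximation", {
  xs <- c(rep(30, 10), rep(35, 5)); ys <- c(rep(30, 5), rep(35, 10))
  p_mine <- rank_sum_test(xs, ys)
  p_ref <- suppressWarnings(stats::wilcox.test(xs, ys, correct = TRUE))$p.value
  expect_equal(p_mine, p_ref, tolerance = 1e-9)
})

test_that("median normalization and its zero guards", {
  expect_equal(median_normalize(30, 30), 1.0)
  expect_equal(median_normalize(0, 17), 0.0)
  expect_equal(median_normalize(5, 0), 5 / 1e-6)
})

test_that("background medians are deterministic and track the depth distribution", {
  cfg <- simulation_config(n_sites = 1500, depth_mean_tumor = 30,
                           depth_mean_normal = 30, depth_dispersion = 1e6,
                           error_rate = 0, seed = 2)
  sim <- simulate_pair(cfg)
  pair <- pair_pileups(sim$tumor, sim$normal)
  b1 <- sample_background(pair, 1000, seed = 5)
  b2 <- sample_background(pair, 1000, seed = 5)
  expect_identical(b1, b2)
  # near-constant depth model: median depth ~ mean
  expect_lt(abs(b1$tumor_depth - 30), 2)
  expect_lt(abs(b1$bqv - 36), 2)
  expect_error(sample_background(pair, 50, seed = 1), ">= 100")
})

test_that("background sampling with fewer usable loci than requested warns and proceeds", {
  cfg <- simulation_config(n_sites = 200, error_rate = 0, seed = 2)
  sim <- simulate_pair(cfg)
  pair <- pair_pileups(sim$tumor, sim$normal)
  expect_warning(b <- sample_background(pair, 5000, seed = 1), "available")
  expect_lte(b$n, 200)
})

feature_fixture <- function() {
  # tumor: 16 ref + 4 alt (alt all forward); normal clean
  tum <- mk_line(pos = 100, ref = "A",
                 alleles = c(rep("A", 16), rep("T", 4)),
                 fwd = c(rep(c(TRUE, FALSE), 8), rep(TRUE, 4)),
                 bqv = c(rep(40, 16), rep(35, 4)),
                 mqv = 60, read_pos = c(1:16, 40, 45, 50, 55))
  nor <- mk_line(pos = 100, ref = "A", alleles = rep("A", 30))
  filler_t <- vapply(300:420, function(p) mk_line(pos = p, ref = "C",
                                                  alleles = rep("C", 10)), "")
  filler_n <- vapply(300:420, function(p) mk_line(pos = p, ref = "C",
                                                  alleles = rep("C", 10)), "")
  pair <- mk_pair(c(tum, filler_t), c(nor, filler_n))
  cand <- screen_candidates(pair)
  bg <- suppressWarnings(sample_background(pair, 100, seed = 1))
  list(pair = pair, cand = cand, bg = bg,
       feats = extract_features(cand, pair, bg))
}

test_that("feature vector instantiates the five groups correctly on a hand case", {
  fx <- feature_fixture()
  f <- fx$feats
  expect_equal(nrow(f), 1)
  expect_named(f, feature_names())
  expect_equal(f$tumor_vaf, 4 / 20)
  expect_equal(f$normal_vaf, 0)
  # all 4 alt reads forward vs ref 8/8 -> Fisher on [[4,0],[8,8]]
  expect_equal(f$strand_bias_fisher_p, oracle_fisher_p(4, 0, 8, 8),
               tolerance = 1e-12)
  expect_equal(f$alt_majority_strand_frac, 1)
  expect_equal(f$n_alt_alleles, 1)
  expect_equal(f$somatic_fisher_p, oracle_fisher_p(16, 4, 30, 0),
               tolerance = 1e-12)
  # read length proxy is the max observed read position (55)
  expect_equal(f$alt_mean_rel_read_pos, mean(c(40, 45, 50, 55)) / 55)
  expect_equal(f$alt_near_end_frac, 0.25)   # only pos 55 is within 5bp of end
  expect_true(all(is.finite(as.matrix(f))))
})

test_that("identical alt and ref quality multisets give neutral rank-sum p", {
  tum <- mk_line(pos = 100, ref = "A",
                 alleles = c(rep("A", 10), rep("T", 10)),
                 bqv = rep(c(30, 32, 34, 36, 38), 4))
  nor <- mk_line(pos = 100, ref = "A", alleles = rep("A", 30))
  pair <- mk_pair(tum, nor)
  cand <- screen_candidates(pair)
  bg <- suppressWarnings(sample_background(pair, 100, seed = 1))
  f <- extract_features(cand, pair, bg)
  expect_equal(f$bqv_rank_sum_p, 1.0)
})

test_that("an all-alt site imputes neutral values for vs_ref comparisons", {
  tum <- mk_line(pos = 100, ref = "A", alleles = rep("T", 12))
  nor <- mk_line(pos = 100, ref = "A", alleles = rep("A", 12))
  pair <- mk_pair(tum, nor)
  cand <- screen_candidates(pair)
  bg <- suppressWarnings(sample_background(pair, 100, seed = 1))
  f <- extract_features(cand, pair, bg)
  expect_equal(f$bqv_rank_sum_p, 1.0)
  expect_equal(f$mqv_rank_sum_p, 1.0)
  expect_equal(f$strand_bias_fisher_p, 1.0)
  expect_equal(f$tumor_vaf, 1.0)
})

test_that("observation order within a locus does not change the features", {
  cfg <- simulation_config(n_sites = 300, n_somatic = 8, error_rate = 0.05,
                           seed = 9)
  sim <- simulate_pair(cfg)
  pair <- pair_pileups(sim$tumor, sim$normal)
  cand <- screen_candidates(pair)
  bg <- suppressWarnings(sample_background(pair, 200, seed = 1))
  f1 <- extract_features(cand, pair, bg)
  # shuffle observations within each tumor site
  set.seed(4)
  obs <- pair$tumor$obs
  perm <- unlist(lapply(split(seq_len(nrow(obs)), obs$site),
                        function(ix) ix[sample.int(length(ix))]),
                 use.names = FALSE)
  pair$tumor$obs <- obs[perm][order(site)]
  f2 <- extract_features(cand, pair, bg)
  expect_equal(f1, f2)
})

test_that("every fuzz-generated candidate yields a finite feature vector", {
  cfg <- simulation_config(n_sites = 800, n_somatic = 15, n_germline = 15,
                           error_rate = 0.08, strand_bias_frac = 0.6,
                           error_end_bias = 0.8, seed = 13)
  sim <- simulate_pair(cfg)
  pair <- pair_pileups(sim$tumor, sim$normal)
  cand <- screen_candidates(pair)
  expect_gt(nrow(cand), 50)
  bg <- suppressWarnings(sample_background(pair, 500, seed = 1))
  f <- extract_features(cand, pair, bg)
  m <- as.matrix(f)
  expect_true(all(is.finite(m)))
  pcols <- c("bqv_rank_sum_p", "mqv_rank_sum_p", "read_pos_rank_sum_p",
             "strand_bias_fisher_p", "somatic_fisher_p", "tumor_vaf",
             "normal_vaf")
  expect_true(all(m[, pcols] >= 0 & m[, pcols] <= 1))
})

test_that("feature tables round-trip through TSV", {
  fx <- feature_fixture()
  tab <- cbind(fx$cand[, c("chrom", "pos", "ref", "alt")], fx$feats,
               label = "TP")
  path <- tempfile(fileext = ".tsv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(back$tumor_vaf, tab$tumor_vaf)
  expect_equal(back$label, "TP")
  expect_equal(ncol(back), ncol(tab))
})
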