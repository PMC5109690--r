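test_that("information gain reproduces direct entropy arithmetic", {
  expect_equal(information_gain(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1.0)
  expect_equal(information_gain(c(1, 0, 1, 0), c(1, 1, 0, 0)), 0.0)
  # H(3/4) - 1/2*H(1) - 1/2*H(1/2)
  h <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  expect_equal(information_gain(c(1, 1, 0, 0), c(1, 1, 1, 0)),
               h(0.25) - 0.5 * 0 - 0.5 * h(0.5), tolerance = 1e-12)
  expect_equal(information_gain(rep(3, 6), c(1, 1, 1, 0, 0, 0)), 0)
  expect_equal(information_gain(c(5, 7, 1), c("a", "a", "a")), 0)
})

test_that("information gain matches the threshold oracle on randomized small sets", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(6:14, 1)
    x <- sample(0:3, n, replace = TRUE)
    y <- sample(c("TP", "FP"), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c("TP", "FP")
    expect_equal(information_gain(x, y), oracle_ig_threshold(x, y),
                 tolerance = 1e-12, info = paste("case", i))
    # and is bounded by the class entropy
    expect_lte(information_gain(x, y),
               oracle_entropy(as.vector(table(y)) / n) + 1e-12)
  }
})

test_that("discrete features condition on values directly", {
  x <- c("u", "u", "v", "v", "w", "w")
  y <- c(1, 1, 0, 0, 1, 0)
  expect_equal(information_gain(x, y), oracle_ig_discrete(x, y),
               tolerance = 1e-12)
})

test_that("feature ranking orders by IG with alphabetical tie-break", {
  y <- rep(c("TP", "FP"), each = 10)
  x <- data.frame(perfect = as.numeric(y == "TP") * 2,
                  zzz_const = rep(1, 20),
                  aaa_const = rep(5, 20),
                  noisy = c(rnorm(10, 0.3), rnorm(10)))
  r <- rank_features(x, y)
  expect_equal(r$feature[1], "perfect")
  expect_equal(r$ig[1], 1.0)
  consts <- r[r$ig == 0, "feature"]
  expect_equal(consts, sort(consts))
})

test_that("cost reweighting scales class weights without changing counts", {
  inst <- mk_toy_instances(250, 250)
  same <- apply_costs(inst, 1, 1)
  expect_equal(same$weight, inst$weight)
  w <- apply_costs(inst, 10, 1)
  expect_equal(nrow(w), 500)
  expect_equal(sum(w$weight[w$label == "FP"]), 2500)
  expect_equal(sum(w$weight[w$label == "TP"]), 250)
  expect_error(apply_costs(inst, 0, 1), "positive")
})

test_that("a stronger FP cost lowers the trained model's hard false-call rate", {
  # quality distributions chosen to overlap so the baseline false-call rate
  # is off the floor and the cost effect is visible
  cfg <- simulation_config(n_sites = 20000, n_somatic = 150,
                           error_rate = 0.05, bqv_error = c(30, 6),
                           mqv_error = c(45, 8), seed = 777)
  inst <- sim_instances(cfg, bg_n = 2000, bg_seed = 1)$instances
  set.seed(3)
  tp <- which(inst$label == "TP"); fp <- which(inst$label == "FP")
  train_idx <- c(sample(tp, 100), sample(fp, 4000))
  train <- inst[train_idx, ]
  test <- inst[-train_idx, ]
  rate <- vapply(c(1, 5, 10), function(cost) {
    mean(vapply(1:5, function(s) {
      m <- train_forest(train, n_trees = 100, seed = s,
                        costs = c(cost_fp = cost, cost_fn = 1))
      mean(predict(m, test)$label[test$label == "FP"] == "TP")
    }, 0))
  }, 0)
  expect_lt(rate[2], rate[1])
  expect_lt(rate[3], rate[2])
})

test_that("VAF-interval restriction keeps the requested band", {
  inst <- mk_toy_instances(3, 3)
  inst$tumor_vaf <- c(0.1, 0.5, 0.9, 0.1, 0.5, 0.9)
  expect_equal(nrow(filter_vaf_interval(inst, 0, 1)), 6)
  expect_equal(filter_vaf_interval(inst, 0.4, 0.6)$tumor_vaf, c(0.5, 0.5))
  expect_error(filter_vaf_interval(inst, 0.5, 0.5), "lo < hi")
  expect_error(filter_vaf_interval(inst, 0.95, 0.99), "widen")
})

test_that("features per node follow floor(log2(M)) + 1", {
  inst15 <- mk_toy_instances(15, 15, p_extra = 14)
  names(inst15)[1:15] <- paste0("f", 1:15)
  m15 <- train_forest(inst15, n_trees = 5, seed = 1,
                      features = paste0("f", 1:15))
  expect_equal(m15$features_per_node, 4L)
  inst16 <- mk_toy_instances(15, 15, p_extra = 15)
  names(inst16)[1:16] <- paste0("f", 1:16)
  m16 <- train_forest(inst16, n_trees = 5, seed = 1,
                      features = paste0("f", 1:16))
  expect_equal(m16$features_per_node, 5L)
})

test_that("a perfectly separating feature drives the oob error to zero", {
  inst <- mk_toy_instances(40, 40, seed = 3)
  m <- train_forest(inst, n_trees = 60, seed = 2)
  expect_equal(m$oob_error, 0)
  pred <- predict(m, inst)
  expect_equal(pred$label, inst$label)
  expect_true(all(pred$probability >= 0.5 & pred$probability <= 1))
})

test_that("prediction votes turn into labels and probabilities as specified", {
  leaf <- function(cls) list(feature = -1L, threshold = 0, left = -1L,
                             right = -1L, pred = cls)
  mk_model <- function(preds) {
    structure(list(version = "somaticRF-model-1",
                   trees = lapply(preds, leaf),
                   n_trees = length(preds), features_per_node = 1L,
                   selected_features = "sig", oob_error = 0, seed = 1L,
                   class_costs = c(cost_fp = 1, cost_fn = 1)),
              class = "forest_model")
  }
  fv <- data.frame(sig = 0)
  all_tp <- predict(mk_model(rep(1L, 300)), fv)
  expect_equal(all_tp$label, "TP")
  expect_equal(all_tp$probability, 1.0)
  mostly <- predict(mk_model(rep(c(1L, 0L), c(180, 120))), fv)
  expect_equal(mostly$label, "TP")
  expect_equal(mostly$probability, 0.6)
  tie <- predict(mk_model(rep(c(1L, 0L), c(150, 150))), fv)
  expect_equal(tie$label, "FP")      # exact ties resolve conservatively
  expect_equal(tie$probability, 0.5)
})

test_that("missing features are reported by name at prediction time", {
  inst <- mk_toy_instances(10, 10)
  m <- train_forest(inst, n_trees = 10, seed = 1)
  expect_error(predict(m, data.frame(noise1 = 1, noise2 = 2)), "sig")
})

test_that("training is reproducible and sensitive to the seed", {
  inst <- sim_instances(simulation_config(n_sites = 400, n_somatic = 10,
                                          error_rate = 0.05, seed = 6),
                        bg_n = 300)$instances
  m1 <- train_forest(inst, n_trees = 25, seed = 7)
  m2 <- train_forest(inst, n_trees = 25, seed = 7)
  expect_identical(m1$trees, m2$trees)
  expect_identical(m1$oob_error, m2$oob_error)
  m3 <- train_forest(inst, n_trees = 25, seed = 8)
  expect_false(identical(m1$trees, m3$trees))
})

test_that("degenerate training inputs are rejected", {
  inst <- mk_toy_instances(10, 10)
  expect_error(train_forest(inst[inst$label == "TP", ], n_trees = 5),
               "both")
  expect_error(train_forest(inst[1, ], n_trees = 5), ">= 2")
})

test_that("cross-validation folds are stratified, seeded and validated", {
  inst <- mk_toy_instances(15, 30, seed = 2)
  cv1 <- cross_validate(inst, k = 5, seed = 3, n_trees = 15)
  cv2 <- cross_validate(inst, k = 5, seed = 3, n_trees = 15)
  expect_identical(cv1$fold, cv2$fold)
  expect_identical(cv1$scores, cv2$scores)
  for (f in 1:5) {
    expect_equal(sum(inst$label == "TP" & cv1$fold == f), 3)
  }
  expect_error(cross_validate(inst, k = 1), ">= 2")
  expect_error(cross_validate(inst, k = 16), "minority")
})

test_that("maximal stratified folds on separable instances classify everything correctly", {
  inst <- mk_toy_instances(5, 5, seed = 4)
  cv <- cross_validate(inst, k = 5, seed = 1, n_trees = 30)
  expect_equal(cv$report$roc_auc, 1.0)
  expect_equal(sum(diag(cv$report$confusion)), 10)
})

test_that("the model archive round-trips and is byte-stable", {
  inst <- mk_toy_instances(12, 12, seed = 5)
  m <- train_forest(inst, n_trees = 20, seed = 9)
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  write_model(m, p1); write_model(m, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_model(p1)
  expect_equal(back$selected_features, m$selected_features)
  expect_equal(back$oob_error, m$oob_error)
  x <- mk_toy_instances(30, 30, seed = 6)
  expect_identical(predict(back, x), predict(m, x))
  bad <- m; bad$version <- "not-a-model"
  pbad <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(bad)["version"], pbad, auto_unbox = TRUE)
  expect_error(read_model(pbad), "version")
})

test_that("the forest matches an established RF implementation on the same data", {
  skip_if_not_installed("ranger")
  dat <- sim_instances(simulation_config(n_sites = 1500, n_somatic = 40,
                                         error_rate = 0.05, seed = 31),
                       bg_n = 500)
  inst <- dat$instances
  m <- train_forest(inst, n_trees = 100, seed = 1)
  mine <- roc_pr_curves(predict(m, inst)$tp_vote_frac, inst$label)
  rf <- ranger::ranger(
    x = inst[feature_names()], y = factor(inst$label),
    num.trees = 100, probability = TRUE, seed = 1)
  theirs <- roc_pr_curves(rf$predictions[, "TP"], inst$label)
  # both separate planted somatics from errors on in-sample votes
  expect_gt(mine$roc_auc, 0.95)
  expect_gt(theirs$roc_auc, 0.95)
  expect_lt(abs(mine$roc_auc - theirs$roc_auc), 0.05)
})
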