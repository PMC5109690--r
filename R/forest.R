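#' Assemble a training table from features and labels
#'
#' @param features Data frame containing the 15 feature columns (extra
#'   columns such as locus identifiers are carried through).
#' @param labels Character/factor vector of `"TP"` / `"FP"`, one per row.
#' @param weights Optional positive instance weights (default 1).
#' @return The training data frame with `label` and `weight` columns.
#' @export
training_instances <- function(features, labels, weights = NULL) {
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  if (!all(labels %in% c("TP", "FP")))
    stop("labels must be 'TP' or 'FP'")
  w <- weights %||% rep(1, length(labels))
  if (any(w <= 0)) stop("instance weights must be positive")
  out <- as.data.frame(features)
  out$label <- labels
  out$weight <- w
  out
}

#' Reweight training instances by misclassification cost
#'
#' Implements cost-sensitive learning for unbalanced training sets: the
#' weight of every FP-class instance is scaled by `cost_fp` (the cost of
#' calling an error a variant) and every TP-class instance by `cost_fn`.
#' A stronger cost on false positives pushes the forest towards conservative
#' calling. The instance count is unchanged; weights enter training through
#' the weighted bootstrap and weighted split entropy.
#'
#' @param instances Training table from [training_instances()].
#' @param cost_fp,cost_fn Positive multiplicative costs.
#' @return The reweighted training table.
#' @export
apply_costs <- function(instances, cost_fp = 1, cost_fn = 1) {
  if (cost_fp <= 0 || cost_fn <= 0) stop("costs must be positive")
  stopifnot(all(c("label", "weight") %in% names(instances)))
  instances$weight <- instances$weight *
    ifelse(instances$label == "FP", cost_fp, cost_fn)
  instances
}

#' Restrict training to a tumor-VAF interval
#'
#' Keeps instances whose `tumor_vaf` feature lies in `[lo, hi]`, for targeted
#' training on e.g. a subclonal frequency band.
#'
#' @param instances Training table.
#' @param lo,hi VAF bounds with `0 <= lo < hi <= 1`.
#' @return The subset; an empty result is an error suggesting a wider
#'   interval.
#' @export
filter_vaf_interval <- function(instances, lo = 0, hi = 1) {
  if (!(lo >= 0 && lo < hi && hi <= 1))
    stop("require 0 <= lo < hi <= 1")
  keep <- instances$tumor_vaf >= lo & instances$tumor_vaf <= hi
  if (!any(keep))
    stop("no instances with tumor VAF in [", lo, ", ", hi,
         "]; widen the interval")
  instances[keep, , drop = FALSE]
}

#' Train the cost-sensitive Random Forest
#'
#' Grows `n_trees` unpruned binary trees. Each tree is fitted on a bootstrap
#' sample of the same size as the training set, drawn with replacement with
#' probability proportional to instance weight (so cost reweighting shifts
#' the effective class distribution). At each node,
#' `floor(log2(M)) + 1` of the M usable features are drawn at random and the
#' split maximizing weighted information gain over midpoint thresholds is
#' taken; growth stops at purity or zero gain. The out-of-bag (oob) error --
#' the majority-vote error of each instance over the trees whose bootstrap
#' excluded it -- is stored as an unbiased estimate of classification error.
#'
#' @param instances Training table from [training_instances()] (optionally
#'   passed through [apply_costs()] / [filter_vaf_interval()]).
#' @param n_trees Number of trees (default 300).
#' @param seed Integer seed; results are reproducible given
#'   (instances, seed, hyperparameters).
#' @param costs Length-2 vector `c(cost_fp, cost_fn)` applied to the
#'   instance weights before training (default `c(1, 1)`).
#' @param top_k Optional dimensionality reduction: keep only the `top_k`
#'   features by information gain.
#' @param features Feature columns to use (default [feature_names()]
#'   intersected with available columns).
#' @param background Optional `background_medians` to store in the model for
#'   provenance.
#' @return A `forest_model`: trees, `n_trees`, `features_per_node`,
#'   `selected_features`, IG ranking, `background`, `oob_error`, `seed`,
#'   `class_costs`.
#' @export
train_forest <- function(instances, n_trees = 300, seed = 1,
                         costs = c(cost_fp = 1, cost_fn = 1),
                         top_k = NULL, features = NULL, background = NULL) {
  stopifnot(n_trees >= 1, all(c("label", "weight") %in% names(instances)))
  if (nrow(instances) < 2) stop("need >= 2 training instances")
  if (length(unique(instances$label)) < 2)
    stop("training requires both TP and FP instances")
  instances <- apply_costs(instances, costs[[1]], costs[[2]])

  features <- features %||% default_feature_cols(instances)
  missing <- setdiff(features, names(instances))
  if (length(missing))
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  ranking <- rank_features(instances[features], instances$label,
                           instances$weight)
  if (!is.null(top_k)) {
    stopifnot(top_k >= 1)
    features <- ranking$feature[seq_len(min(top_k, nrow(ranking)))]
  }

  x <- as.matrix(instances[features])
  if (!all(is.finite(x))) stop("non-finite feature values in training set")
  y <- as.integer(instances$label == "TP")
  mtry <- floor(log2(length(features))) + 1
  fit <- withr_seed(seed, .cpp_grow_forest(x, y, instances$weight,
                                           as.integer(n_trees),
                                           as.integer(mtry)))
  structure(list(
    version = "somaticRF-model-1",
    trees = fit$trees,
    n_trees = as.integer(n_trees),
    features_per_node = as.integer(mtry),
    selected_features = features,
    ig_ranking = ranking,
    background = background,
    oob_error = fit$oob_error,
    seed = as.integer(seed),
    class_costs = c(cost_fp = unname(costs[[1]]), cost_fn = unname(costs[[2]])),
    n_instances = nrow(instances)
  ), class = "forest_model")
}

# canonical 15 features when present, otherwise every numeric non-bookkeeping
# column, so ad-hoc feature tables train too
default_feature_cols <- function(instances) {
  canon <- intersect(feature_names(), names(instances))
  if (length(canon)) return(canon)
  reserved <- c("label", "weight", "chrom", "pos", "ref", "alt")
  cols <- setdiff(names(instances)[vapply(instances, is.numeric, TRUE)],
                  reserved)
  if (!length(cols)) stop("no usable feature columns in the training table")
  cols
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf(paste0("<forest_model> %d trees, %d features (%d per node), ",
                     "oob error %.4f, seed %d\n"),
              x$n_trees, length(x$selected_features), x$features_per_node,
              x$oob_error, x$seed))
  invisible(x)
}

#' Predict candidate classes with a trained forest
#'
#' Each tree casts one vote; the label is the majority vote with exact ties
#' resolved to FP (conservative for somatic calling). The reported class
#' probability is the vote fraction of the assigned label, hence in
#' `[0.5, 1]`; `tp_vote_frac` (in `[0, 1]`) is the score used for
#' threshold-sweep evaluation.
#'
#' @param object A `forest_model`.
#' @param newdata Data frame or matrix holding the model's selected feature
#'   columns; a missing feature raises an error naming it.
#' @param ... Unused.
#' @return `data.frame` with `label` (`TP`/`FP`), `probability` (in
#'   `[0.5, 1]`) and `tp_vote_frac`.
#' @export
predict.forest_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$selected_features, names(newdata))
  if (length(missing))
    stop("newdata lacks model feature(s): ", paste(missing, collapse = ", "))
  x <- as.matrix(newdata[object$selected_features])
  votes1 <- .cpp_predict_forest(object$trees, x)
  frac <- votes1 / object$n_trees
  tp <- 2 * votes1 > object$n_trees    # exact tie -> FP
  data.frame(label = ifelse(tp, "TP", "FP"),
             probability = ifelse(tp, frac, 1 - frac),
             tp_vote_frac = frac,
             stringsAsFactors = FALSE)
}

#' Stratified k-fold cross-validation of the forest
#'
#' Splits instances into k folds stratified by class, trains on k-1 folds
#' and scores the held-out fold, then pools all out-of-fold TP vote
#' fractions into a single [roc_pr_curves()] evaluation. Deterministic
#' given `seed`.
#'
#' @param instances Training table.
#' @param k Number of folds (default 10); must be `>= 2` and no larger than
#'   the minority class count.
#' @param seed Integer seed controlling fold assignment and tree growth.
#' @param ... Passed to [train_forest()] (e.g. `n_trees`, `costs`, `top_k`).
#' @return List with the pooled `report` (an `evaluation_report`), the
#'   out-of-fold `scores`, `labels`, and the fold assignment `fold`.
#' @export
cross_validate <- function(instances, k = 10, seed = 1, ...) {
  n <- nrow(instances)
  if (k < 2) stop("k must be >= 2")
  counts <- table(instances$label)
  if (length(counts) < 2) stop("both classes must be present")
  if (k > min(counts))
    stop("k = ", k, " exceeds the minority class count (", min(counts), ")")
  fold <- integer(n)
  fold_of <- withr_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(instances$label == cl)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
  scores <- numeric(n)
  for (f in seq_len(k)) {
    test <- fold_of == f
    model <- train_forest(instances[!test, , drop = FALSE],
                          seed = seed + f, ...)
    scores[test] <- predict(model, instances[test, , drop = FALSE])$tp_vote_frac
  }
  report <- roc_pr_curves(scores, instances$label)
  list(report = report, scores = scores, labels = instances$label,
       fold = fold_of)
}

#' Save / load a forest model archive
#'
#' The archive is a versioned, self-describing JSON document holding the
#' trees, selected features, IG ranking, background medians, costs and seed.
#' Numbers are written at full precision, so a reloaded model reproduces the
#' original predictions exactly and identical training runs produce
#' byte-identical archives.
#'
#' @param model A `forest_model`.
#' @param path Output (input) file path.
#' @return `write_model` returns `path` invisibly; `read_model` the restored
#'   `forest_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "forest_model"))
  obj <- unclass(model)
  obj$ig_ranking <- as.list(obj$ig_ranking)
  if (!is.null(obj$background)) obj$background <- unclass(obj$background)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$version, "somaticRF-model-1"))
    stop("unrecognized model archive version: ", obj$version)
  obj$trees <- lapply(seq_len(nrow_trees(obj$trees)), function(i) tree_i(obj$trees, i))
  obj$ig_ranking <- as.data.frame(obj$ig_ranking, stringsAsFactors = FALSE)
  if (!is.null(obj$background))
    obj$background <- structure(obj$background, class = "background_medians")
  obj$class_costs <- unlist(obj$class_costs)
  structure(obj, class = "forest_model")
}

# jsonlite simplifies the tree list either to a data.frame of list-columns
# or leaves it as a list; normalise both shapes
nrow_trees <- function(trees) if (is.data.frame(trees)) nrow(trees) else length(trees)
tree_i <- function(trees, i) {
  t <- if (is.data.frame(trees)) lapply(trees, `[[`, i) else trees[[i]]
  list(feature = as.integer(t$feature), threshold = as.numeric(t$threshold),
       left = as.integer(t$left), right = as.integer(t$right),
       pred = as.integer(t$pred))
}
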