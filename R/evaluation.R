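#' ROC and PR curves with AUCs, kappa and confusion matrix
#'
#' Sweeps a classification threshold over the distinct scores in descending
#' order; all instances with equal score cross the threshold together. The
#' ROC AUC is the trapezoid-rule area (equal to the normalized Mann-Whitney
#' U statistic); the PR AUC defaults to the rectangle-under-step area with
#' precision carried from each threshold across its recall increment
#' (`pr_method = "step"`), with a trapezoid alternative behind
#' `pr_method = "trapezoid"`. The precision at recall 0 is set to the
#' precision of the highest-score group (no interpolation through 0/0).
#' The confusion matrix and Cohen's kappa are evaluated at
#' `class_threshold` (default 0.5, the majority-vote rule).
#'
#' @param scores Numeric classification scores (higher = more TP-like), e.g.
#'   TP vote fractions.
#' @param labels `"TP"`/`"FP"` labels (or logical/0-1 with TRUE/1 = TP).
#' @param pr_method `"step"` (default) or `"trapezoid"` PR area.
#' @param class_threshold Score threshold for the hard confusion matrix.
#' @return An `evaluation_report`: `roc_points` (FPR, TPR), `pr_points`
#'   (recall, precision), `roc_auc`, `pr_auc`, `kappa`, `confusion`,
#'   `threshold_table`.
#' @export
roc_pr_curves <- function(scores, labels, pr_method = c("step", "trapezoid"),
                          class_threshold = 0.5) {
  pr_method <- match.arg(pr_method)
  y <- normalize_labels(labels)
  stopifnot(length(scores) == length(y))
  P <- sum(y); N <- sum(!y)
  if (P == 0 || N == 0) stop("both classes must be present")

  ord <- order(-scores)
  s <- scores[ord]; yy <- y[ord]
  grp_last <- c(which(diff(s) < 0), length(s))   # last index of each tie group
  cum_tp <- cumsum(yy)[grp_last]
  cum_fp <- cumsum(!yy)[grp_last]
  thr <- s[grp_last]

  tpr <- cum_tp / P
  fpr <- cum_fp / N
  prec <- cum_tp / (cum_tp + cum_fp)

  roc_points <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  roc_auc <- sum(diff(roc_points$fpr) *
                   (utils::head(roc_points$tpr, -1) + roc_points$tpr[-1]) / 2)

  pr_points <- data.frame(recall = c(0, tpr), precision = c(prec[1], prec))
  dr <- diff(pr_points$recall)
  pr_auc <- if (pr_method == "step") {
    sum(dr * pr_points$precision[-1])
  } else {
    sum(dr * (utils::head(pr_points$precision, -1) + pr_points$precision[-1]) / 2)
  }

  pred_tp <- scores >= class_threshold
  confusion <- matrix(c(sum(pred_tp & y), sum(pred_tp & !y),
                        sum(!pred_tp & y), sum(!pred_tp & !y)),
                      nrow = 2, byrow = TRUE,
                      dimnames = list(pred = c("TP", "FP"),
                                      truth = c("TP", "FP")))
  threshold_table <- data.frame(
    threshold = thr, tp = cum_tp, fp = cum_fp,
    tn = N - cum_fp, fn = P - cum_tp
  )
  structure(list(
    roc_points = roc_points, pr_points = pr_points,
    roc_auc = roc_auc, pr_auc = pr_auc, pr_method = pr_method,
    kappa = cohen_kappa(confusion), confusion = confusion,
    threshold_table = threshold_table, n = length(y)
  ), class = "evaluation_report")
}

normalize_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  as.character(labels) == "TP"
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n=%d  ROC AUC %.4f  PR AUC %.4f (%s)  kappa %.4f\n",
              x$n, x$roc_auc, x$pr_auc, x$pr_method, x$kappa))
  print(x$confusion)
  invisible(x)
}

#' Cohen's kappa from a 2x2 confusion matrix
#'
#' Chance-corrected agreement: \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with
#' observed agreement \eqn{p_o} and chance agreement \eqn{p_e} from the
#' marginals. When \eqn{p_e = 1} (both raters constant) kappa is defined
#' as 0.
#'
#' @param confusion 2x2 matrix of counts (predicted x truth), or a length-4
#'   vector `(tp, fp, fn, tn)` filled row-wise.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(confusion) {
  m <- matrix(as.numeric(confusion), nrow = 2, byrow = !is.matrix(confusion))
  if (any(m < 0) || any(!is.finite(m))) stop("confusion counts must be non-negative")
  n <- sum(m)
  if (n == 0) stop("empty confusion matrix")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(0)
  (po - pe) / (1 - pe)
}

#' Write evaluation curves and metrics to disk
#'
#' Writes `roc.tsv` and `pr.tsv` (curve points), `thresholds.tsv`,
#' `metrics.json` (AUCs, kappa, confusion) and a rendered `curves.png` into
#' `dir`. Output content is deterministic for a given report.
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_curves <- function(report, dir) {
  stopifnot(inherits(report, "evaluation_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("roc.tsv", "pr.tsv", "thresholds.tsv",
                            "metrics.json", "curves.png"))
  utils::write.table(report$roc_points, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$pr_points, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$threshold_table, paths[3], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    roc_auc = report$roc_auc, pr_auc = report$pr_auc,
    pr_method = report$pr_method, kappa = report$kappa,
    confusion = as.vector(report$confusion), n = report$n
  ), paths[4], auto_unbox = TRUE, digits = NA)
  grDevices::png(paths[5], width = 1200, height = 600)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  plot(report$roc_points$fpr, report$roc_points$tpr, type = "l",
       xlab = "FPR", ylab = "TPR", xlim = c(0, 1), ylim = c(0, 1),
       main = sprintf("ROC (AUC = %.4f)", report$roc_auc))
  graphics::abline(0, 1, lty = 3)
  plot(report$pr_points$recall, report$pr_points$precision, type = "s",
       xlab = "Recall", ylab = "Precision", xlim = c(0, 1), ylim = c(0, 1),
       main = sprintf("PR (AUC = %.4f)", report$pr_auc))
  invisible(paths)
}
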