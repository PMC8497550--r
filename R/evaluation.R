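# Ranking evaluation against held-out lncRNA-disease labels: confusion
# counts, ROC/AUC, precision-recall/AUPR, LOOCV and k-fold protocols, and
# per-disease candidate tables.
#
# The model never consumes lncRNA-disease labels, so cross-validation here
# partitions the evaluation labels only: scores are fixed, each held-out
# positive is ranked against all unlabeled pairs.

# Pull the (score, label) vectors for every pair on the axes present in
# both matrices.  Labeled entities without a score (e.g. no association in
# either input layer) are dropped; pairs absent from the label list are
# unlabeled and treated as negatives for ranking.
eval_vectors <- function(scores, labels) {
  stopifnot(inherits(scores, "score_matrix"), inherits(labels, "bipartite_network"))
  sv <- scores$values
  lv <- labels$adjacency
  rn <- intersect(rownames(lv), rownames(sv))
  cn <- intersect(colnames(lv), colnames(sv))
  if (length(rn) == 0 || length(cn) == 0) {
    stop("no overlap between label and score axes")
  }
  sv <- sv[rn, cn, drop = FALSE]
  lv <- lv[rn, cn, drop = FALSE]
  list(score = as.vector(sv), label = as.vector(lv))
}

# Mann-Whitney AUC with midrank tie correction.
rank_auc <- function(score, label) {
  p <- sum(label == 1)
  n <- sum(label == 0)
  if (p == 0) stop("no labeled positive pair: TPR undefined")
  if (n == 0) stop("no negative (unlabeled) pair: FPR undefined")
  r <- rank(score, ties.method = "average")
  (sum(r[label == 1]) - p * (p + 1) / 2) / (p * n)
}

# ROC and PR point sets over the full threshold sweep (thresholds grouped at
# unique score values, descending), plus trapezoidal areas.
sweep_curves <- function(score, label) {
  p <- sum(label == 1)
  n <- sum(label == 0)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  l <- label[ord]
  grp_end <- cumsum(rle(s)$lengths)  # last index of each tied score block
  tp <- cumsum(l)[grp_end]
  fp <- grp_end - tp
  tpr <- c(0, tp / p)
  fpr <- c(0, fp / n)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  recall <- tp / p
  precision <- tp / (tp + fp)
  recall <- c(0, recall)
  precision <- c(precision[1], precision)
  aupr <- sum(diff(recall) * (utils::head(precision, -1) + utils::tail(precision, -1)) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr),
       pr_points = data.frame(recall = recall, precision = precision),
       auc = auc, aupr = aupr)
}

new_evaluation_result <- function(curves, rank_auc, n_pos, n_neg,
                                  per_fold_auc = NULL) {
  structure(list(roc_points = curves$roc_points, auc = curves$auc,
                 pr_points = curves$pr_points, aupr = curves$aupr,
                 rank_auc = rank_auc, per_fold_auc = per_fold_auc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("evaluation_result: AUC %.4f, AUPR %.4f (%d positives vs %d unlabeled)\n",
              x$auc, x$aupr, x$n_pos, x$n_neg))
  if (!is.null(x$per_fold_auc)) {
    cat(sprintf("  per-fold AUC: %s (mean %.4f)\n",
                paste(sprintf("%.4f", x$per_fold_auc), collapse = ", "),
                mean(x$per_fold_auc)))
  }
  invisible(x)
}

#' Confusion counts at a score threshold
#'
#' A pair counts TP if `score >= threshold` and label 1; FP if
#' `score >= threshold` and label 0; TN/FN complementarily.
#'
#' @param scores [score_matrix].
#' @param labels [bipartite_network] of known positives; its axes must be a
#'   subset of the score axes, and every pair on them is evaluated (absent
#'   pairs count as negatives).
#' @param threshold scalar decision threshold.
#' @return Named numeric vector with elements `TP`, `FP`, `TN`, `FN`, `TPR`,
#'   `FPR`.
#' @export
confusion_counts <- function(scores, labels, threshold) {
  v <- eval_vectors(scores, labels)
  if (sum(v$label == 1) == 0) stop("no labeled positive pair: TPR undefined")
  pred <- v$score >= threshold
  tp <- sum(pred & v$label == 1)
  fp <- sum(pred & v$label == 0)
  fn <- sum(!pred & v$label == 1)
  tn <- sum(!pred & v$label == 0)
  c(TP = tp, FP = fp, TN = tn, FN = fn,
    TPR = tp / (tp + fn), FPR = if (fp + tn > 0) fp / (fp + tn) else NaN)
}

#' Leave-one-out cross-validation AUC
#'
#' Each known association is held out in turn and ranked against all
#' unlabeled pairs.  Because the predictor never consumes the labels, the
#' scores are fixed and the aggregate equals the global ranking AUC of
#' positives versus unlabeled pairs, computed with midrank tie correction;
#' the full-threshold ROC and precision-recall curves are returned alongside.
#'
#' @inheritParams confusion_counts
#' @return An `evaluation_result` with `roc_points`, `auc`, `pr_points`,
#'   `aupr` and `rank_auc` (trapezoid and rank AUC agree to 1e-12).
#' @export
loocv_auc <- function(scores, labels) {
  v <- eval_vectors(scores, labels)
  ra <- rank_auc(v$score, v$label)
  curves <- sweep_curves(v$score, v$label)
  new_evaluation_result(curves, ra, sum(v$label == 1), sum(v$label == 0))
}

#' k-fold cross-validation AUC
#'
#' Positives are partitioned into `k` seeded random folds; each fold's
#' positives are ranked against all unlabeled pairs and a fold AUC computed.
#' With `k` equal to the number of positives this reproduces the LOOCV
#' aggregate.  Folds partition the evaluation labels only — the model never
#' sees lncRNA-disease data.
#'
#' @inheritParams confusion_counts
#' @param k number of folds (>= 2, <= number of positives).
#' @param seed integer seed for the fold assignment.
#' @return An `evaluation_result`; `auc` is the mean of `per_fold_auc`.
#' @export
kfold_auc <- function(scores, labels, k = 5, seed = 1L) {
  v <- eval_vectors(scores, labels)
  pos_idx <- which(v$label == 1)
  neg_score <- v$score[v$label == 0]
  if (length(neg_score) == 0) stop("no negative (unlabeled) pair")
  if (k < 2) stop("k must be >= 2")
  if (k > length(pos_idx)) stop("k exceeds the number of positives")
  fold <- with_rng(seed, {
    sample(rep_len(seq_len(k), length(pos_idx)))
  })
  per_fold <- vapply(seq_len(k), function(f) {
    ps <- v$score[pos_idx[fold == f]]
    rank_auc(c(ps, neg_score),
             c(rep(1, length(ps)), rep(0, length(neg_score))))
  }, numeric(1))
  curves <- sweep_curves(v$score, v$label)
  res <- new_evaluation_result(curves, rank_auc(v$score, v$label),
                               length(pos_idx), length(neg_score),
                               per_fold_auc = per_fold)
  res$auc <- mean(per_fold)
  res
}

#' Top candidate lncRNAs for one disease
#'
#' Sorts the lncRNAs by descending score in that disease's column, with ties
#' broken by lncRNA name order for reproducibility, optionally removing
#' already-known positives first, and returns the top `top_n`.
#'
#' @param scores [score_matrix].
#' @param disease disease name (must be a score column).
#' @param exclude optional character vector of lncRNAs to drop before
#'   ranking (e.g. known positives for that disease).
#' @param top_n number of candidates to return (default 15).
#' @return `data.frame` with columns `rank`, `lncrna`, `score`.
#' @export
rank_candidates <- function(scores, disease, exclude = NULL, top_n = 15) {
  stopifnot(inherits(scores, "score_matrix"))
  if (!disease %in% colnames(scores$values)) {
    stop(sprintf("unknown disease: %s", disease))
  }
  col <- scores$values[, disease]
  if (!is.null(exclude)) col <- col[!names(col) %in% exclude]
  ord <- order(-col, names(col))
  top <- utils::head(ord, top_n)
  data.frame(rank = seq_along(top), lncrna = names(col)[top],
             score = unname(col[top]), stringsAsFactors = FALSE)
}

#' Write an evaluation report as JSON
#'
#' @param result `evaluation_result`.
#' @param path output path.
#' @export
write_evaluation <- function(result, path) {
  stopifnot(inherits(result, "evaluation_result"))
  jsonlite::write_json(
    list(auc = result$auc, aupr = result$aupr, rank_auc = result$rank_auc,
         per_fold_auc = result$per_fold_auc,
         n_pos = result$n_pos, n_neg = result$n_neg,
         roc_points = result$roc_points, pr_points = result$pr_points),
    path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}
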