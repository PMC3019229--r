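## ROC evaluation.
##
## The ROC curve is built by a threshold sweep over the scores; tied scores
## enter as a single curve step, which trapezoidal integration treats as a
## diagonal segment, so the AUC equals the probability that a random
## positive outranks a random negative with ties counted one half. The
## truncated score integrates the same curve only up to 10 * n false
## positives (n = number of miRNAs in the evaluation set) while keeping the
## x axis as FPR over all negatives; a perfect ranking therefore attains
## 10 * n / #negatives rather than 1.

#' ROC curve and area under it
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels class labels (pos/neg, down_regulated/unaffected, logical).
#' @return object of class `mirsvm_eval`: `points` (data.frame with
#'   cumulative false/true positive counts `fp`, `tp` and rates `fpr`,
#'   `tpr` at every distinct threshold), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve_auc <- function(scores, labels) {
  yf <- as_binary_factor(labels)
  if (nlevels(droplevels(yf)) < 2L) {
    stop("both classes must be present to compute a ROC curve")
  }
  pos <- yf == "pos"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  ## collapse tied scores into single curve points
  last_of_run <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[last_of_run]
  fp <- cumsum(!p)[last_of_run]
  points <- data.frame(fp = c(0L, fp), tp = c(0L, tp))
  points$fpr <- points$fp / n_neg
  points$tpr <- points$tp / n_pos
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                   utils::tail(points$tpr, -1)) / 2)
  out <- list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg)
  class(out) <- "mirsvm_eval"
  out
}

#' @export
print.mirsvm_eval <- function(x, ...) {
  cat(sprintf("ROC over %d positives / %d negatives: AUC = %.4f\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' Truncated ROC score (ROC_10*n)
#'
#' Area under the ROC curve restricted to the first `10 * n_mirnas` false
#' positive predictions, with the false positive rate still measured
#' against all negatives. The maximum attainable value is
#' `10 * n_mirnas / #negatives`; when the cutoff covers all negatives the
#' score equals the full AUC.
#'
#' @param scores,labels as in [roc_curve_auc()].
#' @param n_mirnas number of miRNAs in the evaluation set (the cutoff is
#'   `10 * n_mirnas` false positives).
#' @return numeric truncated ROC score.
#' @export
roc_truncated <- function(scores, labels, n_mirnas) {
  ev <- roc_curve_auc(scores, labels)
  cutoff <- 10 * n_mirnas
  if (cutoff >= ev$n_neg) return(ev$auc)
  pts <- ev$points
  keep <- pts$fp <= cutoff
  sub <- pts[keep, , drop = FALSE]
  ## interpolate the curve at fp == cutoff inside a tie segment
  if (max(sub$fp) < cutoff) {
    i <- which(!keep)[1L]
    frac <- (cutoff - pts$fp[i - 1L]) / (pts$fp[i] - pts$fp[i - 1L])
    sub <- rbind(sub, data.frame(
      fp = cutoff,
      tp = pts$tp[i - 1L] + frac * (pts$tp[i] - pts$tp[i - 1L]),
      fpr = cutoff / ev$n_neg,
      tpr = (pts$tpr[i - 1L] + frac * (pts$tpr[i] - pts$tpr[i - 1L]))))
  }
  sum(diff(sub$fpr) * (utils::head(sub$tpr, -1) +
                         utils::tail(sub$tpr, -1)) / 2)
}

#' Leave-one-feature-group-out ablation
#'
#' Re-runs the site-level cross-validation with one feature group removed at
#' a time, over the identical fold partition, and reports the drop in mean
#' ROC score. A positive `delta_auc` means the model loses prediction power
#' without the feature, i.e. the feature is informative.
#'
#' @param x normalized site feature matrix.
#' @param y site labels.
#' @param groups named list mapping group name to feature column names;
#'   defaults to the built-in site feature groups (seed_type, duplex,
#'   au_context, position, utr_length, composition).
#' @param spec a [kernel_spec()].
#' @param k folds.
#' @param seed integer seed (fixes the shared fold partition).
#' @return data.frame with columns `omitted`, `mean_auc`, `delta_auc`
#'   (full-model AUC minus ablated AUC), plus one `"(none)"` row for the
#'   full model.
#' @export
ablation_study <- function(x, y, groups = FEATURE_GROUPS,
                           spec = kernel_spec(), k = 10L, seed = 1L) {
  x <- as.matrix(x)
  if (length(groups) < 2L) stop("need at least two feature groups")
  unknown <- setdiff(unlist(groups), colnames(x))
  if (length(unknown)) {
    stop("unknown feature name in groups: ", paste(unknown, collapse = ", "))
  }
  folds <- stratified_folds(y, k, seed)
  full <- crossval_discriminants(x, y, spec, k, seed, folds = folds)
  rows <- data.frame(omitted = "(none)", mean_auc = full$mean_auc,
                     delta_auc = 0, stringsAsFactors = FALSE)
  for (g in names(groups)) {
    keep <- setdiff(colnames(x), groups[[g]])
    cv <- crossval_discriminants(x[, keep, drop = FALSE], y, spec, k, seed,
                                 folds = folds)
    rows <- rbind(rows, data.frame(omitted = g, mean_auc = cv$mean_auc,
                                   delta_auc = full$mean_auc - cv$mean_auc,
                                   stringsAsFactors = FALSE))
  }
  rows
}
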