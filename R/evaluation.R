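# Evaluation measures for per-residue binary classification: confusion
# counts, PPV/TPR/F1/MCC, recall-precision curves and score plots.

#' Confusion counts
#'
#' @param calls binary 0/1 predictions.
#' @param truth binary 0/1 ground truth.
#' @return Object of class `confusion_counts` with fields `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion <- function(calls, truth) {
  if (length(calls) != length(truth))
    stop("calls and truth differ in length")
  calls <- as.integer(calls); truth <- as.integer(truth)
  stopifnot(all(calls %in% 0:1), all(truth %in% 0:1))
  structure(list(
    tp = sum(calls == 1L & truth == 1L),
    tn = sum(calls == 0L & truth == 0L),
    fp = sum(calls == 1L & truth == 0L),
    fn = sum(calls == 0L & truth == 1L)
  ), class = "confusion_counts")
}

#' Point evaluation measures
#'
#' Precision (positive predictive value), recall (true positive rate),
#' F1 and the Matthews correlation coefficient computed from confusion
#' counts. Degenerate denominators follow the convention that keeps
#' cross-validation aggregation total: `ppv`, `tpr` and `f1` return 0
#' when undefined, and `mcc` returns 0 when any marginal is zero.
#'
#' @param c a [confusion()] result.
#' @return A single numeric value.
#' @export
ppv <- function(c) {
  d <- c$tp + c$fp
  if (d == 0) 0 else c$tp / d
}

#' @rdname ppv
#' @export
tpr <- function(c) {
  d <- c$tp + c$fn
  if (d == 0) 0 else c$tp / d
}

#' @rdname ppv
#' @export
f1 <- function(c) {
  p <- ppv(c); r <- tpr(c)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' @rdname ppv
#' @export
mcc <- function(c) {
  m <- with(c, as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (m == 0) return(0)
  with(c, (as.numeric(tp) * tn - as.numeric(fp) * fn)) / sqrt(m)
}

#' Recall-precision curve
#'
#' Sweeps the score cutoff (calls are `score >= threshold`, ties
#' positive) and reports precision and recall per threshold, the
#' trapezoidal area under the precision-versus-recall curve and the
#' random-classifier baseline (the positive fraction). Thresholds with
#' no predicted positives keep the degenerate-precision convention of
#' [ppv()]; the AUC integrates only over thresholds with at least one
#' predicted positive, anchored at recall 0 with the precision of the
#' strictest such threshold.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param truth binary 0/1 ground truth.
#' @param thresholds cutoff grid; defaults to the sorted unique scores
#'   plus the endpoints 0 and 1.
#' @return data.frame `(threshold, precision, recall)` with attributes
#'   `auc` and `baseline`.
#' @export
pr_curve <- function(scores, truth, thresholds = NULL) {
  stopifnot(length(scores) == length(truth),
            all(scores >= 0 & scores <= 1))
  truth <- as.integer(truth)
  if (is.null(thresholds))
    thresholds <- sort(unique(c(0, scores, 1)))
  thresholds <- sort(thresholds)
  npos <- sum(truth == 1L)
  # counts above each threshold via sorted cumulative sums
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  cum_tp <- cumsum(truth[ord] == 1L)
  # number of scores >= t: findInterval on the ascending negated scores
  n_ge <- length(scores) - findInterval(thresholds, rev(s_sorted),
                                        left.open = TRUE)
  tp <- ifelse(n_ge > 0, cum_tp[pmax(n_ge, 1L)], 0L)
  tp[n_ge == 0] <- 0L
  precision <- ifelse(n_ge > 0, tp / n_ge, 0)
  recall <- if (npos > 0) tp / npos else rep(0, length(tp))
  out <- data.frame(threshold = thresholds, precision = precision,
                    recall = recall)
  with_pred <- out[n_ge > 0, , drop = FALSE]
  auc <- 0
  if (nrow(with_pred) > 0) {
    pts <- with_pred[order(with_pred$recall, -with_pred$threshold), ]
    r <- c(0, pts$recall)
    p <- c(pts$precision[1], pts$precision)
    auc <- sum(diff(r) * (head(p, -1) + tail(p, -1)) / 2)
  }
  attr(out, "auc") <- auc
  attr(out, "baseline") <- mean(truth == 1L)
  out
}

#' Score plot: PPV, recall and F1 as functions of the score cutoff
#'
#' Evaluates precision, recall and F1 on a uniform cutoff grid over
#' `[0, 1]` and reports the cutoff maximizing F1.
#'
#' @inheritParams pr_curve
#' @param bins number of grid cutoffs (default 101, i.e. steps of 0.01).
#' @return data.frame `(cutoff, ppv, recall, f1)` with attribute
#'   `best_cutoff`.
#' @export
score_plot <- function(scores, truth, bins = 101) {
  stopifnot(bins >= 2)
  grid <- seq(0, 1, length.out = bins)
  rows <- lapply(grid, function(t) {
    cc <- confusion(as.integer(scores >= t), truth)
    data.frame(cutoff = t, ppv = ppv(cc), recall = tpr(cc), f1 = f1(cc))
  })
  out <- do.call(rbind, rows)
  attr(out, "best_cutoff") <- out$cutoff[which.max(out$f1)]
  out
}
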