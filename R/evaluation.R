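# ROC/AUC with DeLong confidence intervals, Youden-index cutoffs,
# confusion-matrix metrics at a cutoff, and decision-curve analysis.
# The decision rule is "positive iff score >= cutoff" throughout.

# Mann-Whitney AUC with ties counted 1/2.
auc_mw <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC with 95% confidence interval
#'
#' AUC is the Mann-Whitney statistic (ties counted 1/2); the confidence
#' interval uses the DeLong variance by default, or seeded bootstrap
#' resampling.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (both classes required).
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param boot_n,boot_seed bootstrap controls.
#' @return a `roc_result`: `auc`, `ci` (lower, upper), `n_pos`, `n_neg`,
#'   and the ROC `curve` (cutoff, sensitivity, specificity).
#' @export
roc_auc <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                    boot_n = 2000L, boot_seed = 1L) {
  ci_method <- match.arg(ci_method)
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("both classes required", call. = FALSE)
  auc <- auc_mw(scores, y)
  if (ci_method == "delong") {
    r <- suppressMessages(pROC::roc(y, scores, quiet = TRUE,
                                    direction = "<", levels = c(0, 1)))
    ci <- as.numeric(suppressWarnings(pROC::ci.auc(r, method = "delong")))[c(1L, 3L)]
  } else {
    bs <- with_seed(boot_seed, vapply(seq_len(boot_n), function(i) {
      idx <- sample.int(length(y), replace = TRUE)
      if (length(unique(y[idx])) < 2L) return(NA_real_)
      auc_mw(scores[idx], y[idx])
    }, numeric(1L)))
    ci <- quantile(bs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  ci <- pmin(pmax(ci, 0), 1)
  cuts <- sort(unique(scores))
  curve <- data.frame(
    cutoff = cuts,
    sensitivity = vapply(cuts, function(ct) mean(scores[y == 1L] >= ct), numeric(1L)),
    specificity = vapply(cuts, function(ct) mean(scores[y == 0L] < ct), numeric(1L)))
  structure(list(auc = auc, ci = ci, n_pos = sum(y == 1L),
                 n_neg = sum(y == 0L), curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), %d positives / %d negatives\n",
              x$auc, x$ci[1L], x$ci[2L], x$n_pos, x$n_neg))
  invisible(x)
}

#' Youden-index optimal cutoff
#'
#' The observed score maximizing sensitivity + specificity - 1 under the
#' rule "positive iff score >= cutoff"; ties are broken toward the smaller
#' cutoff.
#'
#' @param scores,labels as in [roc_auc()].
#' @return the cutoff value; the achieved Youden J is attached as
#'   attribute `youden`.
#' @export
youden_cutoff <- function(scores, labels) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("both classes required", call. = FALSE)
  cuts <- sort(unique(scores))
  j <- vapply(cuts, function(ct) {
    mean(scores[y == 1L] >= ct) + mean(scores[y == 0L] < ct) - 1
  }, numeric(1L))
  best <- cuts[which.max(j)]  # which.max -> first (smallest) on ties
  attr(best, "youden") <- max(j)
  best
}

#' Confusion-matrix metrics at a cutoff
#'
#' @param scores,labels as in [roc_auc()].
#' @param cutoff classification threshold ("positive iff >= cutoff").
#' @return a `cutoff_metrics` list: cutoff, accuracy, sensitivity,
#'   specificity, ppv, npv and the confusion counts. PPV (or NPV) is `NA`
#'   when no patient is predicted positive (negative).
#' @export
classification_metrics <- function(scores, labels, cutoff) {
  stopifnot(is.finite(cutoff))
  y <- as.integer(labels)
  pred <- as.integer(scores >= cutoff)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  tn <- sum(pred == 0L & y == 0L); fn <- sum(pred == 0L & y == 1L)
  ppv <- if (tp + fp == 0L) {
    warning("no predicted positives; PPV undefined", call. = FALSE)
    NA_real_
  } else tp / (tp + fp)
  npv <- if (tn + fn == 0L) {
    warning("no predicted negatives; NPV undefined", call. = FALSE)
    NA_real_
  } else tn / (tn + fn)
  structure(list(cutoff = cutoff,
                 accuracy = (tp + tn) / length(y),
                 sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0L) tn / (tn + fp) else NA_real_,
                 ppv = ppv, npv = npv,
                 counts = c(tp = tp, fp = fp, tn = tn, fn = fn)),
            class = "cutoff_metrics")
}

#' Decision curve analysis
#'
#' Net benefit `NB(t) = TP(t)/n - FP(t)/n * t/(1-t)` with classification at
#' probability threshold `t`; the treat-all curve classifies everyone
#' positive, treat-none is identically zero.
#'
#' @param scores,labels as in [roc_auc()].
#' @param grid strictly increasing thresholds inside (0, 1);
#'   default 0.01..0.99 step 0.01.
#' @return a `decision_curve` data.frame: threshold, net_benefit,
#'   treat_all, treat_none.
#' @export
decision_curve <- function(scores, labels, grid = seq(0.01, 0.99, by = 0.01)) {
  if (any(grid <= 0) || any(grid >= 1)) {
    stop("thresholds must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("`grid` must be strictly increasing", call. = FALSE)
  }
  y <- as.integer(labels)
  n <- length(y)
  nb <- vapply(grid, function(t) {
    tp <- sum(scores >= t & y == 1L)
    fp <- sum(scores >= t & y == 0L)
    tp / n - fp / n * t / (1 - t)
  }, numeric(1L))
  prev <- mean(y)
  ta <- prev - (1 - prev) * grid / (1 - grid)
  structure(data.frame(threshold = grid, net_benefit = nb,
                       treat_all = ta, treat_none = 0),
            class = c("decision_curve", "data.frame"))
}

#' Full evaluation report for one model on one cohort split
#'
#' @param scores,labels as in [roc_auc()].
#' @param cutoff operating cutoff (typically the training-set Youden
#'   cutoff); defaults to the Youden cutoff of this split.
#' @return an `evaluation_report`: `roc`, `cutoff`, `metrics`, `dca`.
#' @export
evaluate_model <- function(scores, labels, cutoff = NULL) {
  if (is.null(cutoff)) cutoff <- as.numeric(youden_cutoff(scores, labels))
  structure(list(roc = roc_auc(scores, labels),
                 cutoff = cutoff,
                 metrics = suppressWarnings(
                   classification_metrics(scores, labels, cutoff)),
                 dca = decision_curve(scores, labels)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("AUC %.3f (%.3f-%.3f) | cutoff %.3f | acc %.3f sens %.3f spec %.3f ppv %.3f npv %.3f\n",
              x$roc$auc, x$roc$ci[1L], x$roc$ci[2L], x$cutoff, m$accuracy,
              m$sensitivity, m$specificity, m$ppv, m$npv))
  invisible(x)
}
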