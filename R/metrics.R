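# Binary-classification performance: Sn, Sp, Acc, MCC from the 2x2
# confusion counts. Degenerate 0/0 ratios are defined as 0 (with a
# warning), so an all-one-class prediction gets Sp = 0, MCC = 0 rather
# than NaN.

#' Confusion-count performance metrics
#'
#' Computes the four confusion counts and sensitivity
#' `Sn = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`, accuracy
#' `Acc = (TP+TN)/N` and the Matthews correlation coefficient from
#' predicted and true binary labels.
#'
#' @param y_true,y_pred binary (0/1) vectors of equal length.
#' @param warn_degenerate warn when a 0/0 ratio is forced to 0.
#' @return Object of class `sno_metrics`: list with `tp`, `fp`, `tn`,
#'   `fn`, `sn`, `sp`, `acc`, `mcc`.
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
compute_metrics <- function(y_true, y_pred, warn_degenerate = TRUE) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length")
  if (!length(y_true)) stop("empty input")
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  tp <- sum(y_true == 1L & y_pred == 1L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  tn <- sum(y_true == 0L & y_pred == 0L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      if (warn_degenerate)
        warning(sprintf("%s undefined (0/0); reported as 0", what),
                call. = FALSE)
      return(0)
    }
    num / den
  }
  mcc_den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
             sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sn = safe_div(tp, tp + fn, "Sn"),
    sp = safe_div(tn, tn + fp, "Sp"),
    acc = (tp + tn) / length(y_true),
    mcc = safe_div(as.numeric(tp) * tn - as.numeric(fp) * fn,
                   mcc_den, "MCC")),
    class = "sno_metrics")
}

#' @export
print.sno_metrics <- function(x, ...) {
  cat(sprintf("confusion: TP %d  FP %d  TN %d  FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("Sn %.4f  Sp %.4f  Acc %.4f  MCC %.4f\n",
              x$sn, x$sp, x$acc, x$mcc))
  invisible(x)
}

# Build an sno_metrics from pooled counts (used by cross-validation).
metrics_from_counts <- function(tp, fp, tn, fn) {
  y_true <- c(rep(1L, tp + fn), rep(0L, tn + fp))
  y_pred <- c(rep(1L, tp), rep(0L, fn), rep(0L, tn), rep(1L, fp))
  compute_metrics(y_true, y_pred, warn_degenerate = FALSE)
}
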