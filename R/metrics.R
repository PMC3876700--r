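#' Pixelwise segmentation evaluation
#'
#' Confusion counts of a predicted vessel mask against a gold-standard mask,
#' optionally restricted to a field-of-view mask, with the derived rates
#' \deqn{Se = TP/(TP+FN), \quad Sp = TN/(TN+FP), \quad Acc = (TP+TN)/N.}
#' By default every pixel of the frame is counted; pass `fov` to evaluate
#' inside the camera aperture only (both conventions are found in the
#' literature). A zero denominator yields `NA` for that rate, not an error.
#'
#' @param pred,gold 0/1 integer matrices of equal shape.
#' @param fov Optional 0/1 matrix; only `fov == 1` pixels are counted.
#' @return An `eval_result` list: `tp`, `tn`, `fp`, `fn`, `n_eval`,
#'   `sensitivity`, `specificity`, `accuracy`.
#' @export
evaluate <- function(pred, gold, fov = NULL) {
  .check_mask(pred, "pred"); .check_mask(gold, "gold")
  if (!all(dim(pred) == dim(gold)))
    .stopf("evaluate: pred (%d x %d) and gold (%d x %d) shapes differ",
           nrow(pred), ncol(pred), nrow(gold), ncol(gold))
  keep <- if (is.null(fov)) TRUE else {
    .check_mask(fov, "fov")
    if (!all(dim(fov) == dim(pred))) .stopf("evaluate: fov shape differs")
    fov == 1L
  }
  p <- pred[keep] == 1L
  g <- gold[keep] == 1L
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)
  rate <- function(num, den) if (den == 0L) NA_real_ else num / den
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 n_eval = tp + tn + fp + fn,
                 sensitivity = rate(tp, tp + fn),
                 specificity = rate(tn, tn + fp),
                 accuracy = rate(tp + tn, tp + tn + fp + fn)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "pixels evaluated: %d  (TP %d, FP %d, FN %d, TN %d)\nSe %.4f  Sp %.4f  Acc %.4f\n",
    x$n_eval, x$tp, x$fp, x$fn, x$tn,
    x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param pred,gold 0/1 integer matrices of equal shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(pred, gold) {
  .check_mask(pred); .check_mask(gold)
  stopifnot(all(dim(pred) == dim(gold)))
  denom <- sum(pred == 1L) + sum(gold == 1L)
  if (denom == 0L) return(1)
  2 * sum(pred == 1L & gold == 1L) / denom
}
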