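#' Close a non-negative vector onto the unit simplex
#'
#' Divides each element by the total so the parts sum to one. Relative
#' concentrations from an NMR fit live on this simplex: only ratios are
#' meaningful, not absolute scales.
#'
#' @param v Non-negative numeric vector with a positive sum.
#' @return The closed composition (names preserved).
#' @export
#' @examples
#' closure(c(2, 2))  # 0.5 0.5
closure <- function(v) {
  if (any(v < 0)) abort("composition parts must be non-negative")
  s <- sum(v)
  if (!is.finite(s) || s <= 0) abort("cannot close a zero-sum vector")
  v / s
}

#' Geometric-mean center of compositional samples
#'
#' The compositional analogue of the mean: close the vector of per-part
#' geometric means. Used to summarize posterior draws of mixture weights,
#' where the geometric mean respects the simplex geometry better than the
#' arithmetic mean. Zeros are floored at 1e-12 before taking logs.
#'
#' @param samples A numeric matrix, one composition per row.
#' @return The center composition (length = number of columns).
#' @export
comp_center <- function(samples) {
  samples <- as.matrix(samples)
  if (nrow(samples) == 0) abort("need at least one sample")
  g <- exp(colMeans(log(pmax(samples, 1e-12))))
  out <- closure(g)
  names(out) <- colnames(samples)
  out
}

#' Mean absolute error between two compositions
#'
#' `(1/D) * sum |est_i - true_i|` over the D parts, reported in percent of
#' mole fraction. The divisor is the full candidate count, including
#' candidates absent from the mixture.
#'
#' @param est,truth Compositions of equal length.
#' @return MAE in percent.
#' @export
#' @examples
#' composition_mae(c(0.6, 0.4), c(0.5, 0.5))  # 10
composition_mae <- function(est, truth) {
  if (length(est) != length(truth)) abort("compositions differ in length")
  100 * mean(abs(est - truth))
}

#' Present/absent classification accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)` over the candidate compounds,
#' in percent.
#'
#' @param pred_present,true_present Logical vectors of equal length.
#' @return Accuracy in percent.
#' @export
classification_accuracy <- function(pred_present, true_present) {
  if (length(pred_present) == 0) abort("empty classification")
  if (length(pred_present) != length(true_present)) {
    abort("prediction and truth differ in length")
  }
  100 * mean(pred_present == true_present)
}

#' Subcomposition: close a subset of parts
#'
#' @param x A composition.
#' @param indices Indices (or names) of the parts to keep; must select at
#'   least one and fewer than all parts.
#' @return The closed subcomposition.
#' @export
subcomposition <- function(x, indices) {
  sel <- x[indices]
  if (length(sel) < 1) abort("empty subcomposition")
  if (anyNA(sel)) abort("`indices` select missing parts")
  closure(sel)
}
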