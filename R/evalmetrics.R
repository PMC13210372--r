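# Evaluation metrics: quadratic weighted kappa, calibration (ECE / MCE /
# Brier), classification panel, and abstention-aware selective reporting.

#' Quadratic weighted kappa
#'
#' `1 - sum(W * O) / sum(W * E)` with weights `W_ij = (i - j)^2 / (K - 1)^2`
#' for K = 4 ordinal levels, observed counts `O`, and expected counts `E`
#' from the product of the marginals scaled to n. Returns 1 when both
#' sequences are constant and equal (no disagreement possible).
#'
#' @param y_true,y_pred integer labels in 0..3, equal length >= 1
#' @param n_levels number of ordinal levels (default 4)
#' @return kappa in \[-1, 1\]
#' @export
qwk <- function(y_true, y_pred, n_levels = 4L) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1)
    np_stop("np_validation_error", "label vectors must have equal length >= 1")
  lv <- 0:(n_levels - 1L)
  if (!all(y_true %in% lv) || !all(y_pred %in% lv))
    np_stop("np_validation_error", "labels must lie in 0..%d", n_levels - 1L)
  n <- length(y_true)
  O <- table(factor(y_true, levels = lv), factor(y_pred, levels = lv))
  E <- outer(rowSums(O), colSums(O)) / n
  W <- outer(lv, lv, function(i, j) (i - j)^2) / (n_levels - 1L)^2
  denom <- sum(W * E)
  if (denom == 0) return(1.0)
  1 - sum(W * O) / denom
}

#' Expected calibration error
#'
#' Equal-width binning of the predicted class's probability (confidence):
#' `sum_b (n_b / n) |acc_b - conf_b|`; empty bins contribute 0.
#'
#' @param probabilities n x K matrix of class probabilities (rows on the
#'   simplex)
#' @param labels true classes in 0..K-1
#' @param n_bins number of equal-width confidence bins (default 15)
#' @return scalar ECE in \[0, 1\]
#' @export
ece <- function(probabilities, labels, n_bins = 15L) {
  P <- as.matrix(probabilities)
  if (any(P < -1e-9) || any(abs(rowSums(P) - 1) > 1e-6))
    np_stop("np_validation_error", "probability rows must lie on the simplex")
  conf <- apply(P, 1, max)
  pred <- apply(P, 1, which.max) - 1L
  correct <- pred == labels
  bins <- pmin(pmax(ceiling(conf * n_bins), 1L), n_bins)
  total <- 0
  for (b in seq_len(n_bins)) {
    in_b <- bins == b
    if (!any(in_b)) next
    total <- total + sum(in_b) / nrow(P) *
      abs(mean(correct[in_b]) - mean(conf[in_b]))
  }
  total
}

#' Maximum calibration error (same binning as [ece()])
#' @inheritParams ece
#' @return scalar MCE
#' @export
mce <- function(probabilities, labels, n_bins = 15L) {
  P <- as.matrix(probabilities)
  conf <- apply(P, 1, max)
  pred <- apply(P, 1, which.max) - 1L
  correct <- pred == labels
  bins <- pmin(pmax(ceiling(conf * n_bins), 1L), n_bins)
  worst <- 0
  for (b in seq_len(n_bins)) {
    in_b <- bins == b
    if (!any(in_b)) next
    worst <- max(worst, abs(mean(correct[in_b]) - mean(conf[in_b])))
  }
  worst
}

#' Multiclass Brier score (sum-of-squares form)
#' @inheritParams ece
#' @return mean over samples of `sum_k (p_k - y_k)^2`
#' @export
brier <- function(probabilities, labels) {
  P <- as.matrix(probabilities)
  Y <- matrix(0, nrow(P), ncol(P))
  Y[cbind(seq_len(nrow(P)), labels + 1L)] <- 1
  mean(rowSums((P - Y)^2))
}

macro_f1 <- function(y_true, y_pred, levels = 0:3) {
  f1s <- vapply(levels, function(l) {
    tp <- sum(y_true == l & y_pred == l)
    fp <- sum(y_true != l & y_pred == l)
    fn <- sum(y_true == l & y_pred != l)
    if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1s, na.rm = TRUE)
}

class_panel <- function(y_true, y_pred, levels = 0:3) {
  do.call(rbind, lapply(levels, function(l) {
    tp <- sum(y_true == l & y_pred == l)
    fp <- sum(y_true != l & y_pred == l)
    fn <- sum(y_true == l & y_pred != l)
    tn <- sum(y_true != l & y_pred != l)
    data.frame(level = l,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
  }))
}

#' Abstention-aware evaluation report
#'
#' Computes coverage (1 - abstention rate) and the full metric panel on the
#' non-abstained cases. With zero non-abstained cases the selective metrics
#' are `NA` markers and coverage is 0.
#'
#' @param assessments data.frame with `level` (NA allowed), `abstain`
#'   (logical), and optionally columns `p0..p3` of class probabilities
#' @param labels true pain levels 0..3
#' @return object of class `np_eval_report` (a list)
#' @export
selective_report <- function(assessments, labels) {
  stopifnot(nrow(assessments) == length(labels))
  keep <- !assessments$abstain
  coverage <- mean(keep)
  if (!any(keep)) {
    return(structure(list(coverage = 0, n = length(labels),
                          accuracy = NA_real_, selective_accuracy = NA_real_,
                          f1_macro = NA_real_, qwk = NA_real_,
                          ece = NA_real_, mce = NA_real_, brier = NA_real_,
                          per_class = NULL),
                     class = "np_eval_report"))
  }
  yp <- assessments$level[keep]
  yt <- labels[keep]
  has_p <- all(paste0("p", 0:3) %in% names(assessments))
  P <- if (has_p) as.matrix(assessments[keep, paste0("p", 0:3)])
  structure(list(
    coverage = coverage, n = length(labels),
    accuracy = mean(yp == yt),
    selective_accuracy = mean(yp == yt),
    f1_macro = macro_f1(yt, yp),
    qwk = qwk(yt, yp),
    ece = if (has_p) ece(P, yt) else NA_real_,
    mce = if (has_p) mce(P, yt) else NA_real_,
    brier = if (has_p) brier(P, yt) else NA_real_,
    per_class = class_panel(yt, yp)
  ), class = "np_eval_report")
}

#' @export
print.np_eval_report <- function(x, ...) {
  cat(sprintf("<np_eval_report> n=%d coverage=%.3f acc=%.3f qwk=%.3f f1=%.3f\n",
              x$n, x$coverage, x$accuracy %||% NA, x$qwk %||% NA,
              x$f1_macro %||% NA))
  invisible(x)
}

#' Risk-coverage curve over abstention thresholds
#'
#' @param u per-sample uncertainties
#' @param correct per-sample correctness (logical), for the non-abstained
#'   prediction at `tau = 1`
#' @param taus thresholds to sweep
#' @return data.frame with `tau`, `coverage`, `selective_accuracy`
#' @export
risk_coverage_curve <- function(u, correct,
                                taus = seq(0.05, 1, by = 0.05)) {
  do.call(rbind, lapply(taus, function(tau) {
    keep <- u <= tau
    data.frame(tau = tau, coverage = mean(keep),
               selective_accuracy = if (any(keep)) mean(correct[keep])
                                    else NA_real_)
  }))
}
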