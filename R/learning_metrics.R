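# Classifier evaluation: confusion-matrix metrics, the F1 identity, the
# stratified dummy baseline, integer confusion-matrix reconstruction from
# printed metrics, and logistic-coefficient feature importance.

LABEL_LEVELS <- c("inactive", "active")

as_label <- function(x) factor(as.character(x), levels = LABEL_LEVELS)

#' Confusion-matrix evaluation of predicted labels
#'
#' `active` is the positive class. Accuracy = (TP+TN)/n, precision =
#' TP/(TP+FP), recall = TP/(TP+FN), F1 = 2PR/(P+R). Ratios with a zero
#' denominator are reported as `NaN` with a warning.
#'
#' @param pred,truth label vectors (`"active"`/`"inactive"`), equal length.
#' @return an `eval_report`: list with integer `TP`, `FP`, `FN`, `TN` and
#'   numeric `accuracy`, `precision`, `recall`, `f1`.
#' @export
evaluate <- function(pred, truth) {
  pred <- as_label(pred); truth <- as_label(truth)
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  if (length(pred) < 1) stop("empty label vectors")
  tp <- sum(pred == "active" & truth == "active")
  fp <- sum(pred == "active" & truth == "inactive")
  fn <- sum(pred == "inactive" & truth == "active")
  tn <- sum(pred == "inactive" & truth == "inactive")
  n <- tp + fp + fn + tn
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      return(NaN)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (is.nan(precision) || is.nan(recall) ||
            (precision == 0 && recall == 0)) {
    warning("F1 undefined")
    NaN
  } else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn,
                 accuracy = (tp + tn) / n, precision = precision,
                 recall = recall, f1 = f1),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> TP=%d FP=%d FN=%d TN=%d | acc=%.3f prec=%.3f rec=%.3f F1=%.3f\n",
              x$TP, x$FP, x$FN, x$TN,
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' F1 score from precision and recall
#'
#' Harmonic mean 2pr/(p+r). Vectorized.
#'
#' @param p,r precision and recall in \[0, 1\], not both zero.
#' @return F1 score(s).
#' @export
f1_from_precision_recall <- function(p, r) {
  if (any(p < 0 | p > 1 | r < 0 | r > 1)) stop("precision/recall outside [0, 1]")
  if (any(p == 0 & r == 0)) stop("F1 undefined at p = r = 0")
  2 * p * r / (p + r)
}

#' Stratified dummy classifier baseline
#'
#' Predicts labels by i.i.d. draws from the training class frequencies. For
#' a class prior p the expected accuracy on like-distributed test data is
#' p^2 + (1-p)^2.
#'
#' @param y_train training labels.
#' @param n_test number of predictions to draw.
#' @param seed integer seed.
#' @return factor of predicted labels.
#' @export
dummy_stratified <- function(y_train, n_test, seed = 1) {
  y_train <- as_label(y_train)
  if (length(y_train) == 0) stop("empty training labels")
  p_active <- mean(y_train == "active")
  with_seed(seed, {
    as_label(ifelse(stats::runif(n_test) < p_active, "active", "inactive"))
  })
}

#' Reconstruct integer confusion matrices from rounded printed metrics
#'
#' Exhaustively enumerates all (TP, FP, FN, TN) with TP+FP+FN+TN = n and
#' returns those whose accuracy, precision and recall round (half away from
#' zero, `decimals` places) to the given values. Used to check that printed
#' metric triples are mutually consistent.
#'
#' @param n total count (<= 200).
#' @param accuracy,precision,recall printed (rounded) metric values.
#' @param decimals reported decimal places (default 3).
#' @return data frame of solutions (columns TP, FP, FN, TN), zero rows if
#'   infeasible.
#' @export
reconstruct_confusion <- function(n, accuracy, precision, recall,
                                  decimals = 3) {
  if (n > 200) stop("n too large for exhaustive enumeration (max 200)")
  g <- expand.grid(TP = 0:n, FP = 0:n, FN = 0:n)
  g <- g[g$TP + g$FP + g$FN <= n, , drop = FALSE]
  g$TN <- n - g$TP - g$FP - g$FN
  acc <- (g$TP + g$TN) / n
  prec <- ifelse(g$TP + g$FP == 0, NA, g$TP / (g$TP + g$FP))
  rec <- ifelse(g$TP + g$FN == 0, NA, g$TP / (g$TP + g$FN))
  r <- function(x) round_half_away(x, decimals)
  ok <- !is.na(prec) & !is.na(rec) &
    r(acc) == r(accuracy) & r(prec) == r(precision) & r(rec) == r(recall)
  sol <- g[ok, c("TP", "FP", "FN", "TN"), drop = FALSE]
  rownames(sol) <- NULL
  sol
}

#' Normalized feature importance from logistic coefficients
#'
#' For a logistic model fit on standardized features, importance of feature i
#' is 100 * |c_i| / max_j |c_j|: the most important feature scores exactly
#' 100 and every other score is its percentage of that feature's weight.
#'
#' @param coefs named numeric coefficient vector (intercept excluded).
#' @return named numeric vector of scores in \[0, 100\].
#' @export
logistic_importance <- function(coefs) {
  if (length(coefs) == 0) stop("no coefficients")
  mx <- max(abs(coefs))
  if (mx == 0) {
    warning("all coefficients are zero; importance is all-zero")
    return(setNames(numeric(length(coefs)), names(coefs)))
  }
  100 * abs(coefs) / mx
}
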