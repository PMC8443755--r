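# Correlation screening (Pearson / point-biserial) and backward-selection
# multiple linear regression with multiple-correlation summary statistics.

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return correlation coefficient R, or `NA` with a warning for constant
#'   input.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Point-biserial correlation
#'
#' Pearson correlation between a continuous variable and a binary variable
#' coded 0/1.
#'
#' @param x numeric vector.
#' @param y binary labels (factor/character/logical/0-1), both classes
#'   present.
#' @return correlation coefficient R.
#' @export
point_biserial <- function(x, y) {
  yb <- if (is.numeric(y)) y else as.numeric(as_label(y) == "active")
  if (length(unique(yb)) < 2) {
    warning("one class absent; point-biserial undefined")
    return(NA_real_)
  }
  pearson_r(x, yb)
}

#' Rank features by absolute correlation with a response
#'
#' Pearson R for a continuous response, point-biserial R for a binary one
#' (auto-detected unless forced). Features are ordered by decreasing |R|,
#' ties broken by column order; constant features are reported as `NA` and
#' ranked last with a warning.
#'
#' @param X feature matrix with column names.
#' @param y response (continuous vector or binary labels).
#' @param method `"auto"`, `"pearson"` or `"point_biserial"`.
#' @return data frame with columns `feature`, `R`, `method`, ordered by
#'   decreasing |R|.
#' @export
rank_features <- function(X, y, method = c("auto", "pearson", "point_biserial")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (method == "auto") {
    binary <- is.factor(y) || is.character(y) || is.logical(y) ||
      length(unique(y)) == 2
    method <- if (binary) "point_biserial" else "pearson"
  }
  r <- vapply(seq_len(ncol(X)), function(j) {
    suppressWarnings(
      if (method == "pearson") pearson_r(X[, j], y)
      else point_biserial(X[, j], y))
  }, numeric(1))
  if (anyNA(r)) warning("constant features omitted from ranking: ",
                        paste(colnames(X)[is.na(r)], collapse = ", "))
  ord <- order(-abs(r), seq_along(r), na.last = TRUE)
  out <- data.frame(feature = colnames(X)[ord], R = r[ord],
                    method = method, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Ordinary least squares fit with multiple-correlation summary statistics
#'
#' Fits y ~ X with intercept and reports the summary statistics of the
#' regression tables: R (multiple correlation, the square root of R-squared),
#' adjusted R (sign-preserving square root of adjusted R-squared, floored at
#' 0), the overall F statistic and its p-value.
#'
#' @param X feature matrix (n > ncol + 1, full column rank).
#' @param y numeric response.
#' @return an `mlr_report`: list with `features`, `coefficients` (incl.
#'   intercept), `p_values` (per coefficient, excl. intercept), `R`, `adjR`,
#'   `F`, `probF`, `n_features`.
#' @export
fit_mlr <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  n <- nrow(X); kf <- ncol(X)
  if (n <= kf + 1) stop("need n > n_features + 1")
  qx <- qr(cbind(1, X))
  if (qx$rank < kf + 1) {
    drop_idx <- qx$pivot[seq(qx$rank + 1, kf + 1)] - 1
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(X)[drop_idx[drop_idx > 0]], collapse = ", "))
  }
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)
  r2 <- sm$r.squared
  ar2 <- sm$adj.r.squared
  adjr <- if (ar2 < 0) 0 else sqrt(ar2)
  fstat <- (r2 / kf) / ((1 - r2) / (n - kf - 1))
  probf <- stats::pf(fstat, kf, n - kf - 1, lower.tail = FALSE)
  pv <- sm$coefficients[-1, "Pr(>|t|)"]
  structure(list(features = colnames(X),
                 coefficients = stats::coef(fit),
                 p_values = setNames(pv, colnames(X)),
                 R = sqrt(r2), adjR = adjr, F = fstat, probF = probf,
                 n_features = kf),
            class = "mlr_report")
}

#' @export
print.mlr_report <- function(x, ...) {
  cat(sprintf("<mlr_report> %d features | R=%.3f adjR=%.3f F=%.3f probF=%.3g\n",
              x$n_features, x$R, x$adjR, x$F, x$probF))
  if (x$n_features > 0) cat("  ", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

# Intercept-only degenerate report
intercept_only_report <- function(y) {
  structure(list(features = character(0),
                 coefficients = c(`(Intercept)` = mean(y)),
                 p_values = numeric(0),
                 R = 0, adjR = 0, F = 0, probF = 1, n_features = 0L),
            class = "mlr_report")
}

#' Backward-selection multiple linear regression
#'
#' Starts from the `max_features` most correlated candidates (by |R| with
#' the response) and iteratively removes the coefficient with the largest
#' p-value, refitting after each removal, until every remaining coefficient
#' has p <= `p_threshold` and at most `max_features` remain. Deterministic.
#' If every feature is dropped an intercept-only report is returned with a
#' warning.
#'
#' @param X feature matrix with column names.
#' @param y numeric response.
#' @param p_threshold coefficient p-value threshold (default 0.05).
#' @param max_features cap on model size (default 10).
#' @return an `mlr_report`.
#' @export
backward_select <- function(X, y, p_threshold = 0.05, max_features = 10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  cap <- min(max_features, ncol(X), nrow(X) - 2)
  ranked <- rank_features(X, y, method = "pearson")
  cand <- ranked$feature[!is.na(ranked$R)][seq_len(min(cap, sum(!is.na(ranked$R))))]
  current <- cand
  repeat {
    if (length(current) == 0) {
      warning("all features eliminated; returning intercept-only model")
      return(intercept_only_report(y))
    }
    rep_ <- fit_mlr(X[, current, drop = FALSE], y)
    if (length(current) <= max_features && all(rep_$p_values <= p_threshold)) {
      return(rep_)
    }
    worst <- names(which.max(rep_$p_values))
    current <- setdiff(current, worst)
  }
}
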