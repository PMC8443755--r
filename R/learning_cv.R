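# Feature selection and stratified cross-validated tuning. Standardization
# and SelectKBest-style filtering are refit inside each training fold so no
# information from held-out rows leaks into preprocessing; CV metrics pool
# the out-of-fold predictions into a single confusion matrix.

#' Univariate ANOVA-F feature selection (SelectKBest)
#'
#' Scores every feature by its one-way ANOVA F statistic between the two
#' classes and returns the indices of the top `k`, ordered by decreasing F
#' with ties broken by original column order. Constant features score F = 0
#' with a warning.
#'
#' @param X numeric feature matrix.
#' @param y binary labels with both classes present.
#' @param k number of features to keep (1..ncol(X)).
#' @return integer vector of `k` column indices, ordered by decreasing F.
#' @export
kbest_select <- function(X, y, k) {
  X <- as.matrix(X)
  y <- droplevels(as_label(y))
  if (nlevels(y) < 2) stop("both classes must be present")
  if (k < 1 || k > ncol(X)) stop("k must be in 1..ncol(X)")
  f <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (stats::sd(x) == 0) {
      warning("constant feature at column ", j, "; F set to 0")
      return(0)
    }
    stats::anova(stats::lm(x ~ y))[["F value"]][1]
  }, numeric(1))
  ord <- order(-f, seq_along(f))
  ord[seq_len(k)]
}

#' Stratified k-fold assignment
#'
#' Shuffles within each class (seeded) and deals fold labels round-robin so
#' every fold preserves the class proportions as closely as possible.
#'
#' @param y labels.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return integer fold id per sample.
#' @export
stratified_folds <- function(y, folds = 5, seed = 1) {
  y <- as_label(y)
  if (any(table(y) < folds)) {
    stop("a class has fewer than ", folds,
         " members; use fewer folds")
  }
  fold <- integer(length(y))
  load <- integer(folds) # running fold sizes, to balance totals
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      n_cl <- length(idx)
      take <- rep(n_cl %/% folds, folds)
      rem <- n_cl %% folds
      if (rem > 0) {
        # give this class's remainder to the currently lightest folds
        o <- order(load, seq_len(folds))
        take[o[seq_len(rem)]] <- take[o[seq_len(rem)]] + 1L
      }
      fold[idx] <- rep(seq_len(folds), times = take)
      load <- load + take
    }
  })
  fold
}

# One CV pass: for each fold, fit preprocessing + kbest + model on the
# training rows only, predict the held-out rows; pool predictions.
# Returns list(pred = pooled out-of-fold labels, skipped = n failed folds).
cv_pooled_predictions <- function(spec, params, X, y, k = NULL, folds = 5,
                                  seed = 1) {
  X <- as.matrix(X)
  y <- as_label(y)
  fold <- stratified_folds(y, folds, seed)
  pred <- factor(rep(NA, length(y)), levels = LABEL_LEVELS)
  skipped <- 0L
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    sel <- if (is.null(k)) seq_len(ncol(X)) else {
      suppressWarnings(kbest_select(X[tr, , drop = FALSE], y[tr], k))
    }
    res <- tryCatch({
      fit <- fit_model(spec, params, X[tr, sel, drop = FALSE], y[tr])
      predict_model(fit, X[te, sel, drop = FALSE])
    }, error = function(e) NULL)
    if (is.null(res)) {
      skipped <- skipped + 1L
    } else {
      pred[te] <- res
    }
  }
  list(pred = pred, skipped = skipped)
}

#' Choose the number of selected features per model
#'
#' For each model specification at its default (first-grid-point)
#' hyperparameters, evaluates pooled stratified-CV accuracy at every `k` in
#' `k_range` (feature selection refit inside each fold) and returns the
#' accuracy-maximising `k`, ties resolved toward the smaller `k`. An upper
#' cap of 10 features guards against overfitting on small datasets.
#'
#' @param X feature matrix.
#' @param y labels.
#' @param specs list of `model_spec` objects.
#' @param k_range candidate feature counts (default `1:10`, clipped to
#'   `ncol(X)`).
#' @param folds CV folds (default 5).
#' @param seed integer seed.
#' @return named integer vector: best `k` per spec.
#' @export
choose_k <- function(X, y, specs, k_range = 1:10, folds = 5, seed = 1) {
  k_range <- k_range[k_range <= ncol(as.matrix(X))]
  if (length(k_range) == 0) stop("empty k_range after clipping to ncol(X)")
  out <- vapply(specs, function(spec) {
    acc <- vapply(k_range, function(k) {
      cv <- cv_pooled_predictions(spec, default_params(spec), X, y, k = k,
                                  folds = folds, seed = seed)
      ok <- !is.na(cv$pred)
      if (!any(ok)) return(NA_real_)
      mean(cv$pred[ok] == as_label(y)[ok])
    }, numeric(1))
    if (all(is.na(acc))) return(NA_integer_)
    as.integer(k_range[which.max(acc)])
  }, integer(1))
  names(out) <- vapply(specs, `[[`, "", "algorithm")
  out
}

#' Exhaustive grid search with stratified CV
#'
#' Evaluates every point of the Cartesian hyperparameter grid by pooled
#' out-of-fold accuracy under stratified `folds`-fold CV (preprocessing and
#' optional SelectKBest refit per fold), picks the best point (ties: first in
#' declared grid order), refits it on all rows, and reports the pooled CV
#' confusion-matrix metrics of the winning point.
#'
#' @param spec a `model_spec`.
#' @param X feature matrix.
#' @param y labels.
#' @param k number of features to select inside each fold (`NULL` = all).
#' @param folds CV folds (default 5).
#' @param seed integer seed.
#' @return list with `best_params`, `cv_report` (an `eval_report`), `fit`
#'   (final `zoo_fit` on all data), `selected` (feature indices used for the
#'   final fit) and `skipped` grid points.
#' @export
grid_search_cv <- function(spec, X, y, k = NULL, folds = 5, seed = 1) {
  X <- as.matrix(X)
  y <- as_label(y)
  grid <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  skipped <- 0L
  for (i in seq_len(nrow(grid))) {
    params <- as.list(grid[i, , drop = FALSE])
    cv <- cv_pooled_predictions(spec, params, X, y, k = k, folds = folds,
                                seed = seed)
    ok <- !is.na(cv$pred)
    if (!any(ok)) { skipped <- skipped + 1L; next }
    acc <- mean(cv$pred[ok] == y[ok])
    if (is.null(best) || acc > best$acc) {
      best <- list(acc = acc, params = params, pred = cv$pred)
    }
  }
  if (is.null(best)) stop("every grid point failed to fit")
  ok <- !is.na(best$pred)
  cv_report <- suppressWarnings(evaluate(best$pred[ok], y[ok]))
  sel <- if (is.null(k)) seq_len(ncol(X)) else {
    suppressWarnings(kbest_select(X, y, k))
  }
  fit <- fit_model(spec, best$params, X[, sel, drop = FALSE], y)
  list(best_params = best$params, cv_report = cv_report, fit = fit,
       selected = sel, skipped = skipped)
}

#' Tune one model and evaluate it on a holdout
#'
#' The full per-model workflow: choose `k` by CV on the training rows, tune
#' hyperparameters by exhaustive stratified-CV grid search, refit on all
#' training rows, and evaluate once on the holdout. A stratified dummy
#' baseline is evaluated on the same split.
#'
#' @param spec a `model_spec`.
#' @param X feature matrix (all rows).
#' @param y labels (all rows).
#' @param split a `split_spec` from [make_holdout()].
#' @param k_max feature-count cap (default 10).
#' @param folds CV folds (default 5).
#' @param seed integer seed.
#' @return list with `algorithm`, `k`, `selected` (feature names),
#'   `best_params`, `cv_report`, `holdout_report`, `dummy_report`.
#' @export
train_evaluate <- function(spec, X, y, split, k_max = 10, folds = 5,
                           seed = 1) {
  X <- as.matrix(X)
  y <- as_label(y)
  Xtr <- X[split$train, , drop = FALSE]
  ytr <- y[split$train]
  Xho <- X[split$holdout, , drop = FALSE]
  yho <- y[split$holdout]
  k <- choose_k(Xtr, ytr, list(spec), k_range = seq_len(min(k_max, ncol(X))),
                folds = folds, seed = seed)[[1]]
  gs <- grid_search_cv(spec, Xtr, ytr, k = k, folds = folds, seed = seed)
  pred_ho <- predict_model(gs$fit, Xho[, gs$selected, drop = FALSE])
  dummy <- dummy_stratified(ytr, length(yho), seed = seed)
  list(algorithm = spec$algorithm,
       k = k,
       selected = colnames(X)[gs$selected] %||% gs$selected,
       best_params = gs$best_params,
       cv_report = gs$cv_report,
       holdout_report = suppressWarnings(evaluate(pred_ho, yho)),
       dummy_report = suppressWarnings(evaluate(dummy, yho)))
}
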