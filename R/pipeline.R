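# End-to-end orchestration: featurize -> label -> split -> select -> tune ->
# evaluate -> report, under a single seeded configuration, writing CSV/JSON
# artifacts and a checksummed manifest.

#' Pipeline configuration
#'
#' @param out_dir output directory for artifacts.
#' @param seed integer seed governing all randomness (folds, splits, dummy).
#' @param cutoffs named response cutoffs (default [default_cutoffs()]:
#'   soluble yield 520 nM, total yield 1600 nM, soluble fraction 39%).
#' @param balance_cutoffs if `TRUE`, ignore `cutoffs` and balance each
#'   response at its median (used for synthetic data whose scale is
#'   arbitrary).
#' @param holdout_frac holdout fraction in (0, 0.5] (default 0.2).
#' @param contact_cutoff contact distance cutoff, Angstrom (default 4.0).
#' @param sphere_radius contact-sphere radius, Angstrom (default 8.0).
#' @param k_max feature-selection cap (default 10).
#' @param folds CV folds (default 5).
#' @param algorithms classifier ids to run (default the full zoo).
#' @param responses response columns to model.
#' @param synth optional `synth_config`; when given, features and phenotypes
#'   are generated synthetically.
#' @param features optional feature matrix (rows aligned with `phenotypes`).
#' @param phenotypes optional phenotype data frame (see [read_phenotypes()]).
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, cutoffs = default_cutoffs(),
                            balance_cutoffs = FALSE, holdout_frac = 0.2,
                            contact_cutoff = 4.0, sphere_radius = 8.0,
                            k_max = 10, folds = 5,
                            algorithms = ALGORITHMS,
                            responses = c("soluble_yield_nM",
                                          "total_yield_nM",
                                          "soluble_fraction_pct"),
                            synth = NULL, features = NULL,
                            phenotypes = NULL) {
  if (holdout_frac <= 0 || holdout_frac > 0.5)
    stop("holdout_frac must be in (0, 0.5]")
  if (folds < 2) stop("folds must be >= 2")
  if (any(cutoffs <= 0)) stop("cutoffs must be positive")
  if (contact_cutoff <= 0 || sphere_radius <= 0)
    stop("geometric cutoffs must be positive")
  algorithms <- match.arg(algorithms, ALGORITHMS, several.ok = TRUE)
  if (is.null(synth) && (is.null(features) || is.null(phenotypes)))
    stop("provide either 'synth' or both 'features' and 'phenotypes'")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 cutoffs = cutoffs, balance_cutoffs = balance_cutoffs,
                 holdout_frac = holdout_frac,
                 contact_cutoff = contact_cutoff,
                 sphere_radius = sphere_radius, k_max = k_max, folds = folds,
                 algorithms = algorithms, responses = responses,
                 synth = synth, features = features,
                 phenotypes = phenotypes),
            class = "pipeline_config")
}

report_row <- function(response, algorithm, split, rep) {
  data.frame(response = response, algorithm = algorithm, split = split,
             TP = rep$TP, FP = rep$FP, FN = rep$FN, TN = rep$TN,
             accuracy = round_half_away(rep$accuracy, 3),
             precision = round_half_away(rep$precision, 3),
             recall = round_half_away(rep$recall, 3),
             f1 = round_half_away(rep$f1, 3),
             stringsAsFactors = FALSE)
}

# Standardized logistic coefficients of a tuned LOG zoo_fit, for importance.
log_coefficients <- function(fit) {
  stopifnot(fit$algorithm == "LOG")
  co <- as.matrix(stats::coef(fit$model))[, 1]
  co <- co[!names(co) %in% c("(Intercept)", ".dummy")]
  co
}

#' Run the full analysis pipeline
#'
#' Executes every stage for each configured response variable: labelling at
#' the balance cutoff, protein-balanced holdout construction, correlation
#' screening, backward-selection MLR, per-algorithm feature selection +
#' stratified-CV grid-search tuning + holdout evaluation with a stratified
#' dummy baseline, and logistic feature importance. Writes feature and label
#' CSVs, a split JSON, correlation/MLR/metric/importance tables, and a
#' manifest with a config hash and per-artifact checksums.
#'
#' @param cfg a `pipeline_config`.
#' @return the manifest, invisibly (list with `config_hash`, `seed`,
#'   `artifacts`, plus in-memory `results` per response).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(name) {
    p <- file.path(cfg$out_dir, name)
    paths[[name]] <<- p
    p
  }

  if (!is.null(cfg$synth)) {
    ds <- make_labeled_dataset(cfg$synth)
    X <- ds$X
    pheno <- ds$records
  } else {
    X <- as.matrix(cfg$features)
    pheno <- cfg$phenotypes
    if (nrow(X) != nrow(pheno)) stop("features and phenotypes row mismatch")
  }

  utils::write.csv(cbind(pheno, as.data.frame(X)), emit("features.csv"),
                   row.names = FALSE)

  split <- make_holdout(pheno$protein, pheno$soluble_fraction_pct,
                        frac = cfg$holdout_frac, seed = cfg$seed)
  write_split(split, emit("split.json"))

  specs <- default_model_specs()[cfg$algorithms]
  summary_rows <- list()
  results <- list()
  labels_df <- data.frame(row = seq_len(nrow(X)))

  for (resp in cfg$responses) {
    vals <- pheno[[resp]]
    cutoff <- if (cfg$balance_cutoffs) stats::median(vals) else cfg$cutoffs[[resp]]
    y <- binarize_response(vals, cutoff)
    labels_df[[resp]] <- as.character(y)

    corr <- rank_features(X, y)
    utils::write.csv(corr, emit(paste0("correlations_", resp, ".csv")),
                     row.names = FALSE)
    mlr <- backward_select(X, vals, p_threshold = 0.05,
                           max_features = cfg$k_max)
    jsonlite::write_json(
      list(features = mlr$features, R = mlr$R, adjR = mlr$adjR, F = mlr$F,
           probF = mlr$probF, n_features = mlr$n_features),
      emit(paste0("mlr_", resp, ".json")), auto_unbox = TRUE, digits = NA)

    fits <- list()
    for (alg in cfg$algorithms) {
      res <- tryCatch(
        train_evaluate(specs[[alg]], X, y, split, k_max = cfg$k_max,
                       folds = cfg$folds, seed = cfg$seed),
        error = function(e) NULL)
      if (is.null(res)) next
      fits[[alg]] <- res
      summary_rows[[length(summary_rows) + 1]] <-
        report_row(resp, alg, "CV5", res$cv_report)
      summary_rows[[length(summary_rows) + 1]] <-
        report_row(resp, alg, "holdout", res$holdout_report)
    }
    if (length(fits) > 0) {
      dummy <- fits[[1]]$dummy_report
      summary_rows[[length(summary_rows) + 1]] <-
        report_row(resp, "DUMMY", "holdout", dummy)
    }
    jsonlite::write_json(
      lapply(fits, function(r) list(
        algorithm = r$algorithm, k = r$k, selected = r$selected,
        best_params = r$best_params,
        cv = unclass(r$cv_report), holdout = unclass(r$holdout_report))),
      emit(paste0("models_", resp, ".json")), auto_unbox = TRUE, digits = NA)

    if ("LOG" %in% names(fits)) {
      Xtr <- X[split$train, , drop = FALSE]
      ytr <- y[split$train]
      sel <- suppressWarnings(kbest_select(Xtr, ytr, fits$LOG$k))
      log_fit <- fit_model(specs$LOG, fits$LOG$best_params,
                           Xtr[, sel, drop = FALSE], ytr)
      imp <- logistic_importance(log_coefficients(log_fit))
      utils::write.csv(
        data.frame(feature = names(imp),
                   importance = round_half_away(unname(imp), 3)),
        emit(paste0("importance_", resp, ".csv")), row.names = FALSE)
      fits$LOG$importance <- imp
    }
    results[[resp]] <- list(split = split, correlations = corr, mlr = mlr,
                            models = fits, cutoff = cutoff)
  }

  utils::write.csv(labels_df, emit("labels.csv"), row.names = FALSE)
  metrics <- do.call(rbind, summary_rows)
  utils::write.csv(metrics, emit("metrics_summary.csv"), row.names = FALSE)

  cfg_json <- emit("config.json")
  cfg_list <- cfg[setdiff(names(cfg), c("features", "phenotypes"))]
  cfg_list$synth <- if (is.null(cfg$synth)) NULL else unclass(cfg$synth)
  jsonlite::write_json(cfg_list, cfg_json, auto_unbox = TRUE, digits = NA,
                       null = "null")

  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_json)),
    seed = cfg$seed,
    artifacts = lapply(paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    results = results,
    metrics = metrics
  )
  jsonlite::write_json(
    manifest[c("config_hash", "seed", "artifacts")],
    file.path(cfg$out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}
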