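# Classifier zoo backends. Each algorithm id maps to an established
# implementation (glmnet, MASS, e1071, class, kernlab); kernel ridge
# regression used as a classifier (+/-1 encoding, sign readout) is
# implemented directly. A uniform fit/predict interface hides backend
# differences from the CV machinery.

ALGORITHMS <- c("LOG", "KRR", "LDA", "QDA", "SVC", "NuSVC", "POL3", "KNN",
                "BNB", "GNB", "GPC")

#' Model specification for the classifier zoo
#'
#' @param algorithm one of `"LOG"` (ridge logistic regression), `"KRR"`
#'   (kernel ridge regression read out as a classifier), `"LDA"`, `"QDA"`,
#'   `"SVC"` (RBF SVM), `"NuSVC"`, `"POL3"` (degree-3 polynomial-kernel SVM),
#'   `"KNN"`, `"BNB"` (Bernoulli naive Bayes on median-binarized features),
#'   `"GNB"` (Gaussian naive Bayes), `"GPC"` (Gaussian process classifier).
#' @param grid named list of hyperparameter candidate values (non-empty).
#' @param standardize z-score features (fit on the training fold) before
#'   fitting. BNB instead binarizes at per-feature training medians.
#' @return a `model_spec`.
#' @export
model_spec <- function(algorithm, grid = NULL, standardize = NULL) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  defaults <- default_model_specs()[[algorithm]]
  grid <- grid %||% defaults$grid
  standardize <- standardize %||% defaults$standardize
  if (length(grid) == 0 || any(lengths(grid) == 0)) stop("grid must be non-empty")
  structure(list(algorithm = algorithm, grid = grid,
                 standardize = standardize),
            class = "model_spec")
}

#' Default model specifications for the full classifier zoo
#'
#' Hyperparameter grids are repo-defined and deliberately small so the
#' exhaustive grid search stays desk-scale.
#'
#' @return named list of `model_spec` objects.
#' @export
default_model_specs <- function() {
  raw <- list(
    LOG = list(grid = list(lambda = c(1e-4, 1e-3, 1e-2, 1e-1, 1)),
               standardize = TRUE),
    KRR = list(grid = list(lambda = c(0.01, 0.1, 1), sigma = c(0.05, 0.1, 0.5)),
               standardize = TRUE),
    LDA = list(grid = list(tol = 1e-4), standardize = TRUE),
    QDA = list(grid = list(tol = 1e-4), standardize = TRUE),
    SVC = list(grid = list(cost = c(0.1, 1, 10), gamma = c(0.01, 0.1, 1)),
               standardize = TRUE),
    NuSVC = list(grid = list(nu = c(0.25, 0.5), gamma = c(0.01, 0.1, 1)),
                 standardize = TRUE),
    POL3 = list(grid = list(cost = c(0.1, 1, 10), coef0 = c(0, 1)),
                standardize = TRUE),
    KNN = list(grid = list(k = c(1, 3, 5, 7)), standardize = TRUE),
    BNB = list(grid = list(laplace = c(0.5, 1)), standardize = FALSE),
    GNB = list(grid = list(laplace = 0), standardize = FALSE),
    GPC = list(grid = list(sigma = c(0.1, 1)), standardize = TRUE)
  )
  out <- lapply(names(raw), function(a) {
    structure(list(algorithm = a, grid = raw[[a]]$grid,
                   standardize = raw[[a]]$standardize),
              class = "model_spec")
  })
  names(out) <- names(raw)
  out
}

# First point of the declared grid (default hyperparameters for choose_k).
default_params <- function(spec) lapply(spec$grid, `[[`, 1)

# z-score parameters from training data; zero-sd columns left unscaled
standardizer <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(mu = mu, sd = sd)
}
apply_standardizer <- function(X, st) {
  sweep(sweep(X, 2, st$mu), 2, st$sd, `/`)
}

# Bernoulli binarization at per-feature medians (train-fitted)
binarizer <- function(X) list(med = apply(X, 2, stats::median))
apply_binarizer <- function(X, bz) {
  B <- sweep(X, 2, bz$med, `>`)
  as.data.frame(lapply(as.data.frame(B), factor, levels = c(FALSE, TRUE)))
}

rbf_kernel <- function(A, B, sigma) {
  # exp(-sigma * ||a - b||^2), kernlab's rbfdot convention
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * A %*% t(B)
  exp(-sigma * pmax(d2, 0))
}

#' Fit one classifier
#'
#' @param spec a `model_spec`.
#' @param params named list with one value per grid dimension.
#' @param X numeric feature matrix (training rows).
#' @param y training labels (`"inactive"`/`"active"`).
#' @return a `zoo_fit` carrying whatever the backend needs for prediction.
#' @export
fit_model <- function(spec, params, X, y) {
  X <- as.matrix(X)
  y <- as_label(y)
  if (nlevels(droplevels(y)) < 2) stop("training labels contain one class")
  pre <- NULL
  if (spec$standardize) {
    pre <- standardizer(X)
    X <- apply_standardizer(X, pre)
  }
  alg <- spec$algorithm
  fit <- switch(alg,
    LOG = {
      Xg <- if (ncol(X) == 1) cbind(X, .dummy = 0) else X
      glmnet::glmnet(Xg, y, family = "binomial", alpha = 0,
                     lambda = params$lambda, standardize = FALSE)
    },
    KRR = {
      yy <- ifelse(y == "active", 1, -1)
      K <- rbf_kernel(X, X, params$sigma)
      alpha <- solve(K + params$lambda * diag(nrow(X)), yy)
      list(alpha = alpha, Xtrain = X, sigma = params$sigma)
    },
    LDA = MASS::lda(X, grouping = y, tol = params$tol),
    QDA = MASS::qda(X, grouping = y, tol = params$tol),
    SVC = e1071::svm(X, y, type = "C-classification", kernel = "radial",
                     cost = params$cost, gamma = params$gamma, scale = FALSE),
    NuSVC = e1071::svm(X, y, type = "nu-classification", kernel = "radial",
                       nu = params$nu, gamma = params$gamma, scale = FALSE),
    POL3 = e1071::svm(X, y, type = "C-classification", kernel = "polynomial",
                      degree = 3, cost = params$cost, coef0 = params$coef0,
                      gamma = 1 / ncol(X), scale = FALSE),
    KNN = list(Xtrain = X, ytrain = y, k = params$k),
    BNB = {
      bz <- binarizer(X)
      Xb <- apply_binarizer(X, bz)
      list(nb = e1071::naiveBayes(Xb, y, laplace = params$laplace), bz = bz)
    },
    GNB = e1071::naiveBayes(as.data.frame(X), y, laplace = params$laplace),
    GPC = kernlab::gausspr(X, y, kernel = "rbfdot",
                           kpar = list(sigma = params$sigma))
  )
  structure(list(algorithm = alg, params = params, model = fit, pre = pre,
                 features = colnames(X)),
            class = "zoo_fit")
}

#' Predict labels from a fitted zoo model
#'
#' @param fit a `zoo_fit` from [fit_model()].
#' @param X feature matrix (same columns as training).
#' @return factor of predicted labels.
#' @export
predict_model <- function(fit, X) {
  X <- as.matrix(X)
  if (!is.null(fit$pre)) X <- apply_standardizer(X, fit$pre)
  alg <- fit$algorithm
  pred <- switch(alg,
    LOG = {
      Xg <- if (ncol(X) == 1) cbind(X, .dummy = 0) else X
      p <- stats::predict(fit$model, newx = Xg, type = "response")[, 1]
      ifelse(p > 0.5, "active", "inactive")
    },
    KRR = {
      K <- rbf_kernel(X, fit$model$Xtrain, fit$model$sigma)
      predict_krr_class(as.numeric(K %*% fit$model$alpha))
    },
    LDA = as.character(stats::predict(fit$model, X)$class),
    QDA = as.character(stats::predict(fit$model, X)$class),
    SVC = as.character(stats::predict(fit$model, X)),
    NuSVC = as.character(stats::predict(fit$model, X)),
    POL3 = as.character(stats::predict(fit$model, X)),
    KNN = as.character(class::knn(fit$model$Xtrain, X, fit$model$ytrain,
                                  k = fit$model$k)),
    BNB = as.character(stats::predict(
      fit$model$nb, apply_binarizer(X, fit$model$bz))),
    GNB = as.character(stats::predict(fit$model, as.data.frame(X))),
    GPC = as.character(kernlab::predict(fit$model, X, type = "response"))
  )
  as_label(pred)
}

#' Read out kernel ridge regression values as class labels
#'
#' KRR is trained on labels encoded -1/+1; a predicted value strictly above
#' zero is `active`, zero or below is `inactive`.
#'
#' @param values numeric regression outputs.
#' @return factor of labels.
#' @export
predict_krr_class <- function(values) {
  as_label(ifelse(values > 0, "active", "inactive"))
}
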