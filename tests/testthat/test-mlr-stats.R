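test_that("correlations match hand values and the point-biserial identity", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1), 1.0)
  expect_equal(pearson_r(1:10, -(1:10)), -1.0)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_warning(r <- pearson_r(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
  # point-biserial equals pearson under 0/1 coding
  set.seed(6)
  x <- rnorm(40)
  y <- factor(sample(c("active", "inactive"), 40, replace = TRUE),
              levels = c("inactive", "active"))
  expect_equal(point_biserial(x, y), pearson_r(x, as.numeric(y == "active")))
  # identical value distribution in both classes -> R = 0
  x0 <- rep(c(1, 2), 20)
  y0 <- factor(rep(c("active", "inactive"), each = 20),
               levels = c("inactive", "active"))
  expect_equal(point_biserial(x0, y0), 0.0)
  # separated classes with vanishing spread -> R -> 1
  set.seed(7)
  xs <- c(rnorm(25, 0, 1e-6), rnorm(25, 1, 1e-6))
  ys <- factor(rep(c("inactive", "active"), each = 25),
               levels = c("inactive", "active"))
  expect_gt(point_biserial(xs, ys), 0.999)
})

test_that("feature ranking orders by |R| with stable ties", {
  set.seed(9)
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    X <- matrix(rnorm(50 * 8), 50, dimnames = list(NULL, paste0("f", 1:8)))
    y <- 3 * X[, 4] + rnorm(50, 0, 0.8)
    rank_features(X, y)$feature[1] == "f4"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  set.seed(10)
  X <- matrix(rnorm(40 * 3), 40, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] + rnorm(40, 0, 0.5)
  Xdup <- cbind(X, a2 = X[, 1])
  rr <- rank_features(Xdup, y)
  expect_equal(rr$feature[1:2], c("a", "a2"))
  # |R| ordering invariant under affine rescaling of a column
  Xs <- X; Xs[, 1] <- -5 * Xs[, 1] + 2
  expect_equal(rank_features(Xs, y)$feature, rank_features(X, y)$feature)
})

test_that("OLS summary statistics match lm and the normal equations", {
  set.seed(13)
  X <- matrix(rnorm(50 * 3), 50, dimnames = list(NULL, c("a", "b", "c")))
  y <- 1 + 2 * X[, 1] - X[, 2] + rnorm(50, 0, 0.3)
  rep_ <- fit_mlr(X, y)
  # brute-force normal equations oracle
  A <- cbind(1, X)
  beta <- solve(t(A) %*% A, t(A) %*% y)
  expect_equal(unname(rep_$coefficients), as.vector(beta), tolerance = 1e-8)
  sm <- summary(lm(y ~ X))
  expect_equal(rep_$R, sqrt(sm$r.squared))
  expect_equal(rep_$F, unname(sm$fstatistic[1]))
  # exact linear response: R = 1, probF ~ 0 (lm warns about a perfect fit)
  ylin <- 3 * X[, 1] + 0.5 * X[, 3]
  rlin <- suppressWarnings(fit_mlr(X, ylin))
  expect_equal(rlin$R, 1.0, tolerance = 1e-7)
  expect_lt(rlin$probF, 1e-20)
  # single-feature fit: R equals |pearson r|
  r1 <- fit_mlr(X[, 1, drop = FALSE], y)
  expect_equal(r1$R, abs(pearson_r(X[, 1], y)))
  # adjusted R never exceeds R
  expect_lte(rep_$adjR, rep_$R)
  # collinear design is rejected with the column named
  Xbad <- cbind(X, dup = X[, 1])
  expect_error(fit_mlr(Xbad, y), "dup")
})

test_that("probF is uniform under the null", {
  pvals <- vapply(1:200, function(s) {
    set.seed(s)
    X <- matrix(rnorm(50 * 3), 50)
    fit_mlr(X, rnorm(50))$probF
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("backward selection keeps planted predictors and drops noise", {
  # a perfect predictor among noise is always retained, dominates the fit,
  # and the model stays small; exact singleton recovery happens in the
  # majority of seeds (backward elimination at per-coefficient alpha = 0.05
  # retains a best-of-nine noise column whenever its p-value survives, which
  # has probability ~ 1 - 0.95^9)
  runs <- lapply(1:100, function(s) {
    set.seed(s)
    X <- matrix(rnorm(50 * 10), 50, dimnames = list(NULL, paste0("f", 1:10)))
    y <- 4 * X[, 1] + rnorm(50, 0, 0.05)
    suppressWarnings(backward_select(X, y))
  })
  expect_true(all(vapply(runs, function(r) "f1" %in% r$features, logical(1))))
  expect_true(all(vapply(runs, function(r)
    r$coefficients[["f1"]] > 3.5, logical(1))))
  expect_lte(max(vapply(runs, `[[`, numeric(1), "n_features")), 4)
  expect_gte(mean(vapply(runs, function(r)
    identical(r$features, "f1"), logical(1))), 0.5)
  # planted 3-feature signal: all three retained with correct signs
  recovered <- vapply(1:50, function(s) {
    set.seed(s)
    X <- matrix(rnorm(50 * 10), 50, dimnames = list(NULL, paste0("f", 1:10)))
    y <- 3 * X[, 1] + 2 * X[, 2] + 1 * X[, 3] + rnorm(50, 0, 0.5)
    r <- suppressWarnings(backward_select(X, y))
    all(c("f1", "f2", "f3") %in% r$features) &&
      all(r$coefficients[c("f1", "f2", "f3")] > 0)
  }, logical(1))
  expect_gte(mean(recovered), 0.9)
  # degenerate: everything dropped -> intercept-only with warning
  set.seed(1)
  Xn <- matrix(rnorm(30 * 2), 30, dimnames = list(NULL, c("u", "v")))
  got_zero <- FALSE
  for (s in 1:20) {
    set.seed(s)
    yn <- rnorm(30)
    r <- suppressWarnings(backward_select(Xn, yn))
    if (r$n_features == 0) {
      got_zero <- TRUE
      expect_equal(r$R, 0)
      break
    }
  }
  expect_true(got_zero)
})
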