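test_that("fold assignment partitions subjects with near-equal sizes", {
  folds <- make_folds(445, 10, seed = 3)
  expect_equal(length(folds), 445)
  sizes <- as.numeric(table(folds))
  expect_true(all(sizes %in% c(44, 45)))
  expect_equal(sum(sizes), 445)
  expect_identical(folds, make_folds(445, 10, seed = 3))
  expect_error(make_folds(5, 10, seed = 1), "k")
})

test_that("cross-validation is deterministic given (data, config, seed)", {
  co <- make_test_cohort(seed = 91, n_subjects = 40, n_features = 10,
                         n_scores = 2, n_timepoints = 2, support_size = 3)
  a <- smtl_cv(co$x, co$y, lambda1_grid = c(0.1, 1), lambda2_grid = c(1, 10),
               n_folds = 5, inner_folds = 3, seed = 17)
  b <- smtl_cv(co$x, co$y, lambda1_grid = c(0.1, 1), lambda2_grid = c(1, 10),
               n_folds = 5, inner_folds = 3, seed = 17)
  expect_identical(a, b)
  # fold sizes differ by at most one and selections are shared across cells
  sizes <- as.numeric(table(a$fold_assignments))
  expect_lte(diff(range(sizes)), 1)
  expect_true(all(vapply(a$per_fold, function(pf)
    length(pf$selection$selected) >= 1, TRUE)))
  expect_true(all(a$per_cell$rmse >= 0))
  ok_corr <- a$per_cell$corr[!is.na(a$per_cell$corr)]
  expect_true(all(ok_corr >= -1 & ok_corr <= 1))
})

test_that("training-fold records are untouched by test-row perturbations", {
  co <- make_test_cohort(seed = 92, n_subjects = 40, n_features = 10,
                         n_scores = 2, n_timepoints = 2, support_size = 3)
  grids <- list(lambda1_grid = c(0.1, 1), lambda2_grid = c(1, 10))
  a <- do.call(smtl_cv, c(list(co$x, co$y, n_folds = 5, inner_folds = 3,
                               seed = 21), grids))
  f <- 2
  te <- which(a$fold_assignments == f)
  x2 <- co$x
  x2[te, ] <- x2[te, ] + matrix(rnorm(length(te) * ncol(x2), sd = 5),
                                length(te))
  b <- do.call(smtl_cv, c(list(x2, co$y, n_folds = 5, inner_folds = 3,
                               seed = 21), grids))
  # same folds, and everything derived from training rows of fold f is
  # bit-identical: normalization stats, graphs, lambdas, selection
  expect_identical(a$fold_assignments, b$fold_assignments)
  expect_identical(a$per_fold[[f]]$center, b$per_fold[[f]]$center)
  expect_identical(a$per_fold[[f]]$scale, b$per_fold[[f]]$scale)
  expect_identical(a$per_fold[[f]]$graph_fingerprint,
                   b$per_fold[[f]]$graph_fingerprint)
  expect_identical(a$per_fold[[f]]$lambda1, b$per_fold[[f]]$lambda1)
  expect_identical(a$per_fold[[f]]$lambda2, b$per_fold[[f]]$lambda2)
  expect_identical(a$per_fold[[f]]$selection, b$per_fold[[f]]$selection)
})

test_that("lasso_select exercises its error and least-squares limits", {
  set.seed(93)
  x <- matrix(rnorm(200), 50, 4)
  y <- drop(x %*% c(2, -1, 0, 0)) + rnorm(50, sd = 0.1)
  expect_error(lasso_select(x, y, lambda = 1e6), "empty selection")
  expect_equal(lasso_select(x, y, lambda = 0.05), c(1, 2))
  # lambda = 0 on full-rank x reproduces least squares
  fit0 <- glmnet::glmnet(x, y, alpha = 1, lambda = 0, standardize = FALSE,
                         thresh = 1e-12)
  ols <- coef(lm(y ~ x))
  expect_equal(unname(as.numeric(coef(fit0))), unname(as.numeric(ols)),
               tolerance = 1e-4)
})

test_that("lasso_baseline runs the identical protocol and reports per cell", {
  co <- make_test_cohort(seed = 94, n_subjects = 40, n_features = 10,
                         n_scores = 2, n_timepoints = 2, support_size = 3)
  rep <- lasso_baseline(co$x, co$y, n_folds = 5, inner_folds = 3, seed = 31)
  expect_s3_class(rep, "smtl_cv_report")
  expect_equal(rep$method, "lasso")
  expect_equal(nrow(rep$summary), 4)
  expect_identical(rep$fold_assignments,
                   smtl_cv(co$x, co$y, lambda1_grid = 1, lambda2_grid = 1,
                           n_folds = 5, inner_folds = 3,
                           seed = 31)$fold_assignments)
})
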