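test_that("with no regularization the fit is ordinary least squares", {
  co <- make_test_cohort(seed = 11, n_subjects = 100, n_features = 30,
                         n_scores = 2, n_timepoints = 3, support_size = 5)
  fit <- smtl_fit(co$x, co$y, lambda1 = 0, lambda2 = 0)
  XtX <- crossprod(co$x)
  for (t in 1:3) {
    W_ols <- solve(XtX, crossprod(co$x, as_score_list(co$y)[[t]]))
    expect_equal(unname(fit$weights$per_time[[t]]), unname(W_ols),
                 tolerance = 1e-6)
  }
  expect_true(fit$converged)
})

test_that("objective trace is non-increasing across the lambda grid", {
  co <- make_test_cohort(seed = 12, n_subjects = 40, n_features = 15,
                         n_scores = 2, n_timepoints = 3, support_size = 4)
  for (l1 in c(0, 0.1, 1, 10))
    for (l2 in c(0, 0.1, 1, 10)) {
      fit <- smtl_fit(co$x, co$y, l1, l2)
      tr <- fit$objective_trace
      expect_true(all(diff(tr) <= 1e-9 * pmax(abs(tr[-length(tr)]), 1)),
                  info = sprintf("lambda1=%g lambda2=%g", l1, l2))
      expect_lte(fit$n_iter, 50)
    }
})

test_that("permuting feature columns permutes weight rows and keeps the objective", {
  co <- make_test_cohort(seed = 13, n_subjects = 30, n_features = 12,
                         n_scores = 2, n_timepoints = 2, support_size = 3)
  fit <- smtl_fit(co$x, co$y, 0.5, 2)
  set.seed(99)
  perm <- sample(12)
  fit_p <- smtl_fit(co$x[, perm], co$y, 0.5, 2)
  expect_equal(unname(fit_p$weights$unfolded), unname(fit$weights$unfolded[perm, ]),
               tolerance = 1e-8)
  expect_equal(tail(fit_p$objective_trace, 1), tail(fit$objective_trace, 1),
               tolerance = 1e-9)
})

test_that("row sparsity is joint: per-time rows are bounded by the unfolded norm", {
  co <- make_test_cohort(seed = 14, n_subjects = 40, n_features = 20,
                         n_scores = 2, n_timepoints = 3, support_size = 4)
  fit <- smtl_fit(co$x, co$y, 0.1, 10)
  for (t in 1:3) {
    per_t <- apply(abs(fit$weights$per_time[[t]]), 1, max)
    expect_true(all(per_t <= 10 * fit$row_norms + 1e-12))
  }
})

test_that("total row-norm mass shrinks as lambda2 grows", {
  co <- make_test_cohort(seed = 15, n_subjects = 50, n_features = 20,
                         n_scores = 2, n_timepoints = 3, support_size = 5)
  mass <- vapply(c(0.1, 1, 5, 20, 50), function(l2)
    sum(smtl_fit(co$x, co$y, 0.1, l2)$row_norms), 0)
  expect_true(all(diff(mass) <= 1e-8))
})

test_that("fit validates its inputs", {
  co <- make_test_cohort(seed = 16, n_subjects = 10, n_features = 4,
                         n_scores = 2, n_timepoints = 2, support_size = 2)
  ybad <- as_score_list(co$y)
  ybad[[1]] <- ybad[[1]][1:5, , drop = FALSE]
  expect_error(smtl_fit(co$x, ybad), "must be 10 x 2")
  xna <- co$x; xna[1, 1] <- NA
  expect_error(smtl_fit(xna, co$y), "missing")
  expect_error(smtl_fit(co$x, co$y, lambda1 = -1), ">= 0")
})
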