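# Nested cross-validation for the joint-selection pipeline and the per-task
# Lasso baseline. All statistics that could leak (normalization, similarity
# graphs, hyperparameter choices, selection) are computed from training rows
# only; the per-fold records keep enough of them to audit that.

#' Seeded subject-level fold assignment
#'
#' @param n number of subjects.
#' @param k number of folds; fold sizes differ by at most 1.
#' @param seed integer seed (the caller's RNG state is untouched).
#' @return integer vector of fold labels in 1..k.
#' @export
make_folds <- function(n, k, seed) {
  if (k < 2 || k > n) stop("'k' must be in 2..n")
  with_seed(seed, sample(rep(seq_len(k), length.out = n)))
}

# Normalize train/test with training statistics, fit, select, train the SVR
# grid and predict the test block. The workhorse shared by the outer loop
# and the inner hyperparameter search.
fit_select_predict <- function(xtr, ytr, xte, lambda1, lambda2, control,
                               rule, threshold, top_k, cost, epsilon) {
  ztr <- z_normalize(xtr)
  zte <- z_normalize(xte, stats = norm_stats(ztr))
  graphs <- smtl_graphs(ztr, ytr, control$sigma)
  fit <- smtl_fit(ztr, ytr, lambda1, lambda2, control, graphs = graphs)
  sel <- rank_features(fit, rule = rule, threshold = threshold, k = top_k)
  grid <- train_predictors(ztr[, sel$selected, drop = FALSE], ytr,
                           cost = cost, epsilon = epsilon)
  pred <- predict(grid, zte[, sel$selected, drop = FALSE])
  list(pred = pred, selection = sel, fit = fit,
       center = attr(ztr, "center"), scale = attr(ztr, "scale"),
       graph_fingerprint = c(
         L_f = sum(abs(graphs$L_f)), L_s = sum(abs(graphs$L_s)),
         L_c = sum(vapply(graphs$L_c, function(L) sum(abs(L)), 0))))
}

cell_rmse_sum <- function(pred, y_list) {
  s <- 0
  for (t in seq_along(y_list))
    for (cc in seq_len(ncol(y_list[[t]])))
      s <- s + sqrt(mean((pred[t, , cc] - y_list[[t]][, cc])^2))
  s
}

#' Nested cross-validated evaluation of the joint-selection pipeline
#'
#' Outer `n_folds`-fold split at subject level (seeded). Within each outer
#' training fold an inner `inner_folds`-fold search over the
#' `(lambda1, lambda2)` grid picks the pair minimizing the mean validation
#' RMSE summed over all (time, score) cells; the model is then refit on the
#' whole training fold, features are selected once (shared by every cell),
#' per-cell linear epsilon-SVRs are trained on the unit-norm selected
#' features, and the held-out fold is predicted. Normalization statistics,
#' similarity graphs and hyperparameters never see test rows.
#'
#' @param x numeric S x F raw feature matrix (not yet normalized).
#' @param y list of T score matrices (S x C) or T x S x C array.
#' @param lambda1_grid,lambda2_grid candidate regularization weights
#'   (defaults `10^(-3:3)`).
#' @param n_folds outer folds (default 10).
#' @param inner_folds inner folds for hyperparameter choice (default 5).
#' @param seed integer seed controlling every random split.
#' @param control an [smtl_control()] list.
#' @param rule,threshold,top_k feature selection rule, see [rank_features()].
#' @param cost,epsilon SVR parameters.
#' @param time_labels,score_names optional labels for reporting.
#' @param verbose log progress to stderr.
#' @return object of class `smtl_cv_report`; see Details in the package
#'   vignette. Key components: `summary` (per-cell mean/sd Corr and RMSE),
#'   `per_cell` (per fold), `predictions` (long data.frame), `per_fold`
#'   (selection, hyperparameters and leakage-audit records),
#'   `fold_assignments`.
#' @export
smtl_cv <- function(x, y, lambda1_grid = 10^(-3:3), lambda2_grid = 10^(-3:3),
                    n_folds = 10, inner_folds = 5, seed,
                    control = smtl_control(),
                    rule = c("relative_threshold", "top_k"), threshold = 1e-3,
                    top_k = NULL, cost = 1, epsilon = 0.1,
                    time_labels = NULL, score_names = NULL, verbose = FALSE) {
  rule <- match.arg(rule)
  if (missing(seed)) stop("'seed' is required")
  if (length(lambda1_grid) == 0 || length(lambda2_grid) == 0)
    stop("lambda grids must be non-empty")
  x <- as.matrix(x)
  y <- as_score_list(y)
  S <- nrow(x); Tn <- length(y); C <- ncol(y[[1]])
  if (S < 2 * n_folds) stop("too few subjects for ", n_folds, " folds")
  time_labels <- time_labels %||% (names(y) %||% paste0("T", seq_len(Tn)))
  score_names <- score_names %||%
    (colnames(y[[1]]) %||% paste0("score_", seq_len(C)))
  subject_ids <- rownames(x) %||% sprintf("subj_%04d", seq_len(S))
  combos <- expand.grid(lambda1 = lambda1_grid, lambda2 = lambda2_grid,
                        KEEP.OUT.ATTRS = FALSE)
  folds <- make_folds(S, n_folds, seed)
  if (verbose)
    message(sprintf("cv: S=%d F=%d C=%d T=%d, %d-fold outer / %d-fold inner, %d lambda pairs",
                    S, ncol(x), C, Tn, n_folds, inner_folds, nrow(combos)))

  per_fold <- vector("list", n_folds)
  pred_rows <- list()
  cell_rows <- list()
  for (f in seq_len(n_folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    xtr <- x[tr, , drop = FALSE]
    ytr <- lapply(y, function(Yt) Yt[tr, , drop = FALSE])

    best <- 1L
    if (nrow(combos) > 1) {
      ifolds <- make_folds(length(tr), inner_folds, derive_seed(seed, f))
      score <- numeric(nrow(combos))
      for (g in seq_len(nrow(combos))) {
        tot <- 0
        for (i in seq_len(inner_folds)) {
          itr <- which(ifolds != i); ite <- which(ifolds == i)
          res <- fit_select_predict(
            xtr[itr, , drop = FALSE],
            lapply(ytr, function(Yt) Yt[itr, , drop = FALSE]),
            xtr[ite, , drop = FALSE],
            combos$lambda1[g], combos$lambda2[g], control,
            rule, threshold, top_k, cost, epsilon)
          tot <- tot + cell_rmse_sum(
            res$pred, lapply(ytr, function(Yt) Yt[ite, , drop = FALSE]))
        }
        score[g] <- tot / inner_folds
      }
      best <- which.min(score)
    }
    l1 <- combos$lambda1[best]; l2 <- combos$lambda2[best]
    if (verbose)
      message(sprintf("fold %d: lambda1=%g lambda2=%g", f, l1, l2))

    res <- fit_select_predict(xtr, ytr, x[te, , drop = FALSE],
                              l1, l2, control, rule, threshold, top_k,
                              cost, epsilon)
    per_fold[[f]] <- list(
      fold = f, lambda1 = l1, lambda2 = l2,
      selection = unclass(res$selection), n_test = length(te),
      center = res$center, scale = res$scale,
      graph_fingerprint = res$graph_fingerprint,
      n_iter = res$fit$n_iter, converged = res$fit$converged)
    for (t in seq_len(Tn))
      for (cc in seq_len(C)) {
        actual <- y[[t]][te, cc]
        predicted <- res$pred[t, , cc]
        m <- withCallingHandlers(
          evaluate_predictions(predicted, actual),
          warning = function(w) invokeRestart("muffleWarning"))
        cell_rows[[length(cell_rows) + 1L]] <- data.frame(
          time = time_labels[t], score = score_names[cc], fold = f,
          corr = m$corr, rmse = m$rmse, n_test = length(te),
          stringsAsFactors = FALSE)
        pred_rows[[length(pred_rows) + 1L]] <- data.frame(
          subject = subject_ids[te], time = time_labels[t],
          score = score_names[cc], fold = f,
          predicted = predicted, actual = actual, stringsAsFactors = FALSE)
      }
  }
  per_cell <- do.call(rbind, cell_rows)
  predictions <- do.call(rbind, pred_rows)
  summary <- aggregate_cells(per_cell, time_labels, score_names)
  structure(list(
    schema = "smtl_cv_report/1", method = "smtl", seed = seed,
    n_folds = n_folds, inner_folds = inner_folds,
    lambda1_grid = lambda1_grid, lambda2_grid = lambda2_grid,
    dims = list(S = S, F = ncol(x), C = C, T = Tn),
    time_labels = time_labels, score_names = score_names,
    fold_assignments = stats::setNames(folds, subject_ids),
    per_fold = per_fold, per_cell = per_cell, predictions = predictions,
    summary = summary), class = "smtl_cv_report")
}

aggregate_cells <- function(per_cell, time_labels, score_names) {
  cells <- expand.grid(time = time_labels, score = score_names,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- per_cell[per_cell$time == cells$time[i] &
                    per_cell$score == cells$score[i], ]
    data.frame(time = cells$time[i], score = cells$score[i],
               mean_corr = mean(sub$corr, na.rm = TRUE),
               sd_corr = sd(sub$corr[!is.na(sub$corr)]),
               mean_rmse = mean(sub$rmse), sd_rmse = sd(sub$rmse),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.smtl_cv_report <- function(x, ...) {
  cat(sprintf("%s cross-validation report (%d folds, seed %s)\n",
              x$method, x$n_folds, format(x$seed)))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Per-task l1 (Lasso) selection for one response vector
#'
#' Thin wrapper over [glmnet::glmnet()] used by the baseline: selects the
#' features with nonzero coefficients at the given penalty.
#'
#' @param x numeric matrix (already normalized).
#' @param y_vec numeric response.
#' @param lambda l1 penalty.
#' @return increasing integer vector of selected feature indices; errors if
#'   the selection is empty (penalty too large).
#' @export
lasso_select <- function(x, y_vec, lambda) {
  fit <- glmnet::glmnet(x, y_vec, alpha = 1, lambda = lambda,
                        standardize = FALSE, thresh = 1e-12)
  sel <- which(as.numeric(coef(fit))[-1] != 0)
  if (length(sel) == 0)
    stop("empty selection: the l1 penalty removed every feature")
  sel
}

#' Per-task Lasso baseline under the identical CV protocol
#'
#' Same outer folds, normalization discipline and SVR predictors as
#' [smtl_cv()], but feature selection is an independent l1-penalized linear
#' model per (time, score) cell, with the penalty chosen per cell by inner
#' cross-validation on the training fold. This is the single-task comparator
#' for the joint selector.
#'
#' @inheritParams smtl_cv
#' @return an `smtl_cv_report` with `method = "lasso"`. Each fold's
#'   `selection` records the union of the per-cell selections with mean
#'   absolute coefficients as weights.
#' @export
lasso_baseline <- function(x, y, n_folds = 10, inner_folds = 5, seed,
                           cost = 1, epsilon = 0.1, time_labels = NULL,
                           score_names = NULL, verbose = FALSE) {
  if (missing(seed)) stop("'seed' is required")
  x <- as.matrix(x)
  y <- as_score_list(y)
  S <- nrow(x); Tn <- length(y); C <- ncol(y[[1]])
  time_labels <- time_labels %||% (names(y) %||% paste0("T", seq_len(Tn)))
  score_names <- score_names %||%
    (colnames(y[[1]]) %||% paste0("score_", seq_len(C)))
  subject_ids <- rownames(x) %||% sprintf("subj_%04d", seq_len(S))
  folds <- make_folds(S, n_folds, seed)

  per_fold <- vector("list", n_folds)
  pred_rows <- list(); cell_rows <- list()
  for (f in seq_len(n_folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    ztr <- z_normalize(x[tr, , drop = FALSE])
    zte <- z_normalize(x[te, , drop = FALSE], stats = norm_stats(ztr))
    ifold <- make_folds(length(tr), inner_folds, derive_seed(seed, f))
    coef_abs <- matrix(0, ncol(x), 0)
    sel_union <- integer(0)
    for (t in seq_len(Tn))
      for (cc in seq_len(C)) {
        yv <- y[[t]][tr, cc]
        cvfit <- glmnet::cv.glmnet(ztr, yv, alpha = 1, foldid = ifold,
                                   standardize = FALSE)
        # smallest-CV-error lambda that still selects at least one feature
        nz <- cvfit$nzero > 0
        if (!any(nz)) stop("lasso path selected no features in fold ", f)
        idx <- which(nz)[which.min(cvfit$cvm[nz])]
        lam <- cvfit$lambda[idx]
        cf <- as.numeric(coef(cvfit$glmnet.fit, s = lam))[-1]
        sel <- which(cf != 0)
        sel_union <- union(sel_union, sel)
        coef_abs <- cbind(coef_abs, abs(cf))
        xs_tr <- ztr[, sel, drop = FALSE]
        model <- svr_linear(unit_norm_rows(xs_tr), yv, cost, epsilon)
        predicted <- predict(model, unit_norm_rows(zte[, sel, drop = FALSE]))
        actual <- y[[t]][te, cc]
        m <- withCallingHandlers(
          evaluate_predictions(predicted, actual),
          warning = function(w) invokeRestart("muffleWarning"))
        cell_rows[[length(cell_rows) + 1L]] <- data.frame(
          time = time_labels[t], score = score_names[cc], fold = f,
          corr = m$corr, rmse = m$rmse, n_test = length(te),
          stringsAsFactors = FALSE)
        pred_rows[[length(pred_rows) + 1L]] <- data.frame(
          subject = subject_ids[te], time = time_labels[t],
          score = score_names[cc], fold = f,
          predicted = predicted, actual = actual, stringsAsFactors = FALSE)
      }
    rn <- rowMeans(coef_abs)
    per_fold[[f]] <- list(
      fold = f, lambda1 = NA_real_, lambda2 = NA_real_,
      selection = list(ranked = order(-rn, seq_along(rn)),
                       selected = sort(sel_union), row_norms = rn,
                       rule = "lasso_cv_per_cell"),
      n_test = length(te), center = attr(ztr, "center"),
      scale = attr(ztr, "scale"))
    if (verbose) message(sprintf("lasso fold %d: %d features in union",
                                 f, length(sel_union)))
  }
  per_cell <- do.call(rbind, cell_rows)
  structure(list(
    schema = "smtl_cv_report/1", method = "lasso", seed = seed,
    n_folds = n_folds, inner_folds = inner_folds,
    lambda1_grid = numeric(0), lambda2_grid = numeric(0),
    dims = list(S = S, F = ncol(x), C = C, T = Tn),
    time_labels = time_labels, score_names = score_names,
    fold_assignments = stats::setNames(folds, subject_ids),
    per_fold = per_fold, per_cell = per_cell,
    predictions = do.call(rbind, pred_rows),
    summary = aggregate_cells(per_cell, time_labels, score_names)),
    class = "smtl_cv_report")
}
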