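#' Rank and select features by unfolded row norm
#'
#' Features are ranked by the Euclidean norm of their row in the unfolded
#' weight matrix (large norm = influential at some time point/score), ties
#' broken by ascending original index so the ordering is deterministic.
#' Selection keeps either every row above a relative threshold (default:
#' `threshold` times the maximum row norm, since the reweighted solver never
#' produces exact zeros) or the top `k` rows.
#'
#' @param fit an `smtl_fit` object, or a numeric vector of row norms.
#' @param rule `"relative_threshold"` (default) or `"top_k"`.
#' @param threshold relative threshold in (0, 1) for the default rule
#'   (default `1e-3`).
#' @param k number of features kept under the `top_k` rule.
#' @return object of class `smtl_selection`: list with `ranked` (permutation
#'   of 1..F, best first), `selected` (increasing indices), `row_norms` and
#'   `rule` (descriptor string).
#' @export
rank_features <- function(fit, rule = c("relative_threshold", "top_k"),
                          threshold = 1e-3, k = NULL) {
  rule <- match.arg(rule)
  rn <- if (inherits(fit, "smtl_fit")) fit$row_norms else as.numeric(fit)
  if (any(!is.finite(rn))) stop("row norms must be finite")
  if (all(rn == 0)) stop("empty model: all weight rows are zero")
  ranked <- order(-rn, seq_along(rn))
  if (rule == "relative_threshold") {
    if (threshold <= 0) stop("'threshold' must be positive")
    selected <- which(rn > threshold * max(rn))
    desc <- sprintf("relative_threshold(%g)", threshold)
  } else {
    if (is.null(k) || k < 1 || k > length(rn))
      stop("'k' must be in 1..", length(rn))
    selected <- sort(ranked[seq_len(k)])
    desc <- sprintf("top_k(%d)", k)
  }
  structure(list(ranked = ranked, selected = selected, row_norms = rn,
                 rule = desc), class = "smtl_selection")
}

#' Train the grid of per-(time, score) support vector regressors
#'
#' One independent linear epsilon-SVR per (time point, score type) cell, all
#' sharing the same selected feature columns. Each subject's selected feature
#' vector is scaled to unit Euclidean norm before training; apply the same
#' scaling at prediction time (done by [predict.smtl_predictor_grid()]).
#'
#' @param x_selected numeric S x k matrix of selected (normalized) features.
#' @param y list of T score matrices or T x S x C array.
#' @param cost,epsilon SVR parameters (LIBSVM defaults 1 and 0.1).
#' @return object of class `smtl_predictor_grid`: T x C list matrix of
#'   `svr_linear` models.
#' @export
train_predictors <- function(x_selected, y, cost = 1, epsilon = 0.1) {
  x_selected <- as.matrix(x_selected)
  if (nrow(x_selected) < 2) stop("need at least 2 training subjects")
  if (ncol(x_selected) < 1) stop("need at least 1 selected feature")
  y <- as_score_list(y)
  Tn <- length(y); C <- ncol(y[[1]])
  xs <- unit_norm_rows(x_selected)
  grid <- vector("list", Tn * C)
  dim(grid) <- c(Tn, C)
  for (t in seq_len(Tn))
    for (cc in seq_len(C))
      grid[[t, cc]] <- svr_linear(xs, y[[t]][, cc], cost = cost,
                                  epsilon = epsilon)
  structure(list(models = grid, p = ncol(x_selected)),
            class = "smtl_predictor_grid")
}

#' @export
predict.smtl_predictor_grid <- function(object, newdata, ...) {
  xs <- unit_norm_rows(as.matrix(newdata))
  d <- dim(object$models)
  out <- array(NA_real_, c(d[1], nrow(xs), d[2]))
  for (t in seq_len(d[1]))
    for (cc in seq_len(d[2]))
      out[t, , cc] <- predict(object$models[[t, cc]], xs)
  out
}

#' Feature stability report across cross-validation folds
#'
#' Tabulates, for each feature, how often it was selected across folds and
#' its mean unfolded row-norm weight, then returns the top `k` rows ordered
#' by (frequency desc, mean weight desc, index asc). Features never selected
#' sort last, so they only appear when `k` exceeds the number of
#' ever-selected features.
#'
#' @param report an `smtl_cv_report` (from [smtl_cv()] or
#'   [lasso_baseline()]), or a list of `smtl_selection` objects.
#' @param feature_names optional character vector of feature names.
#' @param k number of rows to report (default 30).
#' @return data.frame with columns `feature_name`, `frequency`,
#'   `mean_weight`, `rank`.
#' @export
region_frequency_report <- function(report, feature_names = NULL, k = 30) {
  sels <- if (inherits(report, "smtl_cv_report")) {
    lapply(report$per_fold, `[[`, "selection")
  } else report
  if (length(sels) == 0) stop("no per-fold selections present")
  F_ <- length(sels[[1]]$row_norms)
  if (k > F_) stop("'k' exceeds the number of features")
  freq <- numeric(F_)
  wsum <- numeric(F_)
  for (s in sels) {
    freq[s$selected] <- freq[s$selected] + 1
    wsum <- wsum + s$row_norms
  }
  freq <- freq / length(sels)
  meanw <- wsum / length(sels)
  if (is.null(feature_names))
    feature_names <- sprintf("feature_%03d", seq_len(F_))
  ord <- order(-freq, -meanw, seq_len(F_))[seq_len(k)]
  data.frame(feature_name = feature_names[ord],
             frequency = freq[ord],
             mean_weight = meanw[ord],
             rank = seq_len(k),
             stringsAsFactors = FALSE)
}

#' Write a region stability report as TSV
#'
#' @param tab data.frame from [region_frequency_report()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_region_report <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
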