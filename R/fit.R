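#' Optimizer settings for [smtl_fit()]
#'
#' @param max_iter maximum number of outer iterations (default 50).
#' @param tol stopping threshold (default `1e-6`): iteration stops when the
#'   Frobenius norm of the change of the unfolded weight matrix or the
#'   relative objective decrease drops below it, whichever happens first.
#' @param epsilon_l21 smoothing floor for the l2,1 reweighting (default
#'   `1e-8`).
#' @param sigma heat-kernel bandwidth passed to the similarity graphs;
#'   `NULL` (default) uses the plain `exp(-d^2)` kernel.
#' @param ridge nonnegative diagonal loading added to the Sylvester `A`
#'   matrix; 0 by default, raise it if the solver reports a singular system.
#' @param init_ridge ridge used in the least-squares initialization of the
#'   weights, `W0 = (X'X + init_ridge I)^{-1} X'Y` (default `1e-3`), which
#'   keeps the start well-defined when F > S.
#' @param verbose print the objective value each iteration.
#' @return a list of class `smtl_control`.
#' @export
smtl_control <- function(max_iter = 50L, tol = 1e-6, epsilon_l21 = 1e-8,
                         sigma = NULL, ridge = 0, init_ridge = 1e-3,
                         verbose = FALSE) {
  stopifnot(max_iter >= 1, tol > 0, epsilon_l21 > 0, ridge >= 0,
            init_ridge >= 0)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 epsilon_l21 = epsilon_l21, sigma = sigma, ridge = ridge,
                 init_ridge = init_ridge, verbose = isTRUE(verbose)),
            class = "smtl_control")
}

#' Build the three relational graph Laplacians from data
#'
#' `L_f` (feature graph) and `L_s` (subject graph) are built once from the
#' feature matrix; `L_c[[t]]` is built from the score matrix of each time
#' point. In cross-validation these must be computed from training rows only.
#'
#' @param X numeric S x F feature matrix (typically z-normalized).
#' @param Y list of T score matrices or T x S x C array.
#' @param sigma optional heat-kernel bandwidth.
#' @return list with elements `L_f`, `L_s`, `L_c` (list of length T).
#' @export
smtl_graphs <- function(X, Y, sigma = NULL) {
  X <- as.matrix(X)
  Y <- as_score_list(Y)
  L_f <- if (ncol(X) >= 2) graph_laplacian(feature_similarity(X, sigma))
         else matrix(0, 1, 1)
  L_s <- graph_laplacian(subject_similarity(X, sigma))
  L_c <- lapply(Y, function(Yt) graph_laplacian(score_similarity(Yt, sigma)))
  list(L_f = L_f, L_s = L_s, L_c = L_c)
}

#' Fit the multi-relational temporally constrained multi-task model
#'
#' Minimizes
#' `sum_t ||Y^(t) - X W^(t)||_F^2 + lambda1 sum_t (Tr(W'L_f W) +
#' Tr((XW)'L_s XW) + Tr(W L_c^(t) W')) + lambda2 ||W_hat||_{2,1}`
#' over the per-time weight matrices `W^(t)` (F x C), where
#' `W_hat = [W^(1), ..., W^(T)]` is the row-wise unfolding whose l2,1 norm
#' couples feature selection across all time points and score types.
#'
#' Each outer iteration rebuilds the diagonal l2,1 reweighting matrix from
#' the current unfolded weights and then solves one Sylvester equation
#' `A W^(t) + W^(t) B^(t) = X'Y^(t)` per time point, with
#' `A = X'X + lambda1 L_f + lambda1 X'L_s X + lambda2 L_D (+ ridge I)` and
#' `B^(t) = lambda1 L_c^(t)`. Iteration stops when the unfolded weights move
#' less than `tol` in Frobenius norm or after `max_iter` iterations. The
#' objective trace is non-increasing (majorize-minimize on the l2,1 term).
#'
#' @param x numeric S x F feature matrix (z-normalize beforehand; see
#'   [z_normalize()]).
#' @param y list of T score matrices (S x C) or a T x S x C array.
#' @param lambda1 nonnegative weight of the three relational regularizers.
#' @param lambda2 nonnegative weight of the l2,1 row-sparsity penalty.
#' @param control a [smtl_control()] list.
#' @param graphs optional precomputed [smtl_graphs()] result (reused across
#'   fits on the same training data).
#' @return an object of class `smtl_fit`: list with `weights` (element
#'   `per_time`, list of T F x C matrices, and `unfolded`, F x (C*T)),
#'   `objective_trace`, `n_iter`, `converged`, `row_norms`, `lambda1`,
#'   `lambda2`, `control` and dimension metadata.
#' @export
smtl_fit <- function(x, y, lambda1 = 1, lambda2 = 1,
                     control = smtl_control(), graphs = NULL) {
  x <- as.matrix(x)
  y <- as_score_list(y)
  S <- nrow(x); F_ <- ncol(x); Tn <- length(y); C <- ncol(y[[1]])
  if (S < 2) stop("need at least 2 subjects")
  if (F_ < 1 || Tn < 1) stop("need at least one feature and one time point")
  if (any(!is.finite(x))) stop("'x' contains missing or non-finite values")
  for (t in seq_len(Tn)) {
    if (!all(dim(y[[t]]) == c(S, C)))
      stop("score matrix at time point ", t, " must be ", S, " x ", C)
    if (any(!is.finite(y[[t]])))
      stop("scores at time point ", t, " contain missing or non-finite values")
  }
  if (lambda1 < 0 || lambda2 < 0) stop("lambda1 and lambda2 must be >= 0")

  if (is.null(graphs)) graphs <- smtl_graphs(x, y, control$sigma)

  XtX <- crossprod(x)
  XtLsX <- crossprod(x, graphs$L_s %*% x)
  XtY <- lapply(y, function(Yt) crossprod(x, Yt))
  baseA <- XtX + lambda1 * graphs$L_f + lambda1 * XtLsX
  if (control$ridge > 0) baseA <- baseA + control$ridge * diag(F_)
  # B^(t) is tiny (C x C); eigendecompose once per time point
  eb <- lapply(graphs$L_c, function(L) {
    B <- lambda1 * L
    eigen((B + t(B)) / 2, symmetric = TRUE)
  })

  init <- XtX + control$init_ridge * diag(F_)
  W <- lapply(XtY, function(q) solve(init, q))
  what <- unfold_weights(W)
  obj_trace <- smtl_objective(x, y, W, lambda1, lambda2, graphs)
  converged <- FALSE
  n_iter <- 0L

  for (r in seq_len(control$max_iter)) {
    # the l2,1 reweighting diagonal is refreshed from the current unfolded
    # weights before every time-point solve (Gauss-Seidel over t), which
    # keeps each solve an exact minimizer of the current majorizing
    # surrogate and speeds up the tail of the iteration considerably
    for (t in seq_len(Tn)) {
      rn <- sqrt(rowSums(unfold_weights(W)^2))
      A <- baseA
      if (lambda2 > 0)
        diag(A) <- diag(A) + lambda2 / (2 * pmax(rn, control$epsilon_l21))
      ea <- eigen((A + t(A)) / 2, symmetric = TRUE)
      spread <- max(abs(ea$values), 1)
      denom <- outer(ea$values, eb[[t]]$values, "+")
      if (min(abs(denom)) < 1e-12 * spread)
        stop("singular Sylvester system at iteration ", r, ", time point ", t,
             "; increase smtl_control(ridge = ...)")
      W[[t]] <- ea$vectors %*%
        ((crossprod(ea$vectors, XtY[[t]]) %*% eb[[t]]$vectors) / denom) %*%
        t(eb[[t]]$vectors)
    }
    what_new <- unfold_weights(W)
    if (any(!is.finite(what_new)))
      stop("non-finite weights at iteration ", r)
    obj <- smtl_objective(x, y, W, lambda1, lambda2, graphs)
    obj_prev <- obj_trace[length(obj_trace)]
    obj_trace <- c(obj_trace, obj)
    delta <- frobenius(what_new - what)
    rel_obj <- abs(obj_prev - obj) / max(abs(obj_prev), 1)
    if (control$verbose)
      message(sprintf("iter %3d  objective %.8g  dW %.3g  dJ/J %.3g",
                      r, obj, delta, rel_obj))
    what <- what_new
    n_iter <- r
    # stop on whichever fires first: the printed weight-change cap or the
    # relative objective plateau ("until the objective function converged")
    if (delta < control$tol || rel_obj < control$tol) {
      converged <- TRUE
      break
    }
  }

  W <- lapply(W, function(w) {
    rownames(w) <- colnames(x)
    w
  })
  rownames(what) <- colnames(x)
  structure(list(
    weights = list(per_time = W, unfolded = what),
    objective_trace = obj_trace,
    n_iter = n_iter,
    converged = converged,
    row_norms = sqrt(rowSums(what^2)),
    lambda1 = lambda1, lambda2 = lambda2,
    control = control,
    dims = list(S = S, F = F_, C = C, T = Tn),
    feature_names = colnames(x)
  ), class = "smtl_fit")
}

#' @export
print.smtl_fit <- function(x, ...) {
  d <- x$dims
  cat(sprintf(
    "smtl_fit: S=%d F=%d C=%d T=%d  lambda1=%g lambda2=%g\n", d$S, d$F, d$C,
    d$T, x$lambda1, x$lambda2))
  cat(sprintf("  %d iterations, converged=%s, final objective %.6g\n",
              x$n_iter, x$converged, tail(x$objective_trace, 1)))
  nz <- sum(x$row_norms > 1e-3 * max(x$row_norms))
  cat(sprintf("  active rows (rel. threshold 1e-3): %d / %d\n", nz, d$F))
  invisible(x)
}

#' @importFrom utils tail
NULL
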