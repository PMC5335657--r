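# Heat-kernel similarity graphs over features, subjects and scores, and their
# unnormalized graph Laplacians. Similarity between two vectors a, b is
# exp(-||a - b||^2); an optional bandwidth sigma replaces the exponent by
# -||a - b||^2 / (2 sigma^2).

# Pairwise heat-kernel similarity between the *columns* of M.
heat_kernel <- function(M, sigma = NULL) {
  M <- as.matrix(M)
  g <- crossprod(M)
  n2 <- diag(g)
  d2 <- outer(n2, n2, "+") - 2 * g
  d2[d2 < 0] <- 0
  if (!is.null(sigma)) {
    if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
      stop("'sigma' must be a positive scalar")
    d2 <- d2 / (2 * sigma^2)
  }
  s <- exp(-d2)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  s
}

#' Feature-feature heat-kernel similarity graph
#'
#' Entry (u, v) is `exp(-||x[, u] - x[, v]||^2)`: similar feature columns get
#' similarity close to 1, distant ones decay towards 0. The diagonal is
#' exactly 1.
#'
#' @param x numeric matrix, subjects in rows, features in columns (F >= 2).
#' @param sigma optional positive kernel bandwidth; when given, squared
#'   distances are divided by `2 * sigma^2`. The default (`NULL`) uses the
#'   plain `exp(-d^2)` kernel.
#' @return symmetric F x F similarity matrix with unit diagonal.
#' @export
feature_similarity <- function(x, sigma = NULL) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 features")
  heat_kernel(x, sigma)
}

#' Subject-subject heat-kernel similarity graph
#'
#' Entry (m, n) is `exp(-||x[m, ] - x[n, ]||^2)` over subject rows.
#'
#' @inheritParams feature_similarity
#' @return symmetric S x S similarity matrix with unit diagonal.
#' @export
subject_similarity <- function(x, sigma = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 subjects")
  heat_kernel(t(x), sigma)
}

#' Score-score heat-kernel similarity graph at one time point
#'
#' Entry (p, q) is `exp(-||y[, p] - y[, q]||^2)` over score columns of the
#' S x C score matrix for a single time point. With a single score type the
#' 1 x 1 matrix `[1]` is returned.
#'
#' @param scores_at_t numeric S x C matrix of scores at one time point.
#' @inheritParams feature_similarity
#' @return symmetric C x C similarity matrix with unit diagonal.
#' @export
score_similarity <- function(scores_at_t, sigma = NULL) {
  y <- as.matrix(scores_at_t)
  if (ncol(y) < 1) stop("need at least 1 score column")
  if (ncol(y) == 1) return(matrix(1, 1, 1))
  heat_kernel(y, sigma)
}

#' Unnormalized graph Laplacian of a similarity graph
#'
#' `L = D - S` where `S` is the similarity matrix and `D` the diagonal matrix
#' of its row sums. Self-similarities on the diagonal of `S` cancel, so
#' keeping them (value 1) is equivalent to removing self-loops. The result is
#' symmetric positive semidefinite with zero row sums and non-positive
#' off-diagonal entries.
#'
#' @param graph symmetric similarity matrix with strictly positive entries.
#' @return the Laplacian matrix.
#' @export
graph_laplacian <- function(graph) {
  s <- as.matrix(graph)
  if (nrow(s) != ncol(s)) stop("similarity matrix must be square")
  asym <- max(abs(s - t(s)))
  if (asym > 1e-8 * max(1, max(abs(s))))
    stop("similarity matrix must be symmetric")
  s <- (s + t(s)) / 2
  diag(rowSums(s), nrow(s)) - s
}

#' Diagonal l2,1 reweighting matrix
#'
#' For the unfolded weight matrix `W_hat` (features x (scores * times)), the
#' diagonal entry i is `1 / (2 * max(||w_hat[i, ]||_2, epsilon))`. The induced
#' quadratic penalty `Tr(W_hat' D W_hat)` majorizes the l2,1 norm up to a
#' constant, which is what makes the alternating Sylvester solves descend on
#' the sparse objective. `epsilon` guards the division for (near-)zero rows.
#'
#' @param unfolded_weights numeric F x (C*T) matrix.
#' @param epsilon positive smoothing floor for row norms (default `1e-8`).
#' @return F x F diagonal matrix.
#' @export
l21_reweight_diag <- function(unfolded_weights, epsilon = 1e-8) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0)
    stop("'epsilon' must be a positive scalar")
  w <- as.matrix(unfolded_weights)
  rn <- sqrt(rowSums(w^2))
  d <- 1 / (2 * pmax(rn, epsilon))
  diag(d, nrow(w))
}
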