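#' Solve a symmetric Sylvester equation A W + W B = Q
#'
#' Both `A` (F x F) and `B` (C x C) must be symmetric, which holds for every
#' system the optimizer assembles (`A` is a sum of Gram and Laplacian
#' matrices plus the diagonal l2,1 reweighting; `B` is a scaled score-graph
#' Laplacian). The solver eigendecomposes both sides and divides the rotated
#' right-hand side by the eigenvalue sums, so its cost is one F x F and one
#' C x C eigendecomposition. Solvability requires that no eigenvalue of `A`
#' equals the negative of an eigenvalue of `B`.
#'
#' @param A symmetric F x F matrix.
#' @param B symmetric C x C matrix.
#' @param Q F x C right-hand side.
#' @return the F x C solution matrix `W`.
#' @export
solve_sylvester <- function(A, B, Q) {
  A <- as.matrix(A); B <- as.matrix(B); Q <- as.matrix(Q)
  if (nrow(A) != ncol(A) || nrow(B) != ncol(B))
    stop("'A' and 'B' must be square")
  if (nrow(Q) != nrow(A) || ncol(Q) != nrow(B))
    stop("'Q' must be ", nrow(A), " x ", nrow(B))
  if (max(abs(A - t(A))) > 1e-8 * max(1, max(abs(A))))
    stop("'A' must be symmetric")
  if (max(abs(B - t(B))) > 1e-8 * max(1, max(abs(B))))
    stop("'B' must be symmetric")
  ea <- eigen((A + t(A)) / 2, symmetric = TRUE)
  eb <- eigen((B + t(B)) / 2, symmetric = TRUE)
  denom <- outer(ea$values, eb$values, "+")
  spread <- max(abs(ea$values), abs(eb$values), 1)
  if (min(abs(denom)) < 1e-12 * spread)
    stop("singular Sylvester system: A and -B share an eigenvalue; ",
         "add a small ridge to A (see smtl_control(ridge = ...))")
  W <- ea$vectors %*% ((crossprod(ea$vectors, Q) %*% eb$vectors) / denom) %*%
    t(eb$vectors)
  res <- frobenius(A %*% W + W %*% B - Q) / max(frobenius(Q), 1)
  if (!is.finite(res) || res > 1e-8)
    stop("Sylvester solve did not reach the required residual (",
         format(res), "); the system is ill-conditioned - increase the ridge")
  W
}
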