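# The three relational regularizers and the full objective. Each regularizer
# is defined by its trace form; the explicit pairwise double sum (both (u,v)
# and (v,u)) equals exactly twice the trace under L = degree - similarity,
# and the shared multiplier lambda1 absorbs that constant.

#' Feature-feature smoothness regularizer
#'
#' `Tr(W' L_f W)`: penalizes weight rows that differ across features the
#' heat-kernel graph deems similar.
#'
#' @param W_t numeric F x C weight matrix for one time point.
#' @param L_f F x F feature-graph Laplacian.
#' @return scalar penalty value.
#' @export
regularizer_feature <- function(W_t, L_f) {
  W_t <- as.matrix(W_t)
  if (nrow(L_f) != nrow(W_t)) stop("L_f dimension does not match rows of W_t")
  sum(W_t * (L_f %*% W_t))
}

#' Subject-subject smoothness regularizer
#'
#' `Tr((X W)' L_s (X W))`: similar subjects should receive similar predicted
#' scores.
#'
#' @param W_t numeric F x C weight matrix.
#' @param X numeric S x F feature matrix.
#' @param L_s S x S subject-graph Laplacian.
#' @return scalar penalty value.
#' @export
regularizer_subject <- function(W_t, X, L_s) {
  W_t <- as.matrix(W_t); X <- as.matrix(X)
  if (ncol(X) != nrow(W_t)) stop("X and W_t do not conform")
  if (nrow(L_s) != nrow(X)) stop("L_s dimension does not match rows of X")
  P <- X %*% W_t
  sum(P * (L_s %*% P))
}

#' Score-score smoothness regularizer
#'
#' `Tr(W L_c W')`: correlated score types should have correlated weight
#' columns. Zero when C = 1.
#'
#' @param W_t numeric F x C weight matrix.
#' @param L_c_t C x C score-graph Laplacian for this time point.
#' @return scalar penalty value.
#' @export
regularizer_score <- function(W_t, L_c_t) {
  W_t <- as.matrix(W_t)
  if (ncol(W_t) != nrow(L_c_t)) stop("L_c_t dimension does not match columns of W_t")
  sum((W_t %*% L_c_t) * W_t)
}

l21_norm <- function(w) sum(sqrt(rowSums(as.matrix(w)^2)))

unfold_weights <- function(W_list) do.call(cbind, W_list)

#' Full multi-task objective value
#'
#' `sum_t ||Y^(t) - X W^(t)||_F^2 + lambda1 * sum_t (R_f + R_s + R_c) +
#' lambda2 * ||W_hat||_{2,1}` where `W_hat = [W^(1), ..., W^(T)]`.
#'
#' @param X numeric S x F feature matrix.
#' @param Y list of T score matrices (S x C) or a T x S x C array.
#' @param W list of T weight matrices (F x C).
#' @param lambda1,lambda2 nonnegative regularization weights.
#' @param graphs list with `L_f`, `L_s` and `L_c` (list of T Laplacians), as
#'   produced by [smtl_graphs()].
#' @return scalar objective value.
#' @export
smtl_objective <- function(X, Y, W, lambda1, lambda2, graphs) {
  X <- as.matrix(X)
  Y <- as_score_list(Y)
  if (length(Y) != length(W)) stop("Y and W must have the same number of time points")
  loss <- 0
  reg <- 0
  for (t in seq_along(Y)) {
    if (!all(dim(Y[[t]]) == c(nrow(X), ncol(W[[t]]))))
      stop("dimension mismatch at time point ", t)
    loss <- loss + sum((Y[[t]] - X %*% W[[t]])^2)
    if (lambda1 > 0)
      reg <- reg +
        regularizer_feature(W[[t]], graphs$L_f) +
        regularizer_subject(W[[t]], X, graphs$L_s) +
        regularizer_score(W[[t]], graphs$L_c[[t]])
  }
  loss + lambda1 * reg + lambda2 * l21_norm(unfold_weights(W))
}

# Accept a T x S x C array or a list of S x C matrices and return the list.
as_score_list <- function(Y) {
  if (is.list(Y)) return(lapply(Y, as.matrix))
  if (is.array(Y) && length(dim(Y)) == 3) {
    dn <- dimnames(Y)
    out <- lapply(seq_len(dim(Y)[1]), function(t) {
      m <- Y[t, , , drop = FALSE]
      dim(m) <- dim(Y)[2:3]
      dimnames(m) <- dn[2:3]
      m
    })
    names(out) <- dn[[1]]
    return(out)
  }
  if (is.matrix(Y)) return(list(as.matrix(Y)))
  stop("'Y' must be a list of S x C matrices or a T x S x C array")
}

# Inverse of as_score_list: stack a list of S x C matrices into T x S x C.
as_score_array <- function(Y_list, time_labels = NULL, subject_ids = NULL,
                           score_names = NULL) {
  Tn <- length(Y_list)
  d <- dim(Y_list[[1]])
  arr <- array(NA_real_, c(Tn, d[1], d[2]),
               dimnames = list(time_labels, subject_ids, score_names))
  for (t in seq_len(Tn)) arr[t, , ] <- Y_list[[t]]
  arr
}
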