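#' Column-wise z-normalization with training-row statistics
#'
#' Centers and scales each column of a feature matrix using the mean and
#' sample standard deviation (divisor `n - 1`) computed on a reference subset
#' of rows. The statistics are attached to the result so held-out rows can be
#' transformed with training statistics only, which keeps cross-validation
#' leakage-safe.
#'
#' @param x numeric matrix, subjects in rows, features in columns.
#' @param reference_rows indices of the rows whose statistics define the
#'   transform. Defaults to all rows.
#' @param stats optional list with elements `center` and `scale` (as attached
#'   to a previous result); when supplied, `reference_rows` is ignored and the
#'   stored statistics are applied as-is.
#' @return the transformed matrix with attributes `center` and `scale`.
#' @examples
#' z <- z_normalize(matrix(c(1, 2, 3, 10, 20, 30), ncol = 2))
#' attr(z, "center")
#' @export
z_normalize <- function(x, reference_rows = NULL, stats = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be numeric")
  if (is.null(stats)) {
    rows <- reference_rows %||% seq_len(nrow(x))
    if (length(rows) == 0) stop("'reference_rows' must be non-empty")
    ref <- x[rows, , drop = FALSE]
    center <- colMeans(ref)
    scale <- apply(ref, 2, sd)
    bad <- which(!is.finite(scale) | scale == 0)
    if (length(bad)) {
      nm <- colnames(x)[bad] %||% as.character(bad)
      if (is.null(colnames(x))) nm <- as.character(bad)
      stop("zero-variance column(s) in reference rows: ",
           paste(nm, collapse = ", "))
    }
  } else {
    center <- stats$center
    scale <- stats$scale
    if (length(center) != ncol(x) || length(scale) != ncol(x))
      stop("stored statistics do not match the number of columns")
  }
  out <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Extract normalization statistics from a z-normalized matrix
#'
#' @param x a matrix returned by [z_normalize()].
#' @return list with `center` and `scale`.
#' @export
norm_stats <- function(x) {
  list(center = attr(x, "center"), scale = attr(x, "scale"))
}

# Scale each row of x to unit Euclidean norm (zero rows are left untouched);
# applied per subject before SVR training/prediction.
unit_norm_rows <- function(x) {
  x <- as.matrix(x)
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  x / nrm
}
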