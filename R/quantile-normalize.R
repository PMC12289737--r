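#' Quantile normalization
#'
#' Forces every sample column of a feature x sample matrix to share one
#' empirical distribution: the reference distribution is the across-column
#' mean of the column-wise sorted values, and each value is replaced by the
#' reference value at its within-column rank. Tied values receive the mean
#' of the reference values spanned by their tied ranks, so the operation is
#' idempotent.
#'
#' No baseline transformation is applied.
#'
#' @param x numeric matrix (features in rows, samples in columns) with at
#'   least two columns and no missing values. Censored/ceiling values are
#'   ordinary numbers here and participate in the normalization.
#'
#' @return A matrix of the same shape and dimnames whose columns all have
#'   the same multiset of values (up to tie averaging).
#' @export
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(2, 4, 6)))
#' # both columns become 1.5, 3, 4.5
quantile_normalize <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("'x' must be a numeric matrix")
  if (ncol(x) < 2L)
    stop("quantile normalization needs at least two sample columns")
  if (anyNA(x) || any(!is.finite(x)))
    stop("'x' must not contain missing or non-finite values")
  ref <- rowMeans(apply(x, 2L, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    assigned <- numeric(length(v))
    assigned[order(v)] <- ref
    # equal input values share the mean of their assigned reference values
    out[, j] <- ave(assigned, v, FUN = mean)
  }
  out
}
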