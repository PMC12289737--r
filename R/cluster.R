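#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering with Euclidean distance and complete (maximum)
#' linkage, as used for expression heat-map dendrograms. Clustering
#' `axis = "features"` groups the rows; `axis = "samples"` groups the
#' columns. Complete linkage guarantees monotone (non-decreasing) merge
#' heights; duplicate rows (zero distances) are permitted.
#'
#' @param x numeric matrix, features in rows and samples in columns.
#' @param axis cluster the `"features"` (rows, default) or `"samples"`
#'   (columns).
#'
#' @return A [stats::hclust] object (`merge`, `height`, `order`,
#'   `labels`), directly usable with `plot()` / `as.dendrogram()`.
#' @export
#' @examples
#' m <- rbind(a = c(0, 0), b = c(1, 0), c = c(10, 0))
#' hierarchical_cluster(m)$height  # merges at 1, then 10
hierarchical_cluster <- function(x, axis = c("features", "samples")) {
  axis <- match.arg(axis)
  if (!is.matrix(x) || !is.numeric(x))
    stop("'x' must be a numeric matrix")
  if (any(!is.finite(x))) stop("values must be finite")
  m <- if (axis == "samples") t(x) else x
  if (nrow(m) < 2L) stop("need at least two items to cluster")
  hclust(dist(m, method = "euclidean"), method = "complete")
}
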