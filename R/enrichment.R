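#' Hypergeometric over-representation of one gene set
#'
#' Tests whether a query gene list overlaps a gene set more than expected
#' by chance, given a background universe of N genes: the upper-tail
#' probability of drawing at least k set members when n genes are sampled
#' without replacement from a background containing K set members. Query
#' and set are intersected with the background before counting.
#'
#' The odds ratio is the cross-product ratio of the 2x2 overlap table
#' k (N - K - n + k) / ((K - k)(n - k)); when any cell is zero, 0.5 is
#' added to every cell (Haldane-Anscombe correction).
#'
#' @param query character vector of query gene ids.
#' @param gene_set character vector of set member ids.
#' @param background character vector: the gene universe (e.g. all
#'   expressed genes from [build_background()]). Must be non-empty.
#' @param set_name optional label carried into the result.
#'
#' @return A one-row data.frame of class `enrichment_result` with columns
#'   set_name, k, K, n, N, p, odds_ratio and overlap (comma-separated
#'   overlapping ids).
#' @export
#' @examples
#' bg <- paste0("g", 1:10)
#' hypergeom_overrep(paste0("g", 1:4), paste0("g", c(1:3, 9, 10)), bg)
hypergeom_overrep <- function(query, gene_set, background,
                              set_name = "set") {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background universe")
  q <- intersect(unique(query), background)
  s <- intersect(unique(gene_set), background)
  hit <- intersect(q, s)
  k <- length(hit); K <- length(s); n <- length(q); N <- length(background)
  # P(X >= k) for X ~ Hypergeometric(K successes, N - K failures, n draws)
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  a <- k; b <- n - k; cc <- K - k; d <- N - K - n + k
  if (min(a, b, cc, d) == 0L) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * cc)
  structure(data.frame(set_name = set_name, k = k, K = K, n = n, N = N,
                       p = p, odds_ratio = or,
                       overlap = paste(sort(hit), collapse = ","),
                       stringsAsFactors = FALSE),
            class = c("enrichment_result", "data.frame"))
}

#' Over-representation across a gene-set collection
#'
#' Applies [hypergeom_overrep()] to every set in a collection, adjusts
#' p-values by Benjamini-Hochberg within the collection, and sorts by p.
#' Sets that are empty after intersection with the background are skipped
#' with a warning.
#'
#' @param query character vector of query gene ids.
#' @param collection named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param background gene universe.
#' @param alpha significance cutoff on the adjusted p (default 0.05).
#'
#' @return A data.frame of class `enrichment_result`, one row per tested
#'   set, with additional columns adj_p and significant, ordered by p.
#' @export
enrich_collection <- function(query, collection, background, alpha = 0.05) {
  if (is.null(names(collection)) || anyDuplicated(names(collection)))
    stop("'collection' must be a uniquely named list of gene sets")
  background <- unique(background)
  keep <- vapply(collection,
                 function(s) length(intersect(s, background)) > 0L,
                 logical(1))
  if (any(!keep))
    warning(sum(!keep), " set(s) empty after background intersection, skipped: ",
            paste(names(collection)[!keep], collapse = ", "))
  collection <- collection[keep]
  if (length(collection) == 0L) stop("no testable sets in the collection")
  rows <- lapply(names(collection), function(nm)
    hypergeom_overrep(query, collection[[nm]], background, set_name = nm))
  res <- do.call(rbind, rows)
  res$adj_p <- p.adjust(res$p, method = "BH")
  res$significant <- res$adj_p < alpha
  res <- res[order(res$p, res$set_name), ]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Union of predicted targets over a set of miRNAs
#'
#' Builds the comprehensive list of all predicted target genes of a group
#' of miRNAs (e.g. all upregulated DEmiRNAs). miRNAs missing from the
#' target map are skipped with a warning.
#'
#' @param mirnas character vector of miRNA ids.
#' @param target_map named list mapping miRNA id to a character vector of
#'   target gene ids.
#'
#' @return Sorted character vector: the union of the target sets.
#' @export
demirna_target_union <- function(mirnas, target_map) {
  missing <- setdiff(mirnas, names(target_map))
  if (length(missing) > 0L)
    warning(length(missing), " miRNA(s) absent from the target map, skipped: ",
            paste(missing, collapse = ", "))
  present <- intersect(mirnas, names(target_map))
  sort(unique(unlist(target_map[present], use.names = FALSE)))
}
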