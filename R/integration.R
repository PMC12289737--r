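#' Directed regulatory knowledge graph
#'
#' A typed directed graph over miRNAs, genes and intermediate regulator
#' nodes, built from a three-column edge list. Duplicate edges (same
#' source, target and interaction) are collapsed with a warning.
#'
#' @param edges data.frame with columns `source`, `interaction`, `target`.
#' @param node_types named character vector mapping node id to one of
#'   `"mirna"`, `"gene"`, `"regulator"`. Nodes appearing in edges but not
#'   listed here default to `"regulator"`.
#' @param directions optional named character vector (`"up"`/`"down"`)
#'   with expression direction labels for a subset of nodes.
#'
#' @return An object of class `knowledge_graph` with elements `edges`,
#'   `node_types`, `directions`, and adjacency lists `out` (successors)
#'   and `incoming` (predecessors).
#' @export
knowledge_graph <- function(edges, node_types = NULL, directions = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("source", "interaction", "target") %in% names(edges)))
  edges <- edges[, c("source", "interaction", "target")]
  edges[] <- lapply(edges, as.character)
  key <- paste(edges$source, edges$target, edges$interaction, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate edge(s) removed")
    edges <- edges[!duplicated(key), ]
  }
  edges <- edges[order(edges$source, edges$target), ]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$source, edges$target)))
  nt <- setNames(rep("regulator", length(nodes)), nodes)
  if (!is.null(node_types)) {
    bad <- setdiff(names(node_types), nodes)
    nt[intersect(names(node_types), nodes)] <-
      node_types[intersect(names(node_types), nodes)]
    if (!all(nt %in% c("mirna", "gene", "regulator")))
      stop("node types must be 'mirna', 'gene' or 'regulator'")
  }
  out <- split(edges$target, factor(edges$source, levels = nodes))
  incoming <- split(edges$source, factor(edges$target, levels = nodes))
  structure(list(edges = edges, node_types = nt,
                 directions = directions, nodes = nodes,
                 out = out, incoming = incoming),
            class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  tab <- table(factor(x$node_types, c("mirna", "gene", "regulator")))
  cat("Knowledge graph:", length(x$nodes), "nodes (",
      tab["mirna"], "miRNA,", tab["gene"], "gene,",
      tab["regulator"], "regulator ),", nrow(x$edges), "directed edges\n")
  invisible(x)
}

#' Inverse-correlation overlap of miRNA targets with DEGs
#'
#' Under the canonical repression model an upregulated miRNA should push
#' its targets down, so the interesting overlaps are (a) targets of
#' upregulated miRNAs with downregulated genes and (b) targets of
#' downregulated miRNAs with upregulated genes. Each overlap is tested by
#' the hypergeometric test against the expressed-gene background.
#'
#' @param degs_up,degs_down character vectors of up-/downregulated gene ids.
#' @param demirnas_up,demirnas_down character vectors of up-/downregulated
#'   miRNA ids.
#' @param target_map named list, miRNA id to target gene ids.
#' @param background expressed-gene universe for the test.
#'
#' @return A list with `up_mirna_down_deg` and `down_mirna_up_deg`, each a
#'   list holding the [hypergeom_overrep()] `result` and the overlapping
#'   `genes`.
#' @export
inverse_overlap <- function(degs_up, degs_down, demirnas_up, demirnas_down,
                            target_map, background) {
  if (length(intersect(degs_up, degs_down)) > 0L ||
      length(intersect(demirnas_up, demirnas_down)) > 0L)
    stop("up and down sets must be disjoint")
  one <- function(mirnas, degs, label) {
    targets <- suppressWarnings(demirna_target_union(mirnas, target_map))
    res <- hypergeom_overrep(targets, degs, background, set_name = label)
    list(result = res,
         genes = sort(intersect(intersect(targets, degs), background)))
  }
  list(up_mirna_down_deg = one(demirnas_up, degs_down, "targets(up-miR) & down-DEGs"),
       down_mirna_up_deg = one(demirnas_down, degs_up, "targets(down-miR) & up-DEGs"))
}

#' Find miRNA-gene relations by direct edges or one-intermediate paths
#'
#' For every (miRNA, gene) query pair, searches the directed graph from
#' the miRNA. In mode `"shortest"` only a direct edge miRNA -> gene counts
#' (path length 1). In mode `"shortest_plus_one"` the pair's shortest
#' directed path is accepted if its length is at most 2, i.e. a direct
#' edge, or one intervening node w with miRNA -> w -> g. Each unique
#' (miRNA, gene) pair yields at most one relation; when several
#' intermediates exist the lexicographically smallest is recorded. Edge
#' direction is respected throughout. Output rows are sorted by miRNA id
#' then gene id, so results do not depend on input order.
#'
#' @param graph a [knowledge_graph()].
#' @param demirnas named character vector: names are miRNA ids, values
#'   their direction (`"up"`/`"down"`).
#' @param degs named character vector: gene ids to direction.
#' @param mode `"shortest"` or `"shortest_plus_one"`.
#'
#' @return A data.frame with columns mirna, mirna_direction, gene,
#'   gene_direction, path_length (1 or 2) and intermediate (NA for direct
#'   edges). Query ids absent from the graph are skipped with a warning.
#' @export
find_relations <- function(graph, demirnas, degs,
                           mode = c("shortest", "shortest_plus_one")) {
  stopifnot(inherits(graph, "knowledge_graph"))
  mode <- match.arg(mode)
  if (is.null(names(demirnas)) || is.null(names(degs)))
    stop("'demirnas' and 'degs' must be named direction vectors")
  absent <- setdiff(c(names(demirnas), names(degs)), graph$nodes)
  if (length(absent) > 0L)
    warning(length(absent), " query id(s) absent from the graph, skipped")
  mirnas <- sort(intersect(names(demirnas), graph$nodes))
  genes <- sort(intersect(names(degs), graph$nodes))

  rows <- vector("list", length(mirnas))
  for (i in seq_along(mirnas)) {
    m <- mirnas[i]
    succ <- graph$out[[m]]
    found_g <- character(0); found_len <- integer(0); found_via <- character(0)
    for (g in genes) {
      if (g %in% succ) {
        found_g <- c(found_g, g); found_len <- c(found_len, 1L)
        found_via <- c(found_via, NA_character_)
      } else if (mode == "shortest_plus_one") {
        via <- intersect(succ, graph$incoming[[g]])
        via <- setdiff(via, c(m, g))
        if (length(via) > 0L) {
          found_g <- c(found_g, g); found_len <- c(found_len, 2L)
          found_via <- c(found_via, min(sort(via)))
        }
      }
    }
    if (length(found_g) > 0L)
      rows[[i]] <- data.frame(mirna = m,
                              mirna_direction = unname(demirnas[[m]]),
                              gene = found_g,
                              gene_direction = unname(degs[found_g]),
                              path_length = found_len,
                              intermediate = found_via,
                              stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(mirna = character(0), mirna_direction = character(0),
                      gene = character(0), gene_direction = character(0),
                      path_length = integer(0), intermediate = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Cross-tabulate relation directions
#'
#' Counts unique miRNA-gene relations by the direction pair (miRNA
#' up/down x gene up/down) and reports each cell's share of the total.
#'
#' @param relations data.frame from [find_relations()].
#'
#' @return An object of class `direction_table`: list with `observed`
#'   (2x2 integer matrix, rows = miRNA direction, cols = gene direction),
#'   `percent` and `total`.
#' @export
direction_table <- function(relations) {
  if (nrow(relations) == 0L) stop("empty relation list")
  O <- table(mirna = factor(relations$mirna_direction, c("up", "down")),
             gene = factor(relations$gene_direction, c("up", "down")))
  O <- unclass(O)
  structure(list(observed = O, percent = 100 * O / sum(O), total = sum(O)),
            class = "direction_table")
}

#' @export
print.direction_table <- function(x, ...) {
  cat("Relation direction table (", x$total, "unique relations )\n")
  m <- matrix(sprintf("%d (%.2f%%)", x$observed, x$percent), 2, 2,
              dimnames = list(mirna = c("up", "down"),
                              gene = c("up", "down")))
  print(m, quote = FALSE)
  invisible(x)
}

#' Chi-square test of a 2x2 contingency table
#'
#' Pearson chi-square with 1 df, with optional Yates continuity
#' correction: X^2 = sum((|O - E| - c)^2 / E) with c = min(0.5, |O - E|)
#' when the correction is on (the cap keeps the corrected statistic
#' non-negative) and c = 0 otherwise. Expected counts are the product of
#' the margins over the total. Warns when any expected count is below 5.
#'
#' @param table a [direction_table()] or a 2x2 numeric matrix of counts.
#' @param correct apply the continuity correction (default TRUE).
#'
#' @return An object of class `chisq_2x2`: list with `observed`,
#'   `expected`, `statistic`, `df` (always 1), `p` and `correct`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(1, 37, 53, 1), 2, 2))
chi_square_2x2 <- function(table, correct = TRUE) {
  O <- if (inherits(table, "direction_table")) table$observed else table
  if (!is.matrix(O) || !identical(dim(O), c(2L, 2L)))
    stop("'table' must be a 2x2 matrix of counts")
  if (any(O < 0)) stop("counts must be non-negative")
  total <- sum(O)
  if (total == 0) stop("empty table")
  rs <- rowSums(O); cs <- colSums(O)
  if (any(rs == 0) || any(cs == 0))
    stop("zero row or column margin: chi-square undefined")
  E <- outer(rs, cs) / total
  if (any(E < 5))
    warning("expected count below 5; chi-square approximation may be poor")
  cc <- if (correct) pmin(0.5, abs(O - E)) else 0
  stat <- sum((abs(O - E) - cc)^2 / E)
  structure(list(observed = O, expected = E, statistic = stat, df = 1L,
                 p = pchisq(stat, df = 1L, lower.tail = FALSE),
                 correct = correct),
            class = "chisq_2x2")
}

#' @export
print.chisq_2x2 <- function(x, ...) {
  cat(sprintf("2x2 chi-square%s: X^2 = %.4g, df = 1, p = %.4g\n",
              if (x$correct) " (Yates-corrected)" else "",
              x$statistic, x$p))
  invisible(x)
}
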