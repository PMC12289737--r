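# Independent oracles used across test files. Each one recomputes the
# quantity by the most literal route available (enumeration, brute force,
# closed form) and never calls the package code it checks.

# Upper-tail hypergeometric probability by direct summation of the pmf
# with binomial coefficients.
hyper_enum_oracle <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  i <- i[n - i <= N - K]
  if (length(i) == 0) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Hochberg step-up by literal definition:
# adj_(i) = min_{j >= i} min(1, m p_(j) / j) on the sorted p-values.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- rev(cummin(rev(pmin(1, m * ps / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# BH oracle with p.adjust's NA handling: NAs keep NA and do not count
# toward m.
bh_oracle_na <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- bh_oracle(p[ok])
  out
}

# Uncorrected 2x2 chi-square via the algebraic identity
# (ad - bc)^2 N / (r1 r2 c1 c2).
chisq_closed_form <- function(O) {
  (O[1, 1] * O[2, 2] - O[1, 2] * O[2, 1])^2 * sum(O) /
    prod(rowSums(O), colSums(O))
}

# Naive O(n^3) complete-linkage agglomeration: repeatedly merge the pair
# of clusters with the smallest maximum inter-point Euclidean distance.
# Returns the sorted merge heights.
complete_linkage_oracle <- function(m) {
  clusters <- lapply(seq_len(nrow(m)), identity)
  d <- as.matrix(dist(m))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# Exhaustive enumeration of miRNA -> gene paths of length <= 2 over an
# edge data.frame, the reference for find_relations().
path_enum_oracle <- function(edges, mirnas, genes, max_len) {
  out <- list()
  for (m in mirnas) for (g in genes) {
    direct <- any(edges$source == m & edges$target == g)
    if (direct) {
      out[[length(out) + 1L]] <- data.frame(mirna = m, gene = g,
                                            path_length = 1L)
    } else if (max_len >= 2L) {
      mids <- intersect(edges$target[edges$source == m],
                        edges$source[edges$target == g])
      mids <- setdiff(mids, c(m, g))
      if (length(mids) > 0L)
        out[[length(out) + 1L]] <- data.frame(mirna = m, gene = g,
                                              path_length = 2L)
    }
  }
  if (length(out) == 0L)
    return(data.frame(mirna = character(0), gene = character(0),
                      path_length = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$mirna, res$gene), ]
}

# Small deterministic Ct fixture: 6 samples (3 control, 3 case), values
# chosen by hand.
make_ct_fixture <- function(values, ceiling = 40) {
  ct_matrix(values, rep(c("control", "case"), each = 3), ceiling = ceiling)
}
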