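#' Ct matrix container
#'
#' Holds a miRNA x sample matrix of qPCR cycle-threshold (Ct) values
#' together with a two-level group factor and the ceiling value that
#' encodes "Undetermined" reactions (the polymerase never crossed the
#' detection threshold within the run). Lower Ct means higher abundance.
#'
#' @param values numeric matrix, features in rows and samples in columns.
#'   Row names are miRNA identifiers, column names are sample identifiers.
#' @param groups factor (or character) of length `ncol(values)` with
#'   exactly two levels; the first level (for characters, the
#'   first-appearing label) is treated as the control / reference
#'   condition everywhere downstream.
#' @param ceiling Ct value that stands for "Undetermined" (default 40).
#'
#' @return An object of class `ct_matrix`: a list with elements `values`,
#'   `groups` and `ceiling`.
#' @export
#' @examples
#' m <- matrix(c(20, 25, 21, 26, 22, 24), nrow = 1,
#'             dimnames = list("mir-001", paste0("s", 1:6)))
#' ct_matrix(m, rep(c("control", "case"), each = 3))
ct_matrix <- function(values, groups, ceiling = 40) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  # level order = order of first appearance, so the first-seen label is
  # the control condition regardless of alphabetical order
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  if (length(groups) != ncol(values))
    stop("'groups' must have one label per sample column")
  if (nlevels(groups) != 2L)
    stop("exactly two distinct group labels are required, got ",
         nlevels(groups))
  if (anyNA(values) || any(!is.finite(values)))
    stop("Ct values must be finite; encode Undetermined as the ceiling value")
  if (any(values <= 0) || any(values > ceiling))
    stop("determined Ct values must lie in (0, ceiling]")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("feature%04d", seq_len(nrow(values)))
  structure(list(values = values, groups = groups, ceiling = ceiling),
            class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat("Ct matrix:", nrow(x$values), "miRNAs x", ncol(x$values), "samples\n")
  cat("Groups:", paste(sprintf("%s (n=%d)", levels(x$groups),
                               table(x$groups)), collapse = " vs "), "\n")
  n_und <- sum(x$values == x$ceiling)
  cat("Undetermined (Ct =", x$ceiling, "):", n_und, "values\n")
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$values)

#' Microarray expression matrix container
#'
#' Holds a feature x sample matrix of log2 intensities, per-cell detection
#' flags and a two-level group factor. Flags use the single-letter tokens
#' `"P"` (present), `"M"` (marginal) and `"A"` (absent), following the
#' convention of array feature-extraction software.
#'
#' @param values numeric matrix of log2 intensities, features in rows.
#' @param groups factor of length `ncol(values)` with two levels; first
#'   level is the control condition.
#' @param flags character matrix of the same shape as `values` with
#'   entries in `c("P", "M", "A")`. Defaults to all-present.
#'
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, groups, flags = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (any(!is.finite(values)))
    stop("log2 intensities must be finite")
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  if (length(groups) != ncol(values))
    stop("'groups' must have one label per sample column")
  if (nlevels(groups) != 2L)
    stop("exactly two distinct group labels are required")
  if (is.null(flags)) {
    flags <- matrix("P", nrow(values), ncol(values),
                    dimnames = dimnames(values))
  }
  if (!identical(dim(flags), dim(values)))
    stop("'flags' must have the same shape as 'values'")
  if (!all(flags %in% c("P", "M", "A")))
    stop("flags must be one of 'P', 'M', 'A'")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("feature%05d", seq_len(nrow(values)))
  dimnames(flags) <- dimnames(values)
  structure(list(values = values, groups = groups, flags = flags),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$values), "features x",
      ncol(x$values), "samples (log2 scale)\n")
  cat("Groups:", paste(sprintf("%s (n=%d)", levels(x$groups),
                               table(x$groups)), collapse = " vs "), "\n")
  tab <- table(factor(x$flags, levels = c("P", "M", "A")))
  cat(sprintf("Flags: P=%d M=%d A=%d\n", tab["P"], tab["M"], tab["A"]))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# Shared helper: column indices of control (first level) and case samples.
group_split <- function(groups) {
  lev <- levels(groups)
  list(ctrl = which(groups == lev[1L]), case = which(groups == lev[2L]),
       ctrl_label = lev[1L], case_label = lev[2L])
}
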