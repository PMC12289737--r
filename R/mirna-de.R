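#' Parameters for the miRNA Ct-array pipeline
#'
#' Defaults follow common OpenArray practice for a two-pass filter: a first
#' censoring pass at Ct > 35 before normalization, a stricter second pass at
#' Ct > 30 after normalization, removal of miRNAs undetermined in 4 or more
#' samples at each pass, and calling at BH-adjusted p <= 0.05 with a
#' two-sided fold-change threshold of 2.
#'
#' @param first_pass_threshold Ct above which values are censored before
#'   normalization (default 35).
#' @param second_pass_threshold Ct above which values are re-censored after
#'   normalization (default 30).
#' @param ceiling Ct value encoding "Undetermined" (default 40).
#' @param max_undetermined a miRNA undetermined in this many samples or
#'   more (counted over all samples) is removed (default 4).
#' @param alpha adjusted-p cutoff for calling (default 0.05).
#' @param fc_threshold fold-change threshold, applied two-sided: called
#'   when RQ > fc_threshold or RQ < 1/fc_threshold (default 2).
#'
#' @return A list of class `mirna_de_params`.
#' @export
mirna_de_params <- function(first_pass_threshold = 35,
                            second_pass_threshold = 30,
                            ceiling = 40,
                            max_undetermined = 4L,
                            alpha = 0.05,
                            fc_threshold = 2) {
  stopifnot(second_pass_threshold < first_pass_threshold,
            first_pass_threshold < ceiling,
            alpha > 0, alpha < 1,
            fc_threshold > 1,
            max_undetermined >= 1)
  structure(list(first_pass_threshold = first_pass_threshold,
                 second_pass_threshold = second_pass_threshold,
                 ceiling = ceiling,
                 max_undetermined = as.integer(max_undetermined),
                 alpha = alpha, fc_threshold = fc_threshold),
            class = "mirna_de_params")
}

#' Censor late-cycle Ct values to the Undetermined ceiling
#'
#' Every Ct value strictly greater than `threshold` is set to `ceiling`,
#' marking the reaction as Undetermined; all other values are untouched.
#' The operation is idempotent.
#'
#' @param ct a [ct_matrix()].
#' @param threshold Ct cutoff (strict inequality: a value exactly at the
#'   threshold is kept).
#' @param ceiling replacement value; defaults to the matrix's own ceiling.
#'
#' @return A censored `ct_matrix`.
#' @export
censor_high_ct <- function(ct, threshold, ceiling = ct$ceiling) {
  stopifnot(inherits(ct, "ct_matrix"), threshold < ceiling)
  v <- ct$values
  v[v > threshold] <- ceiling
  ct$values <- v
  ct$ceiling <- ceiling
  ct
}

#' Remove miRNAs undetermined in too many samples
#'
#' Drops features whose count of Undetermined values (entries equal to the
#' ceiling) reaches `max_undetermined`, counted across all samples of both
#' groups. Survivor order is preserved.
#'
#' @param ct a [ct_matrix()].
#' @param max_undetermined removal threshold: a feature with this many or
#'   more Undetermined values is removed.
#'
#' @return A list with `ct` (the filtered matrix) and `removed` (character
#'   vector of removed feature ids). Warns if no feature survives.
#' @export
drop_undetermined_features <- function(ct, max_undetermined = 4L) {
  stopifnot(inherits(ct, "ct_matrix"))
  n_und <- rowSums(ct$values == ct$ceiling)
  drop <- n_und >= max_undetermined
  removed <- rownames(ct$values)[drop]
  ct$values <- ct$values[!drop, , drop = FALSE]
  if (nrow(ct$values) == 0L)
    warning("no features survive the undetermined filter")
  list(ct = ct, removed = removed)
}

# Vectorised equal-variance two-sample t-test on the rows of a matrix.
# Returns two-sided p (NA where the pooled variance is zero) and the
# per-group means.
row_student_t <- function(values, groups) {
  gs <- group_split(groups)
  n1 <- length(gs$ctrl); n2 <- length(gs$case)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least two samples")
  m1 <- rowMeans(values[, gs$ctrl, drop = FALSE])
  m2 <- rowMeans(values[, gs$case, drop = FALSE])
  v1 <- apply(values[, gs$ctrl, drop = FALSE], 1L, var)
  v2 <- apply(values[, gs$case, drop = FALSE], 1L, var)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m2 - m1) / se
  p <- 2 * pt(-abs(tstat), df)
  p[se == 0] <- NA_real_   # degenerate: both groups constant
  list(mean_ctrl = m1, mean_case = m2, t = tstat, p = p, df = df)
}

#' Run the full miRNA Ct-array differential-expression pipeline
#'
#' Executes, in order: censoring at the first-pass threshold, removal of
#' miRNAs undetermined in `max_undetermined` or more samples, quantile
#' normalization (ceiling values included), re-censoring at the stricter
#' second-pass threshold, a second undetermined filter, a per-miRNA
#' equal-variance Student's t-test on the normalized Ct values,
#' Benjamini-Hochberg adjustment, and relative quantification
#' RQ = 2^-ddCt with ddCt = mean Ct(case) - mean Ct(control).
#'
#' Because lower Ct means higher abundance, ddCt < 0 (hence RQ > 1) marks
#' upregulation in the case group. A miRNA is called differentially
#' expressed when adjusted p <= `alpha` and RQ > `fc_threshold` or
#' RQ < 1/`fc_threshold`. miRNAs with zero pooled variance get an NA
#' p-value and are never callable.
#'
#' @param ct a [ct_matrix()] with two groups of at least two samples each.
#' @param params a [mirna_de_params()] object.
#'
#' @return An object of class `mirna_de`: a list with `table` (one row per
#'   surviving miRNA: id, mean_ctrl, mean_case, ddct, rq, raw_p, adj_p,
#'   direction, called), `stage_counts` (features surviving each stage),
#'   `removed` (ids removed at each filter pass), `params` and `groups`.
#' @export
#' @examples
#' cfg <- sim_config(n_mirnas = 60, frac_de = 0.1, seed = 7)
#' sim <- simulate_ct_experiment(cfg)
#' fit <- run_mirna_pipeline(sim$ct)
#' summary(fit)
run_mirna_pipeline <- function(ct, params = mirna_de_params()) {
  stopifnot(inherits(ct, "ct_matrix"), inherits(params, "mirna_de_params"))
  counts <- c(input = nrow(ct$values))

  ct1 <- censor_high_ct(ct, params$first_pass_threshold, params$ceiling)
  f1 <- drop_undetermined_features(ct1, params$max_undetermined)
  counts["first_pass"] <- nrow(f1$ct$values)

  norm <- f1$ct
  norm$values <- quantile_normalize(norm$values)

  ct2 <- censor_high_ct(norm, params$second_pass_threshold, params$ceiling)
  f2 <- drop_undetermined_features(ct2, params$max_undetermined)
  counts["second_pass"] <- nrow(f2$ct$values)

  final <- f2$ct
  tt <- row_student_t(final$values, final$groups)
  adj <- p.adjust(tt$p, method = "BH")
  ddct <- tt$mean_case - tt$mean_ctrl
  rq <- 2^(-ddct)
  called <- !is.na(adj) & adj <= params$alpha &
    (rq > params$fc_threshold | rq < 1 / params$fc_threshold)
  direction <- ifelse(!called, "none", ifelse(rq > 1, "up", "down"))
  n_degenerate <- sum(is.na(tt$p))
  if (n_degenerate > 0L)
    message(n_degenerate,
            " miRNA(s) with zero pooled variance: p set to NA, not callable")

  tab <- data.frame(id = rownames(final$values),
                    mean_ctrl = tt$mean_ctrl,
                    mean_case = tt$mean_case,
                    ddct = ddct, rq = rq,
                    raw_p = tt$p, adj_p = adj,
                    direction = direction, called = called,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, stage_counts = counts,
                 removed = list(first_pass = f1$removed,
                                second_pass = f2$removed),
                 params = params, groups = final$groups),
            class = "mirna_de")
}

#' @export
print.mirna_de <- function(x, ...) {
  cat("miRNA Ct-array differential expression\n")
  cat("Stage survivors:",
      paste(sprintf("%s=%d", names(x$stage_counts), x$stage_counts),
            collapse = ", "), "\n")
  cat(sum(x$table$called), "miRNAs called at adj p <=", x$params$alpha,
      "and FC >", x$params$fc_threshold,
      sprintf("(%d up, %d down)\n", sum(x$table$direction == "up"),
              sum(x$table$direction == "down")))
  invisible(x)
}

#' @export
summary.mirna_de <- function(object, n = 10L, ...) {
  print(object)
  tab <- object$table[order(object$table$adj_p), ]
  cat("\nTop miRNAs by adjusted p:\n")
  print(head(tab, n), digits = 4, row.names = FALSE)
  invisible(tab)
}

#' @export
as.data.frame.mirna_de <- function(x, ...) x$table
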