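#' Relative quantification by the comparative Ct (2^-ddCt) method
#'
#' For each replicate, dCt = Ct(target) - Ct(reference) normalizes the
#' target to a reference (housekeeping) gene. ddCt subtracts the mean
#' control dCt, and RQ = 2^-ddCt is the fold change relative to the
#' control condition; control replicates are referenced to the same
#' control mean, so their mean RQ centers on 1. Group difference is
#' tested by an equal-variance two-sided Student's t-test on the
#' replicate dCt values (the log-scale, variance-stabilized quantity).
#'
#' @param case_target,case_reference numeric vectors of per-replicate Ct
#'   values for the target and reference gene in the case group (same
#'   length, >= 2 replicates).
#' @param control_target,control_reference as above for the control group.
#'
#' @return An object of class `rq_result`: list with per-replicate
#'   `rq_case` and `rq_control`, `ddct_case`, group `mean` and `sem` of
#'   RQ, `mean_ddct`, and `t_p` (p-value of the t-test on dCt).
#' @export
#' @examples
#' delta_delta_ct(case_target = c(24.0, 24.1, 23.9),
#'                case_reference = c(21, 21, 21),
#'                control_target = c(26.0, 26.1, 25.9),
#'                control_reference = c(21, 21, 21))
#' # case is ~2 cycles earlier: RQ near 4
delta_delta_ct <- function(case_target, case_reference,
                           control_target, control_reference) {
  if (length(case_target) != length(case_reference) ||
      length(control_target) != length(control_reference))
    stop("target and reference replicate vectors must have equal length")
  if (length(case_target) < 2L || length(control_target) < 2L)
    stop("at least two replicates per group are required")
  if (any(!is.finite(c(case_target, case_reference,
                       control_target, control_reference))))
    stop("Ct values must be finite")
  dct_case <- case_target - case_reference
  dct_ctrl <- control_target - control_reference
  ref <- mean(dct_ctrl)
  ddct_case <- dct_case - ref
  ddct_ctrl <- dct_ctrl - ref
  rq_case <- 2^(-ddct_case)
  rq_ctrl <- 2^(-ddct_ctrl)
  sem <- function(x) sd(x) / sqrt(length(x))
  p <- if (sd(dct_case) == 0 && sd(dct_ctrl) == 0) {
    if (isTRUE(all.equal(mean(dct_case), mean(dct_ctrl)))) 1 else 0
  } else {
    t.test(dct_case, dct_ctrl, var.equal = TRUE)$p.value
  }
  structure(list(rq_case = rq_case, rq_control = rq_ctrl,
                 ddct_case = ddct_case,
                 mean = c(case = mean(rq_case), control = mean(rq_ctrl)),
                 sem = c(case = sem(rq_case), control = sem(rq_ctrl)),
                 mean_ddct = mean(ddct_case),
                 t_p = p),
            class = "rq_result")
}

#' @export
print.rq_result <- function(x, ...) {
  cat(sprintf("RQ = 2^-ddCt: case %.3g +/- %.2g, control %.3g +/- %.2g (mean +/- SEM)\n",
              x$mean["case"], x$sem["case"],
              x$mean["control"], x$sem["control"]))
  cat(sprintf("mean ddCt = %.3g, Student's t on dCt: p = %.4g\n",
              x$mean_ddct, x$t_p))
  invisible(x)
}

#' Cross-platform concordance of fold changes
#'
#' Pearson correlation of paired per-gene log2 fold changes measured on
#' two platforms (e.g. qPCR vs microarray), with a two-sided p-value from
#' the t transform of r, plus the fraction of genes whose fold-change
#' sign agrees between platforms.
#'
#' @param a,b numeric vectors of log2 fold changes. If both are named,
#'   they are matched by name; otherwise they are paired positionally.
#'
#' @return An object of class `concordance_result`: list with `r`, `p`,
#'   `n`, `sign_agreement` and the matched vectors.
#' @export
platform_concordance <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  }
  if (length(a) != length(b)) stop("'a' and 'b' must pair up")
  if (length(a) < 3L) stop("need at least 3 paired fold changes")
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero variance in one platform's fold changes")
  ct <- cor.test(a, b, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(a),
                 sign_agreement = mean(sign(a) == sign(b)),
                 a = a, b = b),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Platform concordance: Pearson r = %.3f, p = %.3g, n = %d\n",
              x$r, x$p, x$n))
  cat(sprintf("Fold-change sign agreement: %.1f%%\n",
              100 * x$sign_agreement))
  invisible(x)
}
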