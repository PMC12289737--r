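#' Parameters for the microarray differential-expression pipeline
#'
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param fc_threshold linear fold-change threshold, inclusive: a gene is
#'   called when 2^|log2FC| >= fc_threshold (default 1.5).
#' @param cv_max coefficient-of-variation cutoff on linear-scale
#'   intensities; a feature must have CV < cv_max in both conditions
#'   (default 0.50).
#'
#' @return A list of class `mrna_de_params`.
#' @export
mrna_de_params <- function(alpha = 0.05, fc_threshold = 1.5, cv_max = 0.50) {
  stopifnot(alpha > 0, alpha < 1, fc_threshold > 1, cv_max > 0)
  structure(list(alpha = alpha, fc_threshold = fc_threshold, cv_max = cv_max),
            class = "mrna_de_params")
}

#' Detection-flag filter
#'
#' Retains features flagged present (`"P"`) or marginal (`"M"`) in at
#' least one sample; features absent everywhere are removed.
#'
#' @param expr an [expression_matrix()].
#'
#' @return A list with `expr` (filtered matrix) and `removed` (ids).
#' @export
flag_filter <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  keep <- rowSums(expr$flags == "P" | expr$flags == "M") >= 1L
  removed <- rownames(expr$values)[!keep]
  expr$values <- expr$values[keep, , drop = FALSE]
  expr$flags <- expr$flags[keep, , drop = FALSE]
  list(expr = expr, removed = removed)
}

#' Coefficient-of-variation filter
#'
#' Computes, per feature and per condition, CV = sd/mean of the
#' linear-scale intensities (2^log2 value) and retains the feature only if
#' CV < `cv_max` in both conditions (strict inequality). Features whose
#' linear mean is not positive have no defined CV and are removed.
#'
#' @param expr an [expression_matrix()] with at least two samples per group.
#' @param cv_max CV cutoff as a fraction (0.5 means 50%).
#'
#' @return A list with `expr` and `removed`.
#' @export
cv_filter <- function(expr, cv_max = 0.50) {
  stopifnot(inherits(expr, "expression_matrix"), cv_max > 0)
  gs <- group_split(expr$groups)
  if (length(gs$ctrl) < 2L || length(gs$case) < 2L)
    stop("each condition needs at least two samples for a CV")
  lin <- 2^expr$values
  cv_of <- function(cols) {
    m <- rowMeans(lin[, cols, drop = FALSE])
    s <- apply(lin[, cols, drop = FALSE], 1L, sd)
    ifelse(m > 0, s / m, Inf)
  }
  keep <- cv_of(gs$ctrl) < cv_max & cv_of(gs$case) < cv_max
  removed <- rownames(expr$values)[!keep]
  expr$values <- expr$values[keep, , drop = FALSE]
  expr$flags <- expr$flags[keep, , drop = FALSE]
  list(expr = expr, removed = removed)
}

# Inverse of the trigamma function by Newton iteration on 1/trigamma,
# which is nearly linear. Accepts a vector; returns Inf for y <= 0.
trigamma_inverse <- function(y) {
  out <- y
  for (i in seq_along(y)) {
    yi <- y[i]
    if (!is.finite(yi) || yi <= 0) { out[i] <- Inf; next }
    if (yi > 1e7) { out[i] <- 1 / sqrt(yi); next }
    if (yi < 1e-6) { out[i] <- 1 / yi; next }
    x <- 0.5 + 1 / yi
    for (iter in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif) / x < 1e-8) break
    }
    out[i] <- x
  }
  out
}

# Empirical-Bayes hyperparameters (prior df d0, prior variance s0^2) from
# per-feature sample variances s2 on d residual df, by moment matching of
# z = log(s2) against the scaled-F model: E z = log s0^2 + digamma(d0/2) -
# log(d0/2) + log(d/2) - digamma(d/2), Var z = trigamma(d/2) +
# trigamma(d0/2). Zero variances are excluded from estimation.
estimate_variance_prior <- function(s2, df) {
  z <- log(s2[s2 > 0])
  if (length(z) < 2L)
    stop("need at least two positive sample variances to fit a prior")
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderated t-test for two-group microarrays
#'
#' Fits, per feature, the log2 fold change mean(case) - mean(control) and
#' the pooled sample variance on d = n1 + n2 - 2 df, shrinks the variances
#' toward a common prior by empirical Bayes, and tests each moderated
#' statistic against a t distribution with d0 + d degrees of freedom.
#'
#' The prior degrees of freedom d0 and prior variance s0^2 are estimated
#' by closed-form moment matching on the log sample variances (mean and
#' variance of log s^2 matched to their digamma/trigamma expressions under
#' a scaled-F model, solved with an inverse-trigamma Newton step). The
#' posterior variance is the df-weighted average
#' (d0 s0^2 + d s^2) / (d0 + d), so each moderated variance lies between
#' the feature's own variance and the prior. `d0 = 0` recovers the
#' ordinary pooled t-test; `d0 = Inf` pools all features to the common
#' prior variance.
#'
#' The input is quantile-normalized before fitting; typically it has
#' already passed [flag_filter()] and [cv_filter()].
#'
#' @param expr an [expression_matrix()] (log2 scale) with two groups of at
#'   least two samples each.
#' @param params an [mrna_de_params()].
#' @param d0_override optional fixed prior df, bypassing estimation (0
#'   gives the ordinary t-test). If the moment estimator fails, the fit
#'   falls back to d0 = 0 with a warning.
#' @param normalize quantile-normalize the matrix first (default TRUE).
#'
#' @return An object of class `mrna_de`: list with `table` (id, mean_ctrl,
#'   mean_case, log2fc, fc, t, raw_p, adj_p, direction, called), `eb`
#'   (d0, s0_sq, df_resid, per-feature s2 and s2_post), `params`, `groups`.
#'   `fc` is the signed linear fold change, 2^|log2FC| with the sign of
#'   log2FC.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 200, frac_de = 0.1, seed = 3)
#' sim <- simulate_microarray(cfg)
#' fit <- fit_moderated_t(sim$expr)
#' summary(fit)
fit_moderated_t <- function(expr, params = mrna_de_params(),
                            d0_override = NULL, normalize = TRUE) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(params, "mrna_de_params"))
  gs <- group_split(expr$groups)
  n1 <- length(gs$ctrl); n2 <- length(gs$case)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least two samples")
  values <- expr$values
  if (normalize) values <- quantile_normalize(values)

  m1 <- rowMeans(values[, gs$ctrl, drop = FALSE])
  m2 <- rowMeans(values[, gs$case, drop = FALSE])
  log2fc <- m2 - m1
  df <- n1 + n2 - 2L
  v1 <- apply(values[, gs$ctrl, drop = FALSE], 1L, var)
  v2 <- apply(values[, gs$case, drop = FALSE], 1L, var)
  s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / df

  if (is.null(d0_override)) {
    prior <- tryCatch(estimate_variance_prior(s2, df), error = function(e) {
      warning("variance-prior estimation failed (", conditionMessage(e),
              "); falling back to the ordinary t-test (d0 = 0)")
      list(d0 = 0, s0_sq = NA_real_)
    })
  } else {
    prior <- list(d0 = d0_override,
                  s0_sq = if (d0_override > 0)
                    estimate_variance_prior(s2, df)$s0_sq else NA_real_)
  }
  d0 <- prior$d0; s0_sq <- prior$s0_sq

  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
             else if (d0 == 0) s2
             else (d0 * s0_sq + df * s2) / (d0 + df)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- log2fc / se
  p <- 2 * pt(-abs(tstat), d0 + df)
  p[se == 0] <- NA_real_
  adj <- p.adjust(p, method = "BH")

  fc <- sign(log2fc) * 2^abs(log2fc)
  called <- !is.na(adj) & adj < params$alpha &
    2^abs(log2fc) >= params$fc_threshold
  direction <- ifelse(!called, "none", ifelse(log2fc > 0, "up", "down"))

  tab <- data.frame(id = rownames(values),
                    mean_ctrl = m1, mean_case = m2,
                    log2fc = log2fc, fc = fc, t = tstat,
                    raw_p = p, adj_p = adj,
                    direction = direction, called = called,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab,
                 eb = list(d0 = d0, s0_sq = s0_sq, df_resid = df,
                           s2 = s2, s2_post = s2_post),
                 params = params, groups = expr$groups,
                 normalized_values = values),
            class = "mrna_de")
}

#' @export
print.mrna_de <- function(x, ...) {
  cat("Microarray moderated-t differential expression\n")
  cat(sprintf("%d features, prior df d0 = %.3g, prior variance s0^2 = %.4g\n",
              nrow(x$table), x$eb$d0, x$eb$s0_sq))
  cat(sum(x$table$called), "genes called at adj p <", x$params$alpha,
      "and |FC| >=", x$params$fc_threshold,
      sprintf("(%d up, %d down)\n", sum(x$table$direction == "up"),
              sum(x$table$direction == "down")))
  invisible(x)
}

#' @export
summary.mrna_de <- function(object, n = 10L, ...) {
  print(object)
  tab <- object$table[order(object$table$adj_p), ]
  cat("\nTop genes by adjusted p:\n")
  print(head(tab, n), digits = 4, row.names = FALSE)
  invisible(tab)
}

#' @export
as.data.frame.mrna_de <- function(x, ...) x$table

#' @export
coef.mrna_de <- function(object, ...) {
  setNames(object$table$log2fc, object$table$id)
}

#' Split called genes into up- and downregulated sets
#'
#' @param de an `mrna_de` or `mirna_de` fit.
#'
#' @return A list with character vectors `up` and `down`; disjoint, and
#'   their union is exactly the called set.
#' @export
call_degs <- function(de) {
  tab <- de$table
  list(up = tab$id[tab$direction == "up"],
       down = tab$id[tab$direction == "down"])
}

#' Expressed-gene background by low-expression exclusion
#'
#' Computes each feature's mean normalized expression across all samples
#' and retains features at or above the given percentile of that
#' distribution (ties at the cutoff are kept). With `percentile = 10`
#' this reproduces the common "drop the bottom decile" expressed-gene
#' background for enrichment analyses.
#'
#' @param expr an [expression_matrix()] (normalized scale).
#' @param percentile percentile in `[0, 100)` below which features are
#'   excluded.
#'
#' @return Character vector of background feature ids.
#' @export
build_background <- function(expr, percentile = 10) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (percentile < 0 || percentile >= 100)
    stop("'percentile' must be in [0, 100)")
  means <- rowMeans(expr$values)
  cut <- quantile(means, percentile / 100, names = FALSE)
  rownames(expr$values)[means >= cut]
}
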