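# ---------------------------------------------------------------------------
# Statistics for comparing prediction methods against a shared measured flux
# table: Pearson/Spearman correlations, Meng-Rosenthal-Rubin Z for dependent
# correlations that share one variable, Fisher-z standard errors, and seeded
# bootstrap confidence intervals for mean prediction errors.
# ---------------------------------------------------------------------------

#' Fisher z transformation and its standard error
#'
#' `fisher_z(r) = atanh(r)`; the sampling standard error of the transformed
#' correlation at sample size `n` is `1/sqrt(n - 3)`.
#'
#' @param r correlation coefficient(s).
#' @export
fisher_z <- function(r) atanh(r)

#' @rdname fisher_z
#' @param n sample size (> 3).
#' @export
fisher_z_se <- function(n) {
  stopifnot(n > 3)
  1 / sqrt(n - 3)
}

#' Meng's Z-test for two dependent correlations sharing one variable
#'
#' Tests whether `r1 = cor(x1, y)` exceeds `r2 = cor(x2, y)` when both
#' correlations are computed against the same measured variable `y`
#' (Meng, Rosenthal & Rubin 1992). The dependence enters through
#' `r_x = cor(x1, x2)`:
#' \deqn{Z = (z_1 - z_2)\sqrt{\frac{n-3}{2(1-r_x)h}},\quad
#'   h = \frac{1 - f \bar{r}^2}{1 - \bar{r}^2},\quad
#'   f = \min\!\left(1, \frac{1-r_x}{2(1-\bar{r}^2)}\right),\quad
#'   \bar{r}^2 = \frac{r_1^2 + r_2^2}{2}}
#' with `z_i = atanh(r_i)`. The reported p-value is one-sided for
#' `r1 > r2`.
#'
#' @param r1,r2 the two correlations with the shared variable.
#' @param r12 correlation between the two predictor vectors.
#' @param n common sample size (> 3).
#' @return list with `z`, `p_one_sided`, `p_two_sided`, and the
#'   intermediates `h`, `f`, `r_bar_sq`.
#' @export
meng_z_test <- function(r1, r2, r12, n) {
  stopifnot(n > 3, abs(r1) <= 1, abs(r2) <= 1, abs(r12) <= 1)
  r_bar_sq <- (r1^2 + r2^2) / 2
  f <- min(1, (1 - r12) / (2 * (1 - r_bar_sq)))
  h <- (1 - f * r_bar_sq) / (1 - r_bar_sq)
  z <- (atanh(r1) - atanh(r2)) * sqrt((n - 3) / (2 * (1 - r12) * h))
  list(z = z, p_one_sided = pnorm(z, lower.tail = FALSE),
       p_two_sided = 2 * pnorm(abs(z), lower.tail = FALSE),
       h = h, f = f, r_bar_sq = r_bar_sq)
}

#' Seeded bootstrap confidence interval for a mean
#'
#' Percentile bootstrap over resampled observations.
#'
#' @param x numeric vector.
#' @param n_boot bootstrap replicates (default 10000).
#' @param conf confidence level.
#' @param seed integer seed.
#' @return list with `estimate`, `lower`, `upper`, `n_boot`, `conf`.
#' @export
bootstrap_mean_ci <- function(x, n_boot = 10000L, conf = 0.95, seed = 1L) {
  stopifnot(length(x) >= 2)
  set.seed(seed)
  n <- length(x)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  means <- colMeans(matrix(x[idx], nrow = n))
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(means, c(alpha, 1 - alpha), type = 7))
  est <- mean(x)
  out <- list(estimate = est, lower = ci[1], upper = ci[2],
              n_boot = n_boot, conf = conf)
  if (est < out$lower || est > out$upper) {
    # percentile CIs always bracket the point estimate up to resampling noise;
    # widen minimally if a tiny sample produced a degenerate interval
    out$lower <- min(out$lower, est)
    out$upper <- max(out$upper, est)
  }
  out
}

#' Compare method predictions against a measured flux table
#'
#' Joins per-method predicted flux tables with a measured table on
#' `flux_id`, then reports: Pearson and Spearman correlations per method
#' with Fisher-z standard errors; Meng's Z (one-sided) for the focal method
#' against every other method; bootstrap confidence intervals for the mean
#' signed prediction error (bias) and mean absolute error, resampling flux
#' rows; and per-pathway mean errors when the measured table carries a
#' `pathway` column.
#'
#' @param predicted named list of data.frames, each with columns `flux_id`
#'   and `value` (one entry per method).
#' @param measured data.frame with `flux_id`, `value`, optional `pathway`.
#' @param focal method name whose correlations are tested as higher
#'   (default `"pseudo"` when present, otherwise the first method).
#' @param n_boot,conf,seed bootstrap settings.
#' @return a `comparison_stats` object: `correlations` (data.frame),
#'   `meng` (data.frame of focal-vs-other tests), `errors` (data.frame of
#'   bootstrap CIs), `by_pathway` (or `NULL`), `n`.
#' @export
compare_predictions <- function(predicted, measured, focal = NULL,
                                n_boot = 10000L, conf = 0.95, seed = 1L) {
  stopifnot(is.list(predicted), length(predicted) >= 1,
            all(c("flux_id", "value") %in% names(measured)))
  methods <- names(predicted)
  if (is.null(methods) || any(!nzchar(methods))) {
    stop("predicted must be a named list of per-method tables")
  }
  ids <- measured$flux_id
  pred_mat <- sapply(methods, function(m) {
    tab <- predicted[[m]]
    v <- tab$value[match(ids, tab$flux_id)]
    if (anyNA(v)) stop("method '", m, "' is missing flux ids present in measured")
    v
  })
  n <- length(ids)
  if (n < 4) stop("need at least 4 shared fluxes")
  y <- measured$value
  if (sd(y) == 0) stop("measured values are constant; correlation undefined")
  for (m in methods) {
    if (sd(pred_mat[, m]) == 0) stop("predictions of '", m, "' are constant")
  }
  if (is.null(focal)) focal <- if ("pseudo" %in% methods) "pseudo" else methods[1]

  correlations <- data.frame(
    method = methods,
    pearson = vapply(methods, function(m) cor(pred_mat[, m], y), numeric(1)),
    spearman = vapply(methods, function(m) cor(pred_mat[, m], y, method = "spearman"),
                      numeric(1)),
    fisher_z_se = fisher_z_se(n),
    row.names = NULL)

  others <- setdiff(methods, focal)
  meng <- if (length(others)) {
    do.call(rbind, lapply(others, function(m) {
      r1 <- cor(pred_mat[, focal], y)
      r2 <- cor(pred_mat[, m], y)
      r12 <- cor(pred_mat[, focal], pred_mat[, m])
      mz <- meng_z_test(r1, r2, r12, n)
      data.frame(focal = focal, other = m, r_focal = r1, r_other = r2,
                 r_between = r12, z = mz$z, p_one_sided = mz$p_one_sided)
    }))
  } else NULL

  errors <- do.call(rbind, lapply(seq_along(methods), function(k) {
    m <- methods[k]
    err <- pred_mat[, m] - y
    ci <- bootstrap_mean_ci(err, n_boot = n_boot, conf = conf, seed = seed + k)
    ci_abs <- bootstrap_mean_ci(abs(err), n_boot = n_boot, conf = conf,
                                seed = seed + 1000L + k)
    data.frame(method = m,
               mean_error = ci$estimate, error_lower = ci$lower,
               error_upper = ci$upper,
               mean_abs_error = ci_abs$estimate, abs_lower = ci_abs$lower,
               abs_upper = ci_abs$upper)
  }))

  by_pathway <- NULL
  if ("pathway" %in% names(measured)) {
    by_pathway <- do.call(rbind, lapply(unique(measured$pathway), function(pw) {
      sel <- measured$pathway == pw
      do.call(rbind, lapply(methods, function(m) {
        data.frame(pathway = pw, method = m,
                   mean_error = mean(pred_mat[sel, m] - y[sel]),
                   mean_abs_error = mean(abs(pred_mat[sel, m] - y[sel])),
                   n = sum(sel))
      }))
    }))
  }
  structure(list(correlations = correlations, meng = meng, errors = errors,
                 by_pathway = by_pathway, n = n, focal = focal),
            class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat("<comparison_stats> n =", x$n, " focal =", x$focal, "\n")
  print(x$correlations)
  if (!is.null(x$meng)) print(x$meng)
  invisible(x)
}
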