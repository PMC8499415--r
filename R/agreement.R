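#' Intraclass correlation, two-way random, absolute agreement, single measures
#'
#' ICC(A,1) in the McGraw & Wong nomenclature, the standard agreement index
#' for interchangeable raters: subjects and raters are both random effects
#' and systematic rater differences count against agreement. Computed from
#' the two-way ANOVA mean squares; the 95% confidence interval uses the
#' F-distribution with Satterthwaite degrees of freedom.
#'
#' @param ratings numeric matrix or data.frame, subjects in rows, raters in
#'   columns; no missing cells.
#' @param conf confidence level (default 0.95).
#' @return object of class `icc_result`: `estimate`, `ci_low`, `ci_high`,
#'   `model`, `n_subjects`, `n_raters` and the mean squares.
#' @export
icc <- function(ratings, conf = 0.95) {
  x <- as.matrix(ratings)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("missing cells in ratings; no imputation is performed")
  n <- nrow(x); k <- ncol(x)
  if (k < 2L) stop("need at least 2 raters")
  if (n < 3L) stop("need at least 3 subjects")
  grand <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  MSR <- k * sum((rm_ - grand)^2) / (n - 1)
  MSC <- n * sum((cm - grand)^2) / (k - 1)
  SSE <- sum((x - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  eps <- 1e-14 * max(abs(x), 1)
  if (abs(denom) < eps^2 || (MSE < eps && MSC < eps && MSR < eps)) {
    # all ratings identical
    est <- 1; ci <- c(1, 1)
  } else if (MSE < eps && MSC < eps) {
    est <- 1; ci <- c(1, 1)
  } else {
    est <- (MSR - MSE) / denom
    alpha <- 1 - conf
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / (n - 1))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    upper <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    ci <- c(max(-1, min(lower, est)), min(1, max(upper, est)))
  }
  structure(list(estimate = est, ci_low = ci[1], ci_high = ci[2],
                 model = "two-way random, absolute agreement, single measures (ICC(A,1))",
                 n_subjects = n, n_raters = k,
                 MSR = MSR, MSC = MSC, MSE = MSE, conf = conf),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.4f (%d%% CI %.4f - %.4f), %d subjects x %d raters\n",
              x$estimate, round(100 * x$conf), x$ci_low, x$ci_high,
              x$n_subjects, x$n_raters))
  invisible(x)
}

#' Bland-Altman agreement analysis against a reference method
#'
#' Differences are `a - b` with `b` the reference. Bias is the mean
#' difference; the 95% limits of agreement are bias +/- 1.96 sd (sample sd,
#' n - 1 denominator). The bias confidence interval uses the t distribution;
#' the limits' confidence intervals use the classical sqrt(3/n)
#' approximation. A one-sample t-test asks whether the bias differs from
#' zero; with zero-variance differences the test is flagged undefined.
#'
#' @param a measurements of the tested method (mm).
#' @param b measurements of the reference method (mm), same length.
#' @param conf confidence level for the CIs (default 0.95).
#' @return object of class `bland_altman`: `bias`, `bias_ci`, `loa_low`,
#'   `loa_high`, `loa_low_ci`, `loa_high_ci`, `sd_diff`, `n`, `t_stat`,
#'   `p_value`, `degenerate` flag, and plot data (`mean`, `difference`).
#' @export
bland_altman <- function(a, b, conf = 0.95) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("input length mismatch")
  n <- length(a)
  if (n < 3L) stop("need at least 3 paired measurements")
  if (anyNA(a) || anyNA(b)) stop("missing values in measurements")
  d <- a - b
  bias <- mean(d)
  sdd <- stats::sd(d)
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  loa_low <- bias - 1.96 * sdd
  loa_high <- bias + 1.96 * sdd
  se_bias <- sdd / sqrt(n)
  se_loa <- sdd * sqrt(3 / n)
  degenerate <- sdd < 1e-300
  t_stat <- if (degenerate) NA_real_ else bias / se_bias
  p_value <- if (degenerate) NA_real_ else
    2 * stats::pt(-abs(t_stat), df = n - 1)
  structure(list(
    bias = bias,
    bias_ci = c(bias - tq * se_bias, bias + tq * se_bias),
    loa_low = loa_low, loa_high = loa_high,
    loa_low_ci = c(loa_low - tq * se_loa, loa_low + tq * se_loa),
    loa_high_ci = c(loa_high - tq * se_loa, loa_high + tq * se_loa),
    sd_diff = sdd, n = n, t_stat = t_stat, p_value = p_value,
    degenerate = degenerate, conf = conf,
    plot_data = data.frame(mean = (a + b) / 2, difference = d)),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: bias %.3f mm (%.3f - %.3f), LoA %.3f to %.3f mm, n = %d\n",
    x$bias, x$bias_ci[1], x$bias_ci[2], x$loa_low, x$loa_high, x$n))
  if (x$degenerate) cat("  (zero-variance differences: t-test undefined)\n")
  else cat(sprintf("  one-sample t = %.3f, p = %.4g\n", x$t_stat, x$p_value))
  invisible(x)
}

#' Multiplicity adjustment of p-values
#'
#' Bonferroni by default (conservative and reproducible across software);
#' any method of [stats::p.adjust()] can be selected. Adjusted values are
#' monotone in the raw values and capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method adjustment method (default `"bonferroni"`).
#' @return adjusted p-values.
#' @export
adjust_p <- function(p, method = "bonferroni") {
  nm <- names(p)
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::setNames(stats::p.adjust(p, method = method), nm)
}

#' Stratify deviations by reference-curvature threshold
#'
#' Splits deviation records at `|kappa| = kappa_threshold` (default 1 1/mm,
#' the clinically observed threshold below which manual point selection
#' becomes unreliable) and summarises each stratum; also returns the
#' (|kappa|, deviation) scatter data behind curvature-vs-deviation plots.
#'
#' @param deviations data.frame with columns `deviation_mm` and
#'   `reference_kappa_per_mm` (as produced by [batch_measure()]), or a list
#'   of `deviation_record`s.
#' @param kappa_threshold curvature magnitude threshold (1/mm).
#' @return list with `summary` (per-stratum n, median |deviation|, IQR, 95th
#'   percentile), `scatter` data.frame, and the threshold used.
#' @export
threshold_stratify <- function(deviations, kappa_threshold = 1.0) {
  df <- if (is.data.frame(deviations)) deviations else
    do.call(rbind, lapply(deviations, function(d)
      data.frame(deviation_mm = d$deviation,
                 reference_kappa_per_mm = d$reference_kappa)))
  df <- df[!is.na(df$deviation_mm), , drop = FALSE]
  ak <- abs(df$reference_kappa_per_mm)
  strata <- list(below = ak < kappa_threshold, above = ak >= kappa_threshold)
  summ <- do.call(rbind, lapply(names(strata), function(nm) {
    sel <- strata[[nm]]
    dv <- abs(df$deviation_mm[sel])
    if (length(dv) == 0L)
      data.frame(stratum = nm, n = 0L, median_abs_dev_mm = NA_real_,
                 iqr_mm = NA_real_, q95_mm = NA_real_)
    else
      data.frame(stratum = nm, n = length(dv),
                 median_abs_dev_mm = stats::median(dv),
                 iqr_mm = stats::IQR(dv),
                 q95_mm = unname(stats::quantile(dv, 0.95)))
  }))
  list(summary = summ,
       scatter = data.frame(abs_kappa_per_mm = ak,
                            deviation_mm = df$deviation_mm),
       threshold = kappa_threshold)
}
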