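#' Mean bias with t-based confidence interval and paired t-test
#'
#' Bias is defined as mean(estimated - measured). With zero-variance
#' differences the interval degenerates to a point and the paired-t p value
#' is reported as 1 with an `exact_agreement` flag (the test statistic is
#' undefined).
#'
#' @param measured,estimated Paired numeric vectors, length >= 3.
#' @param level Confidence level (0.95).
#' @return List: `bias`, `ci` (length 2), `p`, `n`, `exact_agreement`.
#' @export
mean_bias_ci <- function(measured, estimated, level = 0.95) {
  stopifnot(length(measured) == length(estimated), length(measured) >= 3)
  d <- estimated - measured
  n <- length(d)
  bias <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    return(list(bias = bias, ci = c(bias, bias), p = 1, n = n,
                exact_agreement = TRUE))
  }
  tt <- stats::t.test(estimated, measured, paired = TRUE,
                      conf.level = level)
  list(bias = bias, ci = as.numeric(tt$conf.int), p = unname(tt$p.value),
       n = n, exact_agreement = FALSE)
}

# Hittner-May-Silver modification of Dunn & Clark's z for two dependent
# overlapping correlations r(j,k) vs r(j,h) sharing variable j: the
# correlation-covariance term is evaluated at the back-transformed average
# of the two Fisher-z values.
hms_z_test <- function(r_jk, r_jh, r_kh, n) {
  # clamp away from +/-1 so perfect correlations give an infinite-z limit
  cl <- function(r) pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  r_jk <- cl(r_jk); r_jh <- cl(r_jh)
  z1 <- atanh(r_jk); z2 <- atanh(r_jh)
  rb <- tanh((z1 + z2) / 2)
  c_num <- r_kh * (1 - rb^2 - rb^2) - 0.5 * rb * rb * (1 - rb^2 - rb^2 - r_kh^2)
  c_den <- (1 - rb^2) * (1 - rb^2)
  cc <- c_num / c_den
  # cc is a correlation for non-degenerate inputs; a (near-)perfect r_jk or
  # r_jh drives it past 1, the infinite-information limit of the z statistic
  cc <- max(min(cc, 1 - 1e-12), -1)
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cc))
  p <- 2 * stats::pnorm(-abs(z))
  list(z = z, p = p)
}

#' Pearson correlations of two estimators with a dependent-correlations test
#'
#' Computes r(measured, estA) and r(measured, estB) and tests their equality
#' with the Hittner--May--Silver modification of Dunn--Clark's z for
#' dependent overlapping correlations (both correlations share the measured
#' variable), two-sided.
#'
#' @param measured Common reference vector.
#' @param est_a,est_b The two estimate vectors.
#' @return List: `r_a`, `r_b`, `r_ab`, `z`, `p`, `n`.
#' @export
pearson_with_comparison <- function(measured, est_a, est_b) {
  n <- length(measured)
  stopifnot(length(est_a) == n, length(est_b) == n, n >= 10)
  for (v in list(measured, est_a, est_b))
    if (stats::sd(v) == 0)
      stop("correlation undefined for a constant vector", call. = FALSE)
  r_a <- stats::cor(measured, est_a)
  r_b <- stats::cor(measured, est_b)
  r_ab <- stats::cor(est_a, est_b)
  if (isTRUE(all.equal(r_a, r_b))) {
    return(list(r_a = r_a, r_b = r_b, r_ab = r_ab, z = 0, p = 1, n = n))
  }
  ht <- hms_z_test(r_a, r_b, r_ab, n)
  list(r_a = r_a, r_b = r_b, r_ab = r_ab, z = ht$z, p = ht$p, n = n)
}

#' Intraclass correlation ICC(A,1): two-way model, single measures,
#' absolute agreement
#'
#' Treats the measured and estimated series as k = 2 raters of n subjects.
#' Point estimate `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` from
#' the two-way ANOVA mean squares; confidence interval by the McGraw--Wong
#' F-based procedure (the SPSS "2-way mixed, single measures, absolute
#' agreement" output). Reliability labels: < 0.5 poor, 0.5--0.75 moderate,
#' 0.75--0.9 good, > 0.9 excellent.
#'
#' @param measured,estimated Paired numeric vectors, length >= 5.
#' @param level Confidence level (0.95).
#' @return List: `icc`, `ci`, `label`, `ms` (the ANOVA mean squares), `n`.
#' @export
icc_a1 <- function(measured, estimated, level = 0.95) {
  n <- length(measured)
  stopifnot(length(estimated) == n, n >= 5)
  k <- 2
  y <- cbind(measured, estimated)
  row_m <- rowMeans(y); col_m <- colMeans(y); grand <- mean(y)
  if (stats::var(row_m) == 0)
    stop("zero between-subject variance: ICC undefined", call. = FALSE)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SST <- sum((y - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))

  # McGraw & Wong agreement-ICC interval
  alpha <- 1 - level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  hi <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  if (MSE == 0) { lo <- hi <- icc }  # exact agreement up to affine column shift
  label <- if (icc < 0.5) "poor" else if (icc < 0.75) "moderate"
           else if (icc <= 0.90) "good" else "excellent"
  list(icc = icc, ci = c(lo, hi), label = label,
       ms = c(MSR = MSR, MSC = MSC, MSE = MSE), n = n)
}

#' Proportion of estimates within a cutoff of the measured values
#'
#' `mode = "relative"`: percentage with |est - meas| / meas <= cutoff
#' (requires measured > 0); `mode = "absolute"`: percentage with
#' |est - meas| <= cutoff (mmol/day). Boundaries are inclusive. `cutoff` may
#' be a vector, giving the cumulative-agreement curve used in cutoff plots.
#'
#' @param measured,estimated Paired numeric vectors.
#' @param mode "relative" or "absolute".
#' @param cutoff Non-negative cutoff(s).
#' @return Percentage(s) in `[0, 100]`, one per cutoff.
#' @export
proportion_within <- function(measured, estimated,
                              mode = c("relative", "absolute"), cutoff) {
  mode <- match.arg(mode)
  stopifnot(length(measured) == length(estimated), length(measured) >= 1)
  check_num(cutoff, "cutoff", 0)
  dev <- abs(estimated - measured)
  if (mode == "relative") {
    if (any(measured <= 0))
      stop("relative mode requires measured > 0", call. = FALSE)
    dev <- dev / measured
  }
  vapply(cutoff, function(ct) 100 * mean(dev <= ct), numeric(1))
}

#' P30 accuracy: percentage of estimates within 30\% of the measured value
#'
#' Identical to `proportion_within(mode = "relative", cutoff = 0.30)`.
#'
#' @inheritParams proportion_within
#' @return Percentage in `[0, 100]`.
#' @export
p30 <- function(measured, estimated) {
  proportion_within(measured, estimated, "relative", 0.30)
}

#' Bland--Altman agreement analysis
#'
#' Differences are estimated minus measured; limits of agreement are
#' bias +/- 1.96 SD of the differences (the conventional normal-quantile
#' multiplier, not t-based). The per-record (mean, difference) pairs are
#' returned for plotting.
#'
#' @param measured,estimated Paired numeric vectors, length >= 3.
#' @return Object of class `bland_altman`: list with `bias`, `loa_low`,
#'   `loa_high`, `sd_diff`, and `points` (data.frame mean/diff).
#' @export
bland_altman <- function(measured, estimated) {
  stopifnot(length(measured) == length(estimated), length(measured) >= 3)
  d <- estimated - measured
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, sd_diff = s,
                 points = data.frame(mean = (measured + estimated) / 2,
                                     diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.2f, limits of agreement [%.2f, %.2f] (n = %d)\n",
              x$bias, x$loa_low, x$loa_high, nrow(x$points)))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$points$mean, x$points$diff,
                 xlab = "Mean of measured and estimated (mmol/day)",
                 ylab = "Estimated - measured (mmol/day)", ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2))
  invisible(x)
}

#' Required sample size for detecting a correlation (Fisher-z formula)
#'
#' `n = ((z_{1-alpha/2} + z_{power}) / atanh(r))^2 + 3`, rounded up, then
#' inflated by `1 / (1 - exclusion_rate)` and rounded up again.
#'
#' @param r Assumed correlation in (0, 1).
#' @param alpha Two-sided significance level (0.05).
#' @param power Target power (0.90).
#' @param exclusion_rate Anticipated fraction of excluded specimens (0.10).
#' @return Required number of specimen pairs (integer).
#' @examples
#' sample_size_correlation(0.32) # 110 pairs
#' @export
sample_size_correlation <- function(r, alpha = 0.05, power = 0.90,
                                    exclusion_rate = 0.10) {
  if (!(r > 0 && r < 1)) stop("r must be in (0, 1)", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1,
            exclusion_rate >= 0, exclusion_rate < 1)
  n <- ceiling(((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) /
                  atanh(r))^2 + 3)
  as.integer(ceiling(n / (1 - exclusion_rate)))
}

# metric row for one (analyte, method) series
metrics_row <- function(analyte, method, measured, estimated,
                        ref_est = NULL, abs_cutoff) {
  mb <- mean_bias_ci(measured, estimated)
  r <- stats::cor(measured, estimated)
  r_p <- stats::cor.test(measured, estimated)$p.value
  icc <- icc_a1(measured, estimated)
  cmp_p <- bias_ref_p <- NA_real_
  if (!is.null(ref_est)) {
    cmp <- pearson_with_comparison(measured, estimated, ref_est)
    cmp_p <- cmp$p
    bias_ref_p <- stats::t.test(estimated, ref_est, paired = TRUE)$p.value
  }
  data.frame(analyte = analyte, method = method, n = length(measured),
             mean_est = mean(estimated), sd_est = stats::sd(estimated),
             bias = mb$bias, bias_lo = mb$ci[1], bias_hi = mb$ci[2],
             bias_p = mb$p,
             pearson_r = r, pearson_p = r_p,
             r_vs_ref_p = cmp_p, bias_vs_ref_p = bias_ref_p,
             icc = icc$icc, icc_lo = icc$ci[1], icc_hi = icc$ci[2],
             icc_label = icc$label,
             p30 = p30(measured, estimated),
             stringsAsFactors = FALSE)
}

#' Validate all estimating equations against measured 24 h excretion
#'
#' For each analyte (sodium: new, Kawasaki, INTERSALT, Tanaka; potassium:
#' new, Kawasaki, Tanaka) computes the full agreement suite against the
#' measured values: mean +/- SD of the estimates, mean bias with 95\% CI and
#' paired-t p, Pearson r with its p and a dependent-correlations comparison
#' against the reference method, ICC(A,1) with 95\% CI and reliability
#' label, and P30. Records lacking a method's inputs are dropped pairwise
#' for that method (the per-row `n` is always reported). A companion
#' cutoff table holds the within +/-10\%, +/-30\% relative and the absolute
#' (17.1 mmol/day sodium, 12.8 mmol/day potassium) agreement proportions.
#'
#' @param records Test records in the canonical schema including measured
#'   `u24_na_mmol` and `u24_k_mmol`; estimates are computed internally with
#'   [estimate_all()] unless `est_*` columns are already present.
#' @param methods Methods to evaluate.
#' @param reference Method the r- and bias-comparisons are made against
#'   ("new").
#' @return Object of class `validation_table`: the metric data frame, with
#'   attributes `cutoffs` (long cutoff table) and `bland_altman` (named list
#'   of [bland_altman()] objects per analyte/method).
#' @export
validate_all <- function(records,
                         methods = c("new", "kawasaki", "intersalt", "tanaka"),
                         reference = "new") {
  stopifnot(reference %in% methods)
  if (!any(grepl("^est_", names(records))))
    records <- estimate_all(records, methods = methods)
  rows <- list(); cuts <- list(); ba <- list()
  specs <- list(na = list(measured = "u24_na_mmol", abs_cutoff = 17.1),
                k = list(measured = "u24_k_mmol", abs_cutoff = 12.8))
  for (analyte in names(specs)) {
    meas_col <- specs[[analyte]]$measured
    if (!meas_col %in% names(records))
      stop("records lacks measured column ", meas_col, call. = FALSE)
    for (m in methods) {
      est_col <- paste0("est_", analyte, "_", m)
      if (!est_col %in% names(records)) next  # e.g. no INTERSALT potassium
      ref_col <- paste0("est_", analyte, "_", reference)
      ok <- !is.na(records[[meas_col]]) & !is.na(records[[est_col]])
      has_ref <- ref_col %in% names(records) && m != reference
      if (has_ref) ok <- ok & !is.na(records[[ref_col]])
      meas <- records[[meas_col]][ok]
      est <- records[[est_col]][ok]
      if (length(meas) < 5) next
      ref_est <- if (has_ref) records[[ref_col]][ok] else NULL
      rows[[paste(analyte, m)]] <-
        metrics_row(analyte, m, meas, est, ref_est,
                    specs[[analyte]]$abs_cutoff)
      cuts[[paste(analyte, m)]] <- data.frame(
        analyte = analyte, method = m,
        mode = c("relative", "relative", "absolute"),
        cutoff = c(0.10, 0.30, specs[[analyte]]$abs_cutoff),
        pct = c(proportion_within(meas, est, "relative", c(0.10, 0.30)),
                proportion_within(meas, est, "absolute",
                                  specs[[analyte]]$abs_cutoff)))
      ba[[paste(analyte, m, sep = "_")]] <- bland_altman(meas, est)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("validation_table", "data.frame"),
            cutoffs = do.call(rbind, c(cuts, list(make.row.names = FALSE))),
            bland_altman = ba, reference = reference)
}

#' @export
print.validation_table <- function(x, ...) {
  cat("Agreement of estimated vs measured 24 h excretion",
      sprintf("(reference: %s)\n\n", attr(x, "reference")))
  df <- as.data.frame(unclass(x), stringsAsFactors = FALSE)
  show <- data.frame(
    analyte = toupper(df$analyte), method = df$method, n = df$n,
    `mean+/-SD` = sprintf("%.1f +/- %.1f", df$mean_est, df$sd_est),
    `bias (95% CI)` = sprintf("%.2f (%.2f, %.2f)", df$bias, df$bias_lo,
                              df$bias_hi),
    r = sprintf("%.2f", df$pearson_r),
    `ICC (95% CI)` = sprintf("%.2f (%.2f, %.2f)", df$icc, df$icc_lo,
                             df$icc_hi),
    `P30 (%)` = sprintf("%.1f", df$p30),
    check.names = FALSE)
  print(show, row.names = FALSE)
  invisible(x)
}
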