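#' Paired interocular sample for one metric
#'
#' Holds matched right-eye (OD) and left-eye (OS) values of one metric, with
#' optional per-subject sex labels. Pairs with a missing eye are dropped —
#' subjects without countable cones in both eyes do not enter the symmetry
#' analysis.
#'
#' @param od,os Numeric vectors of per-subject OD and OS values (same
#'   length/order).
#' @param subject Optional subject ids.
#' @param metric Metric label (e.g. `"peak_density"`).
#' @param sex Optional per-subject labels (e.g. `"F"` / `"M"`).
#' @return An object of class `paired_sample`.
#' @export
paired_sample <- function(od, os, subject = NULL, metric = NA_character_,
                          sex = NULL) {
  stopifnot(length(od) == length(os))
  n0 <- length(od)
  if (is.null(subject)) subject <- sprintf("S%03d", seq_len(n0))
  if (!is.null(sex)) stopifnot(length(sex) == n0)
  keep <- is.finite(od) & is.finite(os)
  structure(list(subject = subject[keep], x = as.numeric(od[keep]),
                 y = as.numeric(os[keep]), metric = metric,
                 sex = if (is.null(sex)) NULL else sex[keep],
                 n_dropped = sum(!keep)),
            class = "paired_sample")
}

#' @export
print.paired_sample <- function(x, ...) {
  cat(sprintf("paired_sample [%s]: n = %d pairs (%d dropped)\n", x$metric,
              length(x$x), x$n_dropped))
  invisible(x)
}

as_paired <- function(sample) {
  if (inherits(sample, "paired_sample")) return(sample)
  stop("expected a paired_sample")
}

#' Bland-Altman analysis of paired measurements
#'
#' Mean bias and 95% limits of agreement of the differences `d = OD - OS`,
#' with t-based 95% confidence intervals: limits are `bias +/- 1.96 * SD(d)`,
#' the CI of the bias uses the standard error `SD/sqrt(n)`, and the CI of
#' each limit uses the classic `SD * sqrt(3/n)` standard-error approximation.
#'
#' @param sample A [paired_sample()] (or the `od` vector when `os` given).
#' @param os Optional OS vector when `sample` is a plain OD vector.
#' @return An object of class `bland_altman`: `n`, `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, and 95% CIs `ci_bias`, `ci_loa_low`,
#'   `ci_loa_high`.
#' @export
bland_altman <- function(sample, os = NULL) {
  if (!is.null(os)) sample <- paired_sample(sample, os)
  s <- as_paired(sample)
  d <- s$x - s$y
  n <- length(d)
  if (n < 3L) fm_stop("Bland-Altman needs >= 3 pairs", "insufficient_pairs")
  bias <- mean(d)
  sdd <- sd(d)
  tq <- qt(0.975, n - 1)
  loa <- c(bias - 1.96 * sdd, bias + 1.96 * sdd)
  structure(list(n = n, bias = bias, sd_diff = sdd,
                 loa_low = loa[1], loa_high = loa[2],
                 ci_bias = bias + c(-1, 1) * tq * sdd / sqrt(n),
                 ci_loa_low = loa[1] + c(-1, 1) * tq * sdd * sqrt(3 / n),
                 ci_loa_high = loa[2] + c(-1, 1) * tq * sdd * sqrt(3 / n),
                 metric = s$metric),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 4, ...) {
  f <- function(v) format(v, digits = digits)
  cat(sprintf("Bland-Altman [%s], n = %d\n", x$metric, x$n))
  cat(sprintf("  bias %s (95%% CI %s to %s)\n", f(x$bias), f(x$ci_bias[1]),
              f(x$ci_bias[2])))
  cat(sprintf("  lower limit %s (95%% CI %s to %s)\n", f(x$loa_low),
              f(x$ci_loa_low[1]), f(x$ci_loa_low[2])))
  cat(sprintf("  upper limit %s (95%% CI %s to %s)\n", f(x$loa_high),
              f(x$ci_loa_high[1]), f(x$ci_loa_high[2])))
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' `r_c = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population moments (divisor n), Lin's original convention. Always in
#' `[-1, 1]` and never exceeding |Pearson r|.
#'
#' @inheritParams bland_altman
#' @return The concordance correlation coefficient.
#' @export
concordance_correlation <- function(sample, os = NULL) {
  if (!is.null(os)) sample <- paired_sample(sample, os)
  s <- as_paired(sample)
  x <- s$x; y <- s$y
  n <- length(x)
  if (n < 3L) fm_stop("CCC needs >= 3 pairs", "insufficient_pairs")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  if (vx == 0 && vy == 0) fm_stop("both samples constant", "undefined_ccc")
  2 * cxy / (vx + vy + (mx - my)^2)
}

#' Normality-gated paired symmetry test
#'
#' Shapiro-Wilk on the differences decides the test: paired t when the
#' normality p-value is at least `alpha_normality`, Wilcoxon signed-rank
#' otherwise. Also reports the Pearson R^2 between eyes and Lin's
#' concordance correlation.
#'
#' @inheritParams bland_altman
#' @param alpha_normality Normality gate, default 0.05.
#' @return An object of class `symmetry_test`: `shapiro_p`, `test_used`,
#'   `statistic`, `df` (t path only), `p`, `pearson_r2`, `ccc`, `n`.
#' @export
paired_symmetry_test <- function(sample, os = NULL, alpha_normality = 0.05) {
  if (!is.null(os)) sample <- paired_sample(sample, os)
  s <- as_paired(sample)
  d <- s$x - s$y
  n <- length(d)
  if (n < 3L) fm_stop("paired test needs >= 3 pairs", "insufficient_pairs")
  r2 <- if (sd(s$x) > 0 && sd(s$y) > 0) cor(s$x, s$y)^2 else NA_real_
  ccc <- tryCatch(concordance_correlation(s), error = function(e) NA_real_)
  if (sd(d) == 0) {
    if (all(d == 0)) {
      fm_warn("all differences are zero; degenerate paired t reported",
              "degenerate_differences")
      res <- list(shapiro_p = NA_real_, test_used = "paired-t", statistic = 0,
                  df = n - 1, p = 1)
    } else {
      fm_warn("differences identical; normality undefined, using Wilcoxon",
              "degenerate_differences")
      wt <- suppressWarnings(wilcox.test(d))
      res <- list(shapiro_p = NA_real_, test_used = "wilcoxon",
                  statistic = unname(wt$statistic), df = NA_real_,
                  p = wt$p.value)
    }
  } else {
    sw <- shapiro.test(d)
    if (sw$p.value >= alpha_normality) {
      tt <- t.test(d)
      res <- list(shapiro_p = sw$p.value, test_used = "paired-t",
                  statistic = unname(tt$statistic), df = n - 1,
                  p = tt$p.value)
    } else {
      wt <- suppressWarnings(wilcox.test(d))
      res <- list(shapiro_p = sw$p.value, test_used = "wilcoxon",
                  statistic = unname(wt$statistic), df = NA_real_,
                  p = wt$p.value)
    }
  }
  structure(c(res, list(pearson_r2 = r2, ccc = ccc, n = n,
                        metric = s$metric,
                        mean_od = mean(s$x), sd_od = sd(s$x),
                        mean_os = mean(s$y), sd_os = sd(s$y))),
            class = "symmetry_test")
}

#' @export
print.symmetry_test <- function(x, ...) {
  cat(sprintf("symmetry_test [%s], n = %d\n", x$metric, x$n))
  cat(sprintf("  OD %.5g +/- %.4g, OS %.5g +/- %.4g\n", x$mean_od, x$sd_od,
              x$mean_os, x$sd_os))
  cat(sprintf("  Shapiro-Wilk p = %.3g -> %s: statistic %.4g%s, p = %.3g\n",
              x$shapiro_p, x$test_used, x$statistic,
              if (is.finite(x$df)) sprintf(" (df %g)", x$df) else "", x$p))
  cat(sprintf("  Pearson R^2 = %.3g, concordance r_c = %.3g\n",
              x$pearson_r2, x$ccc))
  invisible(x)
}

#' Coefficient of variation of absolute interocular differences
#'
#' `100 * SD / mean` of the absolute differences between fellow eyes, in
#' percent.
#'
#' @param abs_diffs Positive-mean vector of absolute differences.
#' @return Percent CoV.
#' @export
cov_abs_diff <- function(abs_diffs) {
  v <- abs_diffs[is.finite(abs_diffs)]
  if (length(v) < 2L) fm_stop("CoV needs >= 2 values", "insufficient_pairs")
  m <- mean(v)
  if (m <= 0) fm_stop("CoV undefined for zero mean", "undefined_cov")
  100 * sd(v) / m
}

#' Smallest detectable paired mean difference
#'
#' The smallest true mean difference a two-sided paired t-test at level
#' `alpha` detects with the requested power, given `n` pairs and the SD of
#' the paired differences — the standard noncentral-t power solve
#' ([stats::power.t.test()] with `type = "paired"`). Scales linearly with
#' `sd_diff` and approximately as `1/sqrt(n)`.
#'
#' @param n Number of pairs.
#' @param sd_diff SD of the paired differences (metric units).
#' @param alpha Two-sided significance level, default 0.05.
#' @param power Target power, default 0.80.
#' @return The minimal detectable mean difference, in metric units.
#' @export
detectable_difference <- function(n, sd_diff, alpha = 0.05, power = 0.80) {
  stopifnot(n >= 2, alpha > 0, alpha < 1, power > alpha, power < 1,
            sd_diff > 0)
  power.t.test(n = n, sd = sd_diff, sig.level = alpha, power = power,
               type = "paired", alternative = "two.sided")$delta
}

#' Correlation between peak density and regularity
#'
#' Pearson R^2 and two-sided p-value for the linear association between
#' per-eye peak cone density and the VCAR at that location.
#'
#' @param density,vcar Equal-length numeric vectors.
#' @return List with `r2`, `p`, `n`.
#' @export
density_vcar_correlation <- function(density, vcar) {
  stopifnot(length(density) == length(vcar))
  keep <- is.finite(density) & is.finite(vcar)
  x <- density[keep]; y <- vcar[keep]
  if (length(x) < 3L) fm_stop("correlation needs >= 3 pairs", "insufficient_pairs")
  if (sd(x) == 0 || sd(y) == 0)
    fm_stop("zero variance; correlation undefined", "undefined_correlation")
  ct <- cor.test(x, y)
  list(r2 = unname(ct$estimate)^2, p = ct$p.value, n = length(x))
}

#' Symmetry analysis within subgroups
#'
#' Splits a paired sample by a grouping label (typically sex) and runs
#' [paired_symmetry_test()] within each group; groups with fewer than 3
#' pairs are skipped with a warning.
#'
#' @param sample A [paired_sample()] with a non-null `sex` (or pass `group`).
#' @param group Optional grouping vector overriding `sample$sex`.
#' @param alpha_normality Normality gate passed through.
#' @return Named list of `symmetry_test` results (skipped groups `NULL`).
#' @export
subgroup_analysis <- function(sample, group = NULL, alpha_normality = 0.05) {
  s <- as_paired(sample)
  if (is.null(group)) group <- s$sex
  if (is.null(group)) fm_stop("no grouping labels available", "invalid_parameter")
  stopifnot(length(group) == length(s$x))
  out <- lapply(split(seq_along(s$x), group), function(ix) {
    if (length(ix) < 3L) {
      fm_warn(sprintf("subgroup with n = %d skipped", length(ix)),
              "skipped_group")
      return(NULL)
    }
    paired_symmetry_test(paired_sample(s$x[ix], s$y[ix],
                                       subject = s$subject[ix],
                                       metric = s$metric),
                         alpha_normality = alpha_normality)
  })
  out
}
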