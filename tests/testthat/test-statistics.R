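# construct a vector with exactly the requested mean and sample SD
vec_with_moments <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  z <- (z - mean(z)) / sd(z)
  mean + sd * z
}

test_that("Bland-Altman follows the closed-form prescription", {
  x <- c(10, 12, 9, 14, 11)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)
  expect_equal(ba0$ci_bias, c(0, 0))

  # textbook oracle at 1e-12
  set.seed(5)
  od <- rnorm(25, 100, 10); os <- od + rnorm(25, 2, 3)
  ba <- bland_altman(od, os)
  d <- od - os; n <- 25
  expect_equal(ba$bias, mean(d), tolerance = 1e-12)
  expect_equal(ba$sd_diff, sd(d), tolerance = 1e-12)
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba$ci_bias,
               mean(d) + c(-1, 1) * qt(.975, n - 1) * sd(d) / sqrt(n),
               tolerance = 1e-12)
  expect_equal(ba$ci_loa_low,
               mean(d) - 1.96 * sd(d) +
                 c(-1, 1) * qt(.975, n - 1) * sd(d) * sqrt(3 / n),
               tolerance = 1e-12)

  # translation equivariance
  ba_c <- bland_altman(od + 55, os)
  expect_equal(ba_c$bias, ba$bias + 55, tolerance = 1e-9)
  expect_equal(ba_c$loa_low, ba$loa_low + 55, tolerance = 1e-9)
  expect_error(bland_altman(c(1, 2), c(1, 2)), class = "insufficient_pairs")
})

test_that("the published peak-density agreement numbers are internally consistent", {
  # differences with mean -637 and sample SD 7941 over 43 pairs reproduce the
  # published limits (-16,201 / 14,927) and bias CI (-3083, 1809) to rounding
  d <- vec_with_moments(43, -637, 7941, seed = 11)
  ba <- bland_altman(paired_sample(d, rep(0, 43), metric = "peak_density"))
  expect_lt(abs(ba$loa_low - (-16201)), 1)
  expect_lt(abs(ba$loa_high - 14927), 1)
  expect_lt(abs(ba$ci_bias[1] - (-3083)), 3)
  expect_lt(abs(ba$ci_bias[2] - 1809), 3)
  # and the back-solved sd from those limits returns the same bias CI
  sd_back <- (ba$loa_high - ba$loa_low) / (2 * 1.96)
  expect_equal(sd_back, 7941, tolerance = 1e-9)
})

test_that("concordance correlation matches Lin's population-moment formula", {
  x <- c(1, 2, 3, 4)
  expect_equal(concordance_correlation(x, x), 1, tolerance = 1e-12)
  xc <- c(-2, -1, 1, 2)
  expect_equal(concordance_correlation(xc, -xc), -1, tolerance = 1e-12)

  y <- c(1.1, 2.1, 2.9, 4.2)
  mx <- mean(x); my <- mean(y)
  sxy <- mean((x - mx) * (y - my))
  oracle <- 2 * sxy / (mean((x - mx)^2) + mean((y - my)^2) + (mx - my)^2)
  expect_equal(concordance_correlation(x, y), oracle, tolerance = 1e-12)

  # CCC never exceeds |Pearson r|
  set.seed(8)
  for (k in 1:20) {
    a <- rnorm(15); b <- 2 * rnorm(15) + 0.5 * a + 1
    expect_lte(abs(concordance_correlation(a, b)), abs(cor(a, b)) + 1e-12)
  }
  expect_error(concordance_correlation(rep(1, 5), rep(2, 5)),
               class = "undefined_ccc")
})

test_that("the normality gate selects the paired t or Wilcoxon path", {
  set.seed(13)
  od <- rnorm(30, 100, 5); os <- od + rnorm(30, 0, 2)
  r <- paired_symmetry_test(od, os)
  expect_identical(r$test_used, "paired-t")
  expect_identical(r$df, 29)

  expect_warning(r0 <- paired_symmetry_test(od, od),
                 class = "degenerate_differences")
  expect_equal(r0$p, 1)
  expect_equal(r0$statistic, 0)

  # heavy-tailed differences push the gate to Wilcoxon in most replicates
  set.seed(17)
  nw <- 0
  for (k in 1:100) {
    d <- rt(40, df = 2) * 5
    r <- suppressWarnings(paired_symmetry_test(d + 50, rep(50, 40)))
    nw <- nw + (r$test_used == "wilcoxon")
  }
  expect_gt(nw, 50)

  # invariance to subject-order relabeling
  perm <- sample(30)
  r2 <- paired_symmetry_test(od[perm], os[perm])
  r1 <- paired_symmetry_test(od, os)
  expect_equal(r2$p, r1$p, tolerance = 1e-12)
  expect_equal(r2$ccc, r1$ccc, tolerance = 1e-12)
})

test_that("the paired-t path holds its nominal type-I error", {
  set.seed(29)
  n <- 43; reps <- 1000
  d <- matrix(rnorm(n * reps), n, reps)
  tstat <- sqrt(n) * colMeans(d) / apply(d, 2, sd)
  reject <- mean(abs(tstat) > qt(0.975, n - 1))
  expect_lt(abs(reject - 0.05), 0.015)
})

test_that("coefficient of variation of absolute differences", {
  expect_equal(cov_abs_diff(rep(4, 10)), 0)
  v <- vec_with_moments(43, 6363, 4692, seed = 3)
  expect_lt(abs(cov_abs_diff(v) - 73.7), 0.1)
  expect_equal(round(cov_abs_diff(v)), 74)
  expect_equal(cov_abs_diff(7 * v), cov_abs_diff(v), tolerance = 1e-12)
  expect_error(cov_abs_diff(c(-1, 1)), class = "undefined_cov")
})

test_that("smallest detectable difference solves the paired-t power relation", {
  dd <- detectable_difference(43, sd_diff = 7941)
  # structure: linear in sd, ~1/sqrt(n)
  expect_equal(detectable_difference(43, sd_diff = 2 * 7941), 2 * dd,
               tolerance = 1e-9)
  expect_lt(detectable_difference(172, sd_diff = 7941), dd / 1.9)
  expect_gt(detectable_difference(172, sd_diff = 7941), dd / 2.1)
  # power -> alpha limit drives the detectable difference toward zero
  # (delta ~ sqrt(power - alpha) near the limit)
  expect_lt(detectable_difference(43, sd_diff = 7941, power = 0.051), dd / 8)
  expect_lt(detectable_difference(43, sd_diff = 7941, power = 0.0501),
            detectable_difference(43, sd_diff = 7941, power = 0.051))

  # Monte-Carlo cross-check: the solved delta attains ~80% power
  set.seed(41)
  n <- 43; reps <- 10000
  d <- matrix(rnorm(n * reps, mean = dd, sd = 7941), n, reps)
  tstat <- sqrt(n) * colMeans(d) / apply(d, 2, sd)
  power_mc <- mean(abs(tstat) > qt(0.975, n - 1))
  expect_lt(abs(power_mc - 0.80) / 0.80, 0.02)
})

test_that("density-regularity correlation and its null behaviour", {
  x <- c(1, 3, 4, 7, 9, 11)
  r <- density_vcar_correlation(x, 2 * x + 1)
  expect_equal(r$r2, 1, tolerance = 1e-12)
  expect_error(density_vcar_correlation(rep(1, 6), x),
               class = "undefined_correlation")
  # E[R^2] under independence is ~ 1/(n-1)
  set.seed(19)
  n <- 51
  r2s <- replicate(1000, cor(rnorm(n), rnorm(n))^2)
  expect_lt(abs(mean(r2s) - 1 / (n - 1)), 0.006)
})

test_that("sex-subgroup analysis tests each group and skips tiny ones", {
  set.seed(23)
  od <- rnorm(44, 100, 10); os <- od + rnorm(44, 0, 3)
  sex <- rep(c("F", "M"), each = 22)
  ps <- paired_sample(od, os, metric = "peak_density", sex = sex)
  by <- subgroup_analysis(ps)
  expect_named(by, c("F", "M"))
  expect_true(all(sapply(by, function(g) g$n) == 22))

  # a one-SD injected bias in one group is detected with good power
  set.seed(31)
  hits <- 0
  for (k in 1:60) {
    odk <- rnorm(44, 100, 10)
    osk <- odk + rnorm(44, 0, 3)
    osk[sex == "F"] <- osk[sex == "F"] - 3   # delta = 1 SD of differences
    byk <- suppressWarnings(
      subgroup_analysis(paired_sample(odk, osk, sex = sex)))
    hits <- hits + (byk$F$p < 0.05)
  }
  expect_gte(hits / 60, 0.8)

  tiny <- paired_sample(od[1:5], os[1:5], sex = c("F", "F", "F", "M", "M"))
  expect_warning(by2 <- subgroup_analysis(tiny), class = "skipped_group")
  expect_null(by2$M)
  expect_false(is.null(by2$F))
})
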