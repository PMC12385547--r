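test_that("paired t-test matches the textbook formula on random fixtures", {
  set.seed(101)
  for (i in 1:10) {
    x1 <- rnorm(16, 0.6, 0.03); x2 <- x1 + rnorm(16, 0, 0.02)
    res <- paired_ttest(x1, x2)
    d <- x1 - x2
    t_bf <- mean(d) / (sd(d) / sqrt(16))
    expect_equal(res$t, t_bf, tolerance = 1e-10)
    expect_equal(res$df, 15)
    expect_equal(res$p, 2 * pt(-abs(t_bf), 15), tolerance = 1e-10)
  }
  # identical pairs
  res0 <- paired_ttest(rep(1, 5), rep(1, 5))
  expect_equal(res0$t, 0); expect_equal(res0$p, 1)
  # constructed sample with D = sd_diff / sqrt(n) gives t = 1
  d <- c(1, 2, 3, 4)                 # sd = 1.290994, mean 2.5; scale to match
  x2 <- rep(0, 4); x1 <- d - mean(d) + sd(d) / sqrt(4)
  expect_equal(paired_ttest(x1, x2)$t, 1, tolerance = 1e-12)
  # degenerate: constant non-zero difference
  dres <- paired_ttest(c(1, 2, 3), c(0, 1, 2))
  expect_true(dres$degenerate)
})

test_that("Cohen's d uses the paired definition and the printed bands", {
  set.seed(5)
  x1 <- rnorm(16); x2 <- x1 + rnorm(16, 0.01, 0.05)
  cd <- cohens_d(x1, x2)
  expect_equal(cd$d, mean(x1 - x2) / sd(x1 - x2), tolerance = 1e-12)
  mk <- function(target) {
    # build a 4-pair sample with d exactly `target`
    diffs <- c(-1, 0, 0, 1)                   # sd = sqrt(2/3)
    diffs <- diffs + target * sd(diffs)
    cohens_d(diffs, rep(0, 4))
  }
  expect_equal(mk(0.5)$band, "medium")
  expect_equal(mk(0.25)$band, "small")
  expect_equal(mk(0.85)$band, "large")
  expect_equal(cohens_d(rep(2, 4), rep(2, 4))$band, "negligible")
  expect_equal(cohens_d(c(1, 2, 3), c(0, 1, 2))$band, "undefined")
})

test_that("t-based confidence intervals reproduce the printed worked example", {
  # printed summary cell: mean 0.603, SD 0.023, n = 16 -> CI (0.591, 0.615)
  ci <- mean_ci(0.603, sd = 0.023, n = 16)
  expect_equal(round_half_away(ci$ci, 3), c(0.591, 0.615))
  # raw-data path agrees with the summary path
  set.seed(33)
  x <- rnorm(16, 0.6, 0.02)
  ci2 <- mean_ci(x)
  ci3 <- mean_ci(mean(x), sd = sd(x), n = 16)
  expect_equal(ci2$ci, ci3$ci)
  # sd = 0 collapses to the mean
  expect_equal(mean_ci(rep(4, 5))$ci, c(4, 4))
  # width scales as 1 / sqrt(n)
  set.seed(34)
  w <- vapply(c(20, 80), function(n) {
    y <- rnorm(n, sd = 1)
    diff(mean_ci(0, sd = 1, n = n)$ci)
  }, numeric(1))
  expect_equal(w[1] / w[2], sqrt(80 / 20), tolerance = 0.1)
  expect_error(mean_ci(3), "n >= 2")
})

test_that("Bland-Altman analysis matches brute force and printed rows", {
  set.seed(55)
  x1 <- rnorm(16, 0.5, 0.05); x2 <- rnorm(16, 0.5, 0.05)
  ba <- bland_altman(x1, x2)
  d <- x1 - x2
  expect_equal(ba$D, mean(d), tolerance = 1e-12)
  expect_equal(ba$sd_diff, sd(d), tolerance = 1e-12)
  expect_equal(ba$loa_lower, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba$loa_upper, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba$ci_D,
               mean(d) + c(-1, 1) * qt(0.975, 15) * sd(d) / 4, tolerance = 1e-12)
  expect_equal(ba$n_outside, sum(abs(d - mean(d)) > 1.96 * sd(d)))
  expect_true(ba$loa_lower <= ba$D && ba$D <= ba$loa_upper)
  expect_true(diff(ba$ci_D) < ba$loa_upper - ba$loa_lower)
  # identical pairs collapse
  ba0 <- bland_altman(1:5, 1:5)
  expect_equal(c(ba0$D, ba0$loa_lower, ba0$loa_upper, ba0$n_outside),
               c(0, 0, 0, 0))
  # printed worked examples: (D, SD) -> LOA at report rounding
  expect_equal(round_half_away(-0.003 + c(-1, 1) * 1.96 * 0.023, 3),
               c(-0.048, 0.042))
  expect_equal(round_half_away(0.005 + c(-1, 1) * 1.96 * 0.074, 3),
               c(-0.140, 0.150))
})

test_that("within-participant CV matches its two-value brute force and bands", {
  set.seed(66)
  x1 <- runif(16, 0.4, 0.8); x2 <- runif(16, 0.4, 0.8)
  cv <- within_cv(x1, x2)
  # brute force: per-participant two-value SD over the two-value mean
  cv_bf <- vapply(seq_along(x1), function(i)
    100 * sd(c(x1[i], x2[i])) / mean(c(x1[i], x2[i])), numeric(1))
  expect_equal(cv$cv_i, cv_bf, tolerance = 1e-10)
  expect_equal(cv$cv, mean(cv_bf), tolerance = 1e-10)
  expect_equal(within_cv(x1, x2, aggregate = "rms")$cv,
               sqrt(mean(cv_bf^2)), tolerance = 1e-10)
  # identical pairs give zero CV
  expect_equal(within_cv(x1, x1)$cv, 0)
  # formula inversion: construct a single pair with CV exactly 10%
  m <- 10; target <- 10
  delta <- target / 100 * m * sqrt(2)   # |d| = CV/100 * mean * sqrt(2)
  pair1 <- m + delta / 2; pair2 <- m - delta / 2
  cvb <- within_cv(c(pair1, pair1), c(pair2, pair2))
  expect_equal(cvb$cv, 10, tolerance = 1e-10)
  expect_equal(cvb$band, "acceptable")    # boundary closed at 10
  expect_equal(within_cv(c(11, 11), c(9, 9))$band, "moderate")
  expect_equal(within_cv(c(20, 20), c(5, 5))$band, "high")
  expect_warning(within_cv(c(1, -2), c(1, -2)), "excluded")
})

test_that("ICC forms match brute-force ANOVA mean squares exactly", {
  set.seed(77)
  for (i in 1:5) {
    m <- cbind(rnorm(16, 10, 2), rnorm(16, 10.5, 2))
    ms <- brute_force_ms(m)
    res <- icc(m)
    expect_equal(res$ms$MSR, ms$MSR, tolerance = 1e-10)
    expect_equal(res$ms$MSC, ms$MSC, tolerance = 1e-10)
    expect_equal(res$ms$MSE, ms$MSE, tolerance = 1e-10)
    k <- 2; n <- 16
    expect_equal(res$consistency$single$est,
                 (ms$MSR - ms$MSE) / (ms$MSR + (k - 1) * ms$MSE),
                 tolerance = 1e-10)
    expect_equal(res$consistency$average$est,
                 (ms$MSR - ms$MSE) / ms$MSR, tolerance = 1e-10)
    expect_equal(res$agreement$single$est,
                 (ms$MSR - ms$MSE) /
                   (ms$MSR + (k - 1) * ms$MSE + k / n * (ms$MSC - ms$MSE)),
                 tolerance = 1e-10)
    expect_equal(res$agreement$average$est,
                 (ms$MSR - ms$MSE) / (ms$MSR + (ms$MSC - ms$MSE) / n),
                 tolerance = 1e-10)
    # average >= single when positive
    if (res$agreement$single$est > 0)
      expect_gte(res$agreement$average$est, res$agreement$single$est)
  }
})

test_that("ICC behaves definitionally under offsets and perfect agreement", {
  x <- rnorm(20, 5, 1)
  r1 <- icc(x, x)
  expect_equal(r1$consistency$single$est, 1)
  # constant offset: consistency stays 1, absolute agreement drops
  r2 <- icc(x, x + 0.5)
  expect_equal(r2$consistency$single$est, 1)
  expect_lt(r2$agreement$single$est, 1)
  # zero between-participant variance: estimate may be <= 0 but is reported
  set.seed(88)
  r3 <- icc(rnorm(12, 0, 1), rnorm(12, 0, 1))
  expect_true(is.finite(r3$consistency$single$est))
  expect_true(all(is.finite(r3$consistency$single$ci)))
})

test_that("ICC estimator recovers a constructed true value with calibrated CIs", {
  # true single ICC 0.75: sd_b = 0.03, sd_w = 0.03 / sqrt(3)
  sd_b <- 0.03; sd_w <- 0.03 / sqrt(3)
  n <- 16; reps <- 500
  est <- cov_c <- numeric(reps)
  set.seed(2024)
  for (r in seq_len(reps)) {
    p <- rnorm(n, 0, sd_b)
    m <- cbind(0.6 + p + rnorm(n, 0, sd_w), 0.6 + p + rnorm(n, 0, sd_w))
    res <- icc(m)
    est[r] <- res$consistency$single$est
    ci <- res$consistency$single$ci
    cov_c[r] <- ci[1] <= 0.75 && 0.75 <= ci[2]
  }
  expect_lt(abs(median(est) - 0.75), 0.05)
  expect_gte(mean(cov_c), 0.92)
  expect_lte(mean(cov_c), 0.98)
})

test_that("ICC classification follows the two published conventions", {
  cl <- classify_icc(0.65)
  expect_equal(cl$cicchetti, "good")
  expect_equal(cl$koo, "moderate")
  expect_equal(classify_icc(0.95)$cicchetti, "excellent")
  expect_equal(classify_icc(0.95)$koo, "excellent")
  expect_equal(classify_icc(0.10)$cicchetti, "poor")
  expect_equal(classify_icc(0.10)$koo, "poor")
  expect_equal(classify_icc(0.45)$cicchetti, "moderate")
  expect_equal(classify_icc(0.80)$koo, "good")
})

test_that("the reliability table mirrors the published layout", {
  co <- cohort_spec(n_participants = 16, seed = 19)
  tidy <- simulate_cohort(co)$truth
  tab <- build_reliability_table(tidy)
  # 3 comparisons x 4 metrics x 3 regions
  expect_equal(nrow(tab), 36)
  expect_setequal(unique(tab$comparison),
                  c("ScannerA_test_retest", "ScannerB_test_retest",
                    "ScannerA_vs_ScannerB_pooled"))
  # pooled mean column equals (test mean + retest mean) / 2 exactly
  expect_equal(tab$pooled_mean, (tab$test_mean + tab$retest_mean) / 2,
               tolerance = 1e-12)
  # LOA bracket D; CI of D narrower than LOA
  expect_true(all(tab$loa_lower <= tab$ba_D & tab$ba_D <= tab$loa_upper))
  expect_true(all(tab$ba_ci_hi - tab$ba_ci_lo <
                    tab$loa_upper - tab$loa_lower))
  # adjusted p present and >= raw p
  expect_true(all(tab$p_adjusted >= tab$p - 1e-15))
  # rounded report output carries 3-decimal cells
  r <- round_reliability_table(tab)
  expect_true(all(abs(r$ba_D * 1000 - round(r$ba_D * 1000)) < 1e-9))
})

test_that("cohorts with no session or scanner effects yield honest nulls", {
  co <- cohort_spec(n_participants = 16, seed = 23,
                    between_participant_sd = list(FA = 0.03),
                    between_session_sd = list(FA = 0.01))
  tidy <- simulate_cohort(co)$truth
  tab <- build_reliability_table(tidy, icc_form = "consistency")
  fa <- tab[tab$metric == "FA", ]
  # no systematic effect was simulated: most raw p should be unremarkable
  expect_gte(mean(fa$p > 0.05), 0.5)
  # ICC near its construction value 0.9 = 0.03^2 / (0.03^2 + 0.01^2)
  expect_equal(mean(fa$icc_single), 0.9, tolerance = 0.1)
})

test_that("incomplete designs are skipped with a warning", {
  co <- cohort_spec(n_participants = 4, seed = 3)
  tidy <- simulate_cohort(co)$truth
  drop <- !(tidy$participant == "P01" & tidy$session == 2 &
              tidy$scanner == "ScannerA" & tidy$metric == "FA" &
              tidy$region == "PT")
  expect_warning(tab <- build_reliability_table(tidy[drop, ]), "skipped")
  expect_equal(nrow(tab), 35)
})
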