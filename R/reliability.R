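# Test-retest / inter-scanner reliability battery: paired t-tests, Cohen's
# d with effect-size bands, Bland-Altman analysis, within-participant
# coefficients of variation, and single/average intraclass correlation
# coefficients (two-way ANOVA, consistency and absolute-agreement forms)
# with F-based 95% confidence intervals and Cicchetti/Koo classification.

#' Paired sample of test-retest measurements
#'
#' @param x1,x2 paired measurements (visit 1, visit 2), equal length >= 2,
#'   no missing values.
#' @param id optional participant identifiers.
#' @return A list of class `paired_sample`.
#' @export
paired_sample <- function(x1, x2, id = seq_along(x1)) {
  if (length(x1) != length(x2)) stopf("x1 and x2 must have equal length")
  if (length(x1) < 2) stopf("need at least 2 pairs")
  if (anyNA(x1) || anyNA(x2)) stopf("missing pairs are not allowed")
  structure(list(id = id, x1 = x1, x2 = x2, n = length(x1)),
            class = "paired_sample")
}

as_paired <- function(sample, x2 = NULL) {
  if (inherits(sample, "paired_sample")) return(sample)
  paired_sample(sample, x2)
}

#' Paired-samples t-test
#'
#' Two-sided test of zero mean difference, df = n - 1.  A zero-variance
#' difference yields p = 1 when the mean difference is 0 and a degenerate
#' flag otherwise.
#'
#' @param sample a [paired_sample()] (or `x1` with `x2` supplied).
#' @param x2 second visit when `sample` is a plain vector.
#' @return List with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_ttest <- function(sample, x2 = NULL) {
  s <- as_paired(sample, x2)
  d <- s$x1 - s$x2
  if (stats::sd(d) == 0) {
    return(list(t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                df = s$n - 1, p = if (mean(d) == 0) 1 else 0,
                mean_diff = mean(d), degenerate = mean(d) != 0))
  }
  tt <- stats::t.test(s$x1, s$x2, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d), degenerate = FALSE)
}

#' Paired Cohen's d with effect-size band
#'
#' `d = mean(diff) / sd(diff)`; bands: negligible < 0.20,
#' small 0.20-0.49, medium 0.50-0.79, large >= 0.80.
#'
#' @inheritParams paired_ttest
#' @return List with `d` and `band` (`NA`/"undefined" at zero variance).
#' @export
cohens_d <- function(sample, x2 = NULL) {
  s <- as_paired(sample, x2)
  d <- s$x1 - s$x2
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (mean(d) == 0) return(list(d = 0, band = "negligible"))
    return(list(d = NA_real_, band = "undefined"))
  }
  dd <- mean(d) / sdd
  band <- if (abs(dd) < 0.20) "negligible"
  else if (abs(dd) < 0.50) "small"
  else if (abs(dd) < 0.80) "medium"
  else "large"
  list(d = dd, band = band)
}

#' Mean with SD and t-based confidence interval
#'
#' `mean +/- t(1 - alpha/2, n - 1) * sd / sqrt(n)`.
#'
#' @param values numeric vector, n >= 2.
#' @param level confidence level (default 0.95).
#' @param sd,n optional printed summary inputs: when given together with a
#'   scalar `values` (the printed mean), the CI is computed from the
#'   summary values instead of raw data.
#' @return List with `mean`, `sd`, `ci` (length-2 vector).
#' @export
mean_ci <- function(values, level = 0.95, sd = NULL, n = NULL) {
  if (!is.null(sd)) {
    m <- values
    stopifnot(length(m) == 1, !is.null(n))
  } else {
    if (length(values) < 2) stopf("need n >= 2 values")
    m <- mean(values); sd <- stats::sd(values); n <- length(values)
  }
  half <- stats::qt(1 - (1 - level) / 2, n - 1) * sd / sqrt(n)
  list(mean = m, sd = sd, ci = c(m - half, m + half))
}

#' Bland-Altman analysis of paired measurements
#'
#' Mean difference `D = mean(x1 - x2)`, limits of agreement
#' `D +/- 1.96 * sd(diff)`, t-based 95% CI of D, and the count of pairs
#' outside the limits.
#'
#' @inheritParams paired_ttest
#' @param loa_multiplier multiplier of the SD of differences for the
#'   limits of agreement (default 1.96).
#' @param level confidence level of the CI of the mean difference.
#' @return List of class `ba_result`: `D`, `sd_diff`, `ci_D`,
#'   `loa_lower`, `loa_upper`, `n_outside`.
#' @export
bland_altman <- function(sample, x2 = NULL, loa_multiplier = 1.96,
                         level = 0.95) {
  s <- as_paired(sample, x2)
  d <- s$x1 - s$x2
  D <- mean(d); sdd <- stats::sd(d)
  half <- stats::qt(1 - (1 - level) / 2, s$n - 1) * sdd / sqrt(s$n)
  structure(list(D = D, sd_diff = sdd, ci_D = c(D - half, D + half),
                 loa_lower = D - loa_multiplier * sdd,
                 loa_upper = D + loa_multiplier * sdd,
                 n_outside = sum(abs(d - D) > loa_multiplier * sdd)),
            class = "ba_result")
}

#' Within-participant coefficient of variation
#'
#' Per participant, `CV_i = (|x1_i - x2_i| / sqrt(2)) /
#' ((x1_i + x2_i) / 2) * 100` (the two-value within-participant SD over
#' the within-participant mean); the group CV aggregates per-participant
#' CVs by arithmetic mean (default) or root-mean-square.  Bands:
#' <= 10% acceptable, 10-20% moderate, > 20% high.
#'
#' @inheritParams paired_ttest
#' @param aggregate `"mean"` or `"rms"`.
#' @return List of class `cv_result`: `cv_i` (per participant, %),
#'   `cv` (group, %), `band`, `aggregate`, `n_excluded`.
#' @export
within_cv <- function(sample, x2 = NULL, aggregate = c("mean", "rms")) {
  aggregate <- match.arg(aggregate)
  s <- as_paired(sample, x2)
  m_i <- (s$x1 + s$x2) / 2
  keep <- m_i > 0
  if (any(!keep)) warnf("%d participant(s) with non-positive mean excluded",
                        sum(!keep))
  sd_i <- abs(s$x1 - s$x2) / sqrt(2)
  cv_i <- 100 * sd_i[keep] / m_i[keep]
  cv <- if (aggregate == "mean") mean(cv_i) else sqrt(mean(cv_i^2))
  eps <- 1e-9   # boundary cases land on the lower band
  band <- if (cv <= 10 + eps) "acceptable"
  else if (cv <= 20 + eps) "moderate" else "high"
  structure(list(cv_i = cv_i, cv = cv, band = band, aggregate = aggregate,
                 n_excluded = sum(!keep)), class = "cv_result")
}

# two-way ANOVA mean squares for an n x k matrix (rows = participants,
# columns = conditions/sessions), via stats::aov
anova_mean_squares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(value = as.vector(m),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(value ~ subject + rater, data = df))[[1]]
  list(MSR = tab["subject", "Mean Sq"], MSC = tab["rater", "Mean Sq"],
       MSE = tab["Residuals", "Mean Sq"], n = n, k = k)
}

#' Intraclass correlation coefficients with confidence intervals
#'
#' Two-way ANOVA ICC for k repeated measurements on n participants.
#' Consistency forms: single `(MSR - MSE) / (MSR + (k-1) MSE)`, average
#' `(MSR - MSE) / MSR`.  Absolute-agreement forms additionally penalize
#' the condition (session/scanner) effect:
#' single `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`, average
#' `(MSR - MSE) / (MSR + (MSC - MSE)/n)`.  95% CIs use the exact
#' F-distribution construction for the consistency forms and the
#' Satterthwaite approximation (McGraw-Wong) for absolute agreement.
#'
#' @param sample a [paired_sample()], a plain vector with `x2`, or an
#'   `n x k` matrix.
#' @param x2 second condition when `sample` is a vector.
#' @param level confidence level (default 0.95).
#' @return List of class `icc_result`: for each of `consistency` and
#'   `agreement`, `single` and `average` estimates with `ci`; plus the
#'   ANOVA mean squares.
#' @export
icc <- function(sample, x2 = NULL, level = 0.95) {
  m <- if (is.matrix(sample)) sample else {
    s <- as_paired(sample, x2)
    cbind(s$x1, s$x2)
  }
  ms <- anova_mean_squares(m)
  n <- ms$n; k <- ms$k
  alpha <- 1 - level
  MSR <- ms$MSR; MSC <- ms$MSC; MSE <- ms$MSE

  # consistency: exact F interval
  Fobs <- MSR / MSE
  FL <- Fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
  FU <- Fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
  c_single <- (MSR - MSE) / (MSR + (k - 1) * MSE)
  c_single_ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
  c_avg <- (MSR - MSE) / MSR
  c_avg_ci <- c(1 - 1 / FL, 1 - 1 / FU)

  # absolute agreement: Satterthwaite df for the MSC/MSE mixture
  a_single <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  aa <- (k * a_single) / (n * (1 - a_single))
  bb <- 1 + (k * a_single * (n - 1)) / (n * (1 - a_single))
  v <- (aa * MSC + bb * MSE)^2 /
    ((aa * MSC)^2 / (k - 1) + (bb * MSE)^2 / ((n - 1) * (k - 1)))
  if (is.finite(v) && v > 0) {
    Fs <- stats::qf(1 - alpha / 2, n - 1, v)
    lower <- n * (MSR - Fs * MSE) /
      (Fs * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    Fs2 <- stats::qf(1 - alpha / 2, v, n - 1)
    upper <- n * (Fs2 * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * Fs2 * MSR)
    a_single_ci <- c(lower, upper)
  } else a_single_ci <- c(NA_real_, NA_real_)   # degenerate design (tiny n)
  sb <- function(x) k * x / (1 + (k - 1) * x)   # Spearman-Brown step-up
  a_avg <- (MSR - MSE) / (MSR + (MSC - MSE) / n)
  a_avg_ci <- sb(a_single_ci)

  structure(list(
    consistency = list(single = list(est = c_single, ci = c_single_ci),
                       average = list(est = c_avg, ci = c_avg_ci)),
    agreement = list(single = list(est = a_single, ci = a_single_ci),
                     average = list(est = a_avg, ci = a_avg_ci)),
    ms = ms), class = "icc_result")
}

#' Classify an ICC value under the Cicchetti and Koo conventions
#'
#' Cicchetti: < 0.40 poor, 0.40-0.59 moderate, 0.60-0.74 good,
#' 0.75-1.00 excellent.  Koo: < 0.50 poor, 0.50-0.75 moderate,
#' 0.75-0.90 good, > 0.90 excellent.
#'
#' @param value ICC estimate (or CI endpoint) in `[-1, 1]`.
#' @return List with `cicchetti` and `koo` band labels.
#' @export
classify_icc <- function(value) {
  if (!is.finite(value))
    return(list(cicchetti = NA_character_, koo = NA_character_))
  stopifnot(value >= -1, value <= 1)
  cic <- if (value < 0.40) "poor" else if (value < 0.60) "moderate"
  else if (value < 0.75) "good" else "excellent"
  koo <- if (value < 0.50) "poor" else if (value < 0.75) "moderate"
  else if (value <= 0.90) "good" else "excellent"
  list(cicchetti = cic, koo = koo)
}

#' Build the full reliability table from tidy tract metrics
#'
#' Input is the tidy output of the ROI stage: one row per participant x
#' scanner x session x region x metric.  For every scanner a test-retest
#' comparison (session 1 vs session 2) is built, plus an inter-scanner
#' comparison of the per-participant session means (pooled values) when
#' two scanners are present.  Each row carries test/retest/pooled mean,
#' SD and 95% CI, the paired t-test p-value, Cohen's d with band,
#' Bland-Altman results, the within-participant CV with band, and single
#' and average ICCs with CIs under the configured form.
#'
#' @param tidy data frame with columns `participant`, `scanner`,
#'   `session`, `region`, `metric`, `value`.
#' @param icc_form `"agreement"` (default) or `"consistency"`.
#' @param cv_aggregate passed to [within_cv()].
#' @param p_adjust multiple-testing correction across the metric x region
#'   tests of each comparison (`"bonferroni"` or `"none"`); the raw p is
#'   always reported.
#' @return Data frame of class `reliability_table`, one row per
#'   comparison x metric x region.
#' @export
build_reliability_table <- function(tidy, icc_form = c("agreement", "consistency"),
                                    cv_aggregate = "mean",
                                    p_adjust = c("bonferroni", "none")) {
  icc_form <- match.arg(icc_form)
  p_adjust <- match.arg(p_adjust)
  need <- c("participant", "scanner", "session", "region", "metric", "value")
  if (!all(need %in% names(tidy)))
    stopf("tidy input must have columns %s", paste(need, collapse = ", "))
  scanners <- sort(unique(tidy$scanner))
  comparisons <- lapply(scanners, function(sc) {
    sub <- tidy[tidy$scanner == sc, ]
    sessions <- sort(unique(sub$session))
    if (length(sessions) < 2) return(NULL)
    list(name = sprintf("%s_test_retest", sc),
         split = function(rg, mt) {
           a <- sub[sub$region == rg & sub$metric == mt, ]
           w1 <- a[a$session == sessions[1], ]
           w2 <- a[a$session == sessions[2], ]
           w2 <- w2[match(w1$participant, w2$participant), ]
           list(id = w1$participant, x1 = w1$value, x2 = w2$value)
         })
  })
  if (length(scanners) == 2) {
    pooled <- stats::aggregate(value ~ participant + scanner + region + metric,
                               tidy, mean)
    comparisons <- c(comparisons, list(list(
      name = sprintf("%s_vs_%s_pooled", scanners[1], scanners[2]),
      split = function(rg, mt) {
        a <- pooled[pooled$region == rg & pooled$metric == mt, ]
        w1 <- a[a$scanner == scanners[1], ]
        w2 <- a[a$scanner == scanners[2], ]
        w2 <- w2[match(w1$participant, w2$participant), ]
        list(id = w1$participant, x1 = w1$value, x2 = w2$value)
      })))
  }
  comparisons <- Filter(Negate(is.null), comparisons)
  rows <- list()
  for (cmp in comparisons) {
    for (mt in sort(unique(tidy$metric))) {
      for (rg in sort(unique(tidy$region))) {
        pr <- cmp$split(rg, mt)
        if (anyNA(pr$x1) || anyNA(pr$x2) || length(pr$x1) < 2) {
          warnf("incomplete pairs for %s / %s / %s; row skipped",
                cmp$name, mt, rg)
          next
        }
        s <- paired_sample(pr$x1, pr$x2, pr$id)
        tt <- paired_ttest(s); cd <- cohens_d(s); ba <- bland_altman(s)
        cv <- within_cv(s, aggregate = cv_aggregate)
        ic <- icc(s)[[icc_form]]
        m1 <- mean_ci(s$x1); m2 <- mean_ci(s$x2)
        mp <- mean_ci((s$x1 + s$x2) / 2)
        clamp1 <- function(x) if (is.finite(x)) max(min(x, 1), -1) else x
        cls_s <- classify_icc(clamp1(ic$single$est))
        cls_a <- classify_icc(clamp1(ic$average$est))
        rows[[length(rows) + 1]] <- data.frame(
          comparison = cmp$name, metric = mt, region = rg, n = s$n,
          test_mean = m1$mean, test_sd = m1$sd,
          test_ci_lo = m1$ci[1], test_ci_hi = m1$ci[2],
          retest_mean = m2$mean, retest_sd = m2$sd,
          retest_ci_lo = m2$ci[1], retest_ci_hi = m2$ci[2],
          pooled_mean = mp$mean, pooled_sd = mp$sd,
          pooled_ci_lo = mp$ci[1], pooled_ci_hi = mp$ci[2],
          t = tt$t, p = tt$p, cohens_d = cd$d, d_band = cd$band,
          ba_D = ba$D, ba_sd = ba$sd_diff,
          ba_ci_lo = ba$ci_D[1], ba_ci_hi = ba$ci_D[2],
          loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
          ba_n_outside = ba$n_outside,
          cv = cv$cv, cv_band = cv$band,
          icc_single = ic$single$est,
          icc_single_lo = ic$single$ci[1], icc_single_hi = ic$single$ci[2],
          icc_average = ic$average$est,
          icc_average_lo = ic$average$ci[1], icc_average_hi = ic$average$ci[2],
          icc_single_cicchetti = cls_s$cicchetti, icc_single_koo = cls_s$koo,
          icc_average_cicchetti = cls_a$cicchetti, icc_average_koo = cls_a$koo,
          icc_form = icc_form)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust != "none" && !is.null(out)) {
    out$p_adjusted <- NA_real_
    for (cmp in unique(out$comparison)) {
      sel <- out$comparison == cmp
      out$p_adjusted[sel] <- stats::p.adjust(out$p[sel], method = p_adjust)
    }
  }
  class(out) <- c("reliability_table", "data.frame")
  out
}

#' Round a reliability table for report output
#'
#' Applies half-away-from-zero rounding to 3 decimals to every numeric
#' column except the counts, mirroring printed report precision; full
#' precision is retained in the unrounded table.
#'
#' @param table a `reliability_table`.
#' @param digits decimal places (default 3).
#' @return The rounded data frame.
#' @export
round_reliability_table <- function(table, digits = 3) {
  num <- vapply(table, is.numeric, logical(1))
  num[names(table) %in% c("n", "ba_n_outside")] <- FALSE
  table[num] <- lapply(table[num], round_half_away, digits = digits)
  table
}
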