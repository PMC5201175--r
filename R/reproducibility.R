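#' Root-mean-square deviation of test-retest differences
#'
#' `sqrt(sum(d^2) / n)` over the per-subject differences between the two
#' sessions.
#'
#' @param d Differences (scan1 - scan2), ms; length >= 2.
#' @return rMSD, ms.
#' @export
rmsd <- function(d) {
  if (length(d) < 2) stop("rmsd needs at least 2 differences", call. = FALSE)
  sqrt(sum(d^2) / length(d))
}

#' 95% CI half-width of the mean test-retest difference
#'
#' `t(0.975, n - 1) * sd(d) / sqrt(n)`: the large-sample 1.96 multiplier is
#' replaced by the Student-t quantile appropriate to the cohort size (2.131 at
#' n = 16, 2.179 at n = 13). Indicates the measurement variability expected in
#' a group of `n` subjects.
#'
#' @param d Differences (scan1 - scan2), ms; length >= 2.
#' @param conf Confidence level (default 0.95).
#' @return Half-width of the CI, ms.
#' @export
ci_mean_difference <- function(d, conf = 0.95) {
  n <- length(d)
  if (n < 2) stop("CI needs at least 2 differences", call. = FALSE)
  stats::qt(1 - (1 - conf) / 2, df = n - 1) * stats::sd(d) / sqrt(n)
}

#' Within-subject SD and repeatability coefficient
#'
#' `wSD = rMSD / sqrt(2)` and `r = 2.77 * wSD` (equivalently `1.96 * rMSD`):
#' the repeatability coefficient bounds the difference expected in 95% of
#' paired observations on one individual.
#'
#' @param d Differences (scan1 - scan2), ms; length >= 2.
#' @return Named numeric `c(wsd_ms = , repeatability_ms = )`.
#' @export
wsd_and_repeatability <- function(d) {
  w <- rmsd(d) / sqrt(2)
  c(wsd_ms = w, repeatability_ms = 2.77 * w)
}

#' Coefficient of variation of paired repeats
#'
#' Per subject, the sample SD of the two repeated measurements over their
#' mean (x100); reported as mean and SD of the per-subject CVs across the
#' cohort.
#'
#' @param t1_scan1,t1_scan2 Paired measurements, same length; all pair means
#'   must be positive.
#' @return Named numeric `c(cv_mean_pct = , cv_sd_pct = )`.
#' @export
cv_pairs <- function(t1_scan1, t1_scan2) {
  stopifnot(length(t1_scan1) == length(t1_scan2))
  m <- (t1_scan1 + t1_scan2) / 2
  if (any(m <= 0)) stop("pair means must be > 0", call. = FALSE)
  cv <- abs(t1_scan1 - t1_scan2) / sqrt(2) / m * 100
  c(cv_mean_pct = mean(cv), cv_sd_pct = stats::sd(cv))
}

#' Distributional pre-checks for a test-retest set
#'
#' Shapiro-Wilk normality test on the differences, Wilcoxon signed-rank test
#' of zero bias, and Kendall's tau between the absolute differences and the
#' per-subject means (repeatability statistics assume `|d|` does not scale
#' with the measurement). Degenerate inputs for the Kendall test (no variation
#' in `|d|` or in the means, so every pair is tied) return `tau = 0`,
#' `p = 1` by convention.
#'
#' @param t1_scan1,t1_scan2 Paired measurements (length >= 3).
#' @return One-row tibble: `shapiro_p`, `wilcoxon_p`, `kendall_tau`,
#'   `kendall_p`.
#' @export
precheck_tests <- function(t1_scan1, t1_scan2) {
  stopifnot(length(t1_scan1) == length(t1_scan2))
  d <- t1_scan1 - t1_scan2
  if (length(d) < 3) stop("pre-checks need at least 3 pairs", call. = FALSE)
  shapiro_p <- if (stats::sd(d) == 0) NA_real_ else stats::shapiro.test(d)$p.value
  wilcoxon_p <- if (all(d == 0)) 1 else
    suppressWarnings(stats::wilcox.test(d, mu = 0)$p.value)
  m <- (t1_scan1 + t1_scan2) / 2
  if (stats::sd(abs(d)) == 0 || stats::sd(m) == 0) {
    kt <- 0; kp <- 1
  } else {
    ct <- suppressWarnings(stats::cor.test(abs(d), m, method = "kendall"))
    kt <- unname(ct$estimate); kp <- ct$p.value
  }
  tibble::tibble(shapiro_p = shapiro_p, wilcoxon_p = wilcoxon_p,
                 kendall_tau = kt, kendall_p = kp)
}

#' Test-retest reproducibility report
#'
#' Computes the full reproducibility row for one ROI and method: cohort mean,
#' mean absolute difference, t-corrected 95% CI of the mean difference (ms and
#' % of the mean), within-subject SD, repeatability coefficient, CV
#' (mean +/- SD), and the distributional pre-checks. The differences are
#' recomputed from the paired measurements, never supplied.
#'
#' @param t1_scan1,t1_scan2 Paired per-subject ROI means from the two
#'   sessions, ms.
#' @param roi,method Labels for the output row.
#' @return One-row tibble in the layout of the study's reproducibility table,
#'   plus the pre-check columns.
#' @export
repro_report <- function(t1_scan1, t1_scan2, roi = "ROI", method = "VFA") {
  stopifnot(length(t1_scan1) == length(t1_scan2), length(t1_scan1) >= 2)
  d <- t1_scan1 - t1_scan2
  wr <- wsd_and_repeatability(d)
  cv <- cv_pairs(t1_scan1, t1_scan2)
  mean_ms <- mean(c(t1_scan1, t1_scan2))
  ci <- ci_mean_difference(d)
  pc <- if (length(d) >= 3) precheck_tests(t1_scan1, t1_scan2) else
    tibble::tibble(shapiro_p = NA_real_, wilcoxon_p = NA_real_,
                   kendall_tau = NA_real_, kendall_p = NA_real_)
  tibble::tibble(
    roi = roi, method = method, n_subjects = length(d),
    mean_ms = mean_ms,
    mean_abs_diff_ms = mean(abs(d)),
    ci_ms = ci, ci_pct = 100 * ci / mean_ms,
    wsd_ms = unname(wr["wsd_ms"]),
    repeatability_ms = unname(wr["repeatability_ms"]),
    cv_mean_pct = unname(cv["cv_mean_pct"]),
    cv_sd_pct = unname(cv["cv_sd_pct"]),
    !!!pc)
}
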