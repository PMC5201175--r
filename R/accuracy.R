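#' Percent error against a reference
#'
#' `100 * |test - ref| / ref`, the accuracy metric comparing a test T1 to the
#' inversion recovery gold standard. Scale-invariant and vectorized.
#'
#' @param test_t1_ms,ref_t1_ms Test and reference values; the reference must
#'   be strictly positive.
#' @return Percent error(s).
#' @export
percent_error <- function(test_t1_ms, ref_t1_ms) {
  if (any(ref_t1_ms <= 0)) stop("reference values must be > 0", call. = FALSE)
  100 * abs(test_t1_ms - ref_t1_ms) / ref_t1_ms
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`, an
#' agreement measure combining correlation and calibration. Moments divide by
#' `n` (population convention, Lin's original definition) by default; the
#' sample (`n - 1`) convention is available for comparison with software that
#' uses it.
#'
#' @param x,y Paired measurements (length >= 2).
#' @param moments `"population"` or `"sample"`.
#' @return The CCC, in `[-1, 1]`.
#' @export
concordance_correlation <- function(x, y,
                                    moments = c("population", "sample")) {
  moments <- match.arg(moments)
  stopifnot(length(x) == length(y), length(x) >= 2)
  n <- length(x)
  denom_n <- if (moments == "population") n else n - 1
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / denom_n
  vy <- sum((y - my)^2) / denom_n
  cxy <- sum((x - mx) * (y - my)) / denom_n
  if (vx + vy + (mx - my)^2 == 0) {
    stop("degenerate input: both variables are constant", call. = FALSE)
  }
  2 * cxy / (vx + vy + (mx - my)^2)
}

check_paired_cohort <- function(cohort) {
  need <- c("subject_id", "vfa_t1_ms", "vfa_b1_t1_ms", "ir_t1_ms")
  if (!all(need %in% names(cohort))) {
    stop("cohort needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  vals <- unlist(cohort[c("vfa_t1_ms", "vfa_b1_t1_ms", "ir_t1_ms")])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all T1 measurements must be finite and > 0", call. = FALSE)
  }
  invisible(cohort)
}

#' Subject-level bootstrap of the mean difference in absolute deviation
#'
#' Point estimate: the mean over all records of
#' `|VFA - IR| - |VFA_B1 - IR|`, i.e. how much closer to the gold standard the
#' B1-corrected value sits. A positive value (and an all-positive CI) means
#' the correction reduces the absolute deviation. The bootstrap resamples
#' whole subjects with replacement -- both sessions of a resampled subject
#' travel together -- and the CI is the 2.5/97.5 percentile of the resampled
#' means. For small cohorts all `n^n` ordered resamples can be enumerated
#' exactly instead of sampled.
#'
#' @param cohort Tibble with columns `subject_id`, `vfa_t1_ms`,
#'   `vfa_b1_t1_ms`, `ir_t1_ms` (one row per subject-session record).
#' @param n_boot Number of bootstrap resamples (>= 100; 1000 is the
#'   conventional choice).
#' @param seed RNG seed for resampling.
#' @param exhaustive Enumerate all ordered resamples instead of sampling
#'   (feasible only for very small cohorts; `n^n` grows fast).
#' @return One-row tibble: `boot_avg_ms`, `boot_ci_lo_ms`, `boot_ci_hi_ms`,
#'   `n_subjects`, `n_records`.
#' @export
bootstrap_mean_abs_dev_diff <- function(cohort, n_boot = 1000, seed = 1L,
                                        exhaustive = FALSE) {
  check_paired_cohort(cohort)
  subjects <- unique(cohort$subject_id)
  n <- length(subjects)
  if (n < 2) stop("bootstrap needs at least 2 subjects", call. = FALSE)
  if (!exhaustive && n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  dev <- abs(cohort$vfa_t1_ms - cohort$ir_t1_ms) -
    abs(cohort$vfa_b1_t1_ms - cohort$ir_t1_ms)
  avg <- mean(dev)
  by_subj <- split(dev, factor(cohort$subject_id, levels = subjects))
  resample_mean <- function(idx) mean(unlist(by_subj[idx], use.names = FALSE))
  boots <- if (exhaustive) {
    if (n^n > 1e6) stop("exhaustive enumeration infeasible for n = ", n,
                        call. = FALSE)
    grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    apply(grid, 1, resample_mean)
  } else {
    with_preserved_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        resample_mean(sample.int(n, n, replace = TRUE))
      }, numeric(1))
    })
  }
  ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  tibble::tibble(boot_avg_ms = avg, boot_ci_lo_ms = ci[1],
                 boot_ci_hi_ms = ci[2], n_subjects = n,
                 n_records = nrow(cohort))
}

#' Accuracy report for a paired cohort
#'
#' Per-method percent error (mean and SD across records), concordance with
#' the IR gold standard, and the subject-level bootstrap of the mean
#' difference in absolute deviation, in the layout of the study's accuracy
#' table.
#'
#' @inheritParams bootstrap_mean_abs_dev_diff
#' @return Tibble with one row per method (`VFA`, `VFA_B1`): `pct_err_mean`,
#'   `pct_err_sd`, `ccc`; the bootstrap row is attached as attribute
#'   `"bootstrap"` and also returned by [glance_accuracy()].
#' @export
accuracy_report <- function(cohort, n_boot = 1000, seed = 1L) {
  check_paired_cohort(cohort)
  per_method <- dplyr::bind_rows(
    tibble::tibble(method = "VFA",
                   pct_err_mean = mean(percent_error(cohort$vfa_t1_ms,
                                                     cohort$ir_t1_ms)),
                   pct_err_sd = stats::sd(percent_error(cohort$vfa_t1_ms,
                                                        cohort$ir_t1_ms)),
                   ccc = concordance_correlation(cohort$ir_t1_ms,
                                                 cohort$vfa_t1_ms)),
    tibble::tibble(method = "VFA_B1",
                   pct_err_mean = mean(percent_error(cohort$vfa_b1_t1_ms,
                                                     cohort$ir_t1_ms)),
                   pct_err_sd = stats::sd(percent_error(cohort$vfa_b1_t1_ms,
                                                        cohort$ir_t1_ms)),
                   ccc = concordance_correlation(cohort$ir_t1_ms,
                                                 cohort$vfa_b1_t1_ms))
  )
  attr(per_method, "bootstrap") <-
    bootstrap_mean_abs_dev_diff(cohort, n_boot = n_boot, seed = seed)
  per_method
}

#' Bootstrap row of an accuracy report
#' @param report A result of [accuracy_report()].
#' @return The attached bootstrap tibble.
#' @export
glance_accuracy <- function(report) attr(report, "bootstrap")
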