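#' Tidy a T1 map into a per-voxel tibble
#'
#' @param x A [t1_map()].
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `slice`, `t1_ms`, `s0`, `rss`, `valid`.
#' @export
tidy.t1_map <- function(x, ...) {
  d <- dim(x$t1_ms)
  idx <- arrayInd(seq_along(x$t1_ms), d)
  tibble::tibble(row = idx[, 1], col = idx[, 2], slice = idx[, 3],
                 t1_ms = as.vector(x$t1_ms), s0 = as.vector(x$s0),
                 rss = as.vector(x$rss), valid = as.vector(x$valid_mask))
}

#' One-row summary of a T1 map
#'
#' @param x A [t1_map()].
#' @param ... Unused.
#' @return Tibble with `method`, `n_voxels`, `n_valid`, `median_t1_ms`,
#'   `mean_t1_ms`, `sd_t1_ms`.
#' @export
glance.t1_map <- function(x, ...) {
  v <- x$t1_ms[x$valid_mask]
  tibble::tibble(method = x$method, n_voxels = length(x$t1_ms),
                 n_valid = sum(x$valid_mask),
                 median_t1_ms = stats::median(v), mean_t1_ms = mean(v),
                 sd_t1_ms = stats::sd(v))
}

#' Plot a T1 map as a raster
#'
#' @param object A [t1_map()].
#' @param slice Slice index to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.t1_map <- function(object, slice = 1, ...) {
  df <- dplyr::filter(tidy.t1_map(object), .data$slice == !!slice)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$t1_ms)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20", name = "T1 (ms)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0("T1 map (", object$method, ")"),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of test-retest measurements
#'
#' Differences between the two sessions against the pair means, with the mean
#' difference (solid), its t-corrected 95% CI (dashed), and the repeatability
#' coefficient band (dotted).
#'
#' @param t1_scan1,t1_scan2 Paired per-subject measurements, ms.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(t1_scan1, t1_scan2, title = "Bland-Altman") {
  d <- t1_scan1 - t1_scan2
  m <- (t1_scan1 + t1_scan2) / 2
  ci <- ci_mean_difference(d)
  r <- unname(wsd_and_repeatability(d)["repeatability_ms"])
  df <- tibble::tibble(mean = m, diff = d)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = mean(d), linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = mean(d) + c(-ci, ci),
                        linetype = "dashed", colour = "blue") +
    ggplot2::geom_hline(yintercept = c(-r, r), linetype = "dotted",
                        colour = "red") +
    ggplot2::labs(title = title, x = "Mean T1 of repeats (ms)",
                  y = "Difference (ms)") +
    ggplot2::theme_minimal()
}

#' Plot a phase-versus-B1 lookup table
#'
#' @param object A `phase_lookup`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_lookup <- function(object, ...) {
  df <- as.data.frame(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b1_ut, y = .data$phase_rad)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "B1 (uT)", y = "Phase difference (rad)",
                  title = pulse_id(object$pulse)) +
    ggplot2::theme_minimal()
}
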