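#' SPGR (spoiled gradient echo) steady-state signal
#'
#' `S = S0 * sin(f*a) * (1 - E1) / (1 - E1 * cos(f*a))` with
#' `E1 = exp(-TR/T1)`, where `a` is the prescribed flip angle and `f` the
#' transmit correction factor (actual/prescribed flip angle). TE is assumed
#' much shorter than T2* and does not enter.
#'
#' @param t1_ms T1, ms (> 0). Vectorized over all arguments.
#' @param s0 Amplitude (scanner gain x proton density), arbitrary units.
#' @param alpha_deg Prescribed flip angle, degrees.
#' @param f Flip-angle correction factor (> 0), 1 = nominal.
#' @param tr_ms Repetition time, ms (> 0).
#' @return Signal in the units of `s0`.
#' @export
spgr_signal <- function(t1_ms, s0, alpha_deg, f = 1, tr_ms = 7.9) {
  stopifnot(all(t1_ms > 0), all(tr_ms > 0), all(f > 0))
  a <- f * alpha_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  s0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Inversion recovery magnitude signal
#'
#' `S = S0 * |cos(a) * (1 - exp(-TD/T1)) * exp(-TI/T1) + 1 - exp(-TI/T1)|`,
#' the magnitude model for an IR preparation with inversion angle `a`,
#' predelay TD and inversion time TI.
#'
#' @param t1_ms T1, ms (> 0). Vectorized.
#' @param s0 Amplitude.
#' @param ti_ms Inversion time, ms (> 0).
#' @param td_ms Predelay before the inversion pulse, ms (> 0).
#' @param inv_flip_deg Inversion pulse flip angle, degrees.
#' @return Magnitude signal.
#' @export
ir_signal <- function(t1_ms, s0, ti_ms, td_ms = 2500, inv_flip_deg = 180) {
  stopifnot(all(t1_ms > 0), all(ti_ms > 0), all(td_ms > 0))
  ca <- cos(inv_flip_deg * pi / 180)
  v <- exp(-ti_ms / t1_ms)
  s0 * abs(ca * (1 - exp(-td_ms / t1_ms)) * v + 1 - v)
}

#' Voxelwise fit options
#'
#' @param t1_bounds_ms `c(low, high)` box constraints on T1, ms.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @param tol Relative decrease of the residual sum of squares below which the
#'   fit is declared converged.
#' @param init_strategy `"linearized"` (DESPOT1 regression for VFA, minimum-
#'   signal TI for IR) or `"fixed"` (midpoint of the T1 bounds).
#' @param min_signal Voxels whose maximum signal is below this floor are
#'   skipped and marked invalid.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(t1_bounds_ms = c(1, 10000), max_iter = 50, tol = 1e-10,
                        init_strategy = c("linearized", "fixed"),
                        min_signal = 1e-6) {
  init_strategy <- match.arg(init_strategy)
  if (t1_bounds_ms[1] <= 0 || t1_bounds_ms[2] <= t1_bounds_ms[1]) {
    stop("t1_bounds_ms must satisfy 0 < low < high", call. = FALSE)
  }
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  structure(list(t1_bounds_ms = t1_bounds_ms, max_iter = as.integer(max_iter),
                 tol = tol, init_strategy = init_strategy,
                 min_signal = min_signal),
            class = "fit_options")
}

# Vectorized Levenberg-Marquardt over voxels for a 2-parameter separable model
# S = S0 * g(T1). `gfun(t1, rows)` returns the profile matrix and its
# derivative d g / d T1 for the given voxel rows. All active voxels advance
# simultaneously; the damping factor is per voxel and steps are only accepted
# when they reduce the residual sum of squares, so the converged RSS never
# exceeds the initialization RSS. Voxels leave the active set once their
# relative RSS decrease falls below `opts$tol` (or the damped step stalls),
# so late iterations only touch the remaining stragglers.
lm_fit_maps <- function(Y, gfun, t1_init, s0_init, opts) {
  nv <- nrow(Y)
  lo <- opts$t1_bounds_ms[1]; hi <- opts$t1_bounds_ms[2]
  t1 <- pmin(pmax(t1_init, lo), hi)
  s0 <- pmax(s0_init, 0)
  cur <- rowSums((s0 * gfun(t1, seq_len(nv))$g - Y)^2)
  lambda <- rep(1e-3, nv)
  active <- rep(TRUE, nv)
  for (it in seq_len(opts$max_iter)) {
    idx <- which(active)
    if (length(idx) == 0L) break
    Ya <- Y[idx, , drop = FALSE]
    t1a <- t1[idx]; s0a <- s0[idx]; la <- lambda[idx]; cura <- cur[idx]
    gr <- gfun(t1a, idx)
    R <- s0a * gr$g - Ya                # residuals
    J1 <- s0a * gr$dg_dt1               # d r / d T1
    J2 <- gr$g                          # d r / d S0
    a11 <- rowSums(J1 * J1); a12 <- rowSums(J1 * J2); a22 <- rowSums(J2 * J2)
    g1 <- rowSums(J1 * R); g2 <- rowSums(J2 * R)
    improved <- rep(FALSE, length(idx))
    trial <- cura
    t1_new <- t1a; s0_new <- s0a
    for (tries in 1:8) {
      need <- !improved
      if (!any(need)) break
      d11 <- a11 + la * pmax(a11, 1e-12)
      d22 <- a22 + la * pmax(a22, 1e-12)
      det <- d11 * d22 - a12^2
      det[abs(det) < 1e-300] <- NA
      dt1 <- -(d22 * g1 - a12 * g2) / det
      ds0 <- -(d11 * g2 - a12 * g1) / det
      cand_t1 <- pmin(pmax(t1a + dt1, lo), hi)
      cand_s0 <- pmax(s0a + ds0, 0)
      bad <- !is.finite(cand_t1) | !is.finite(cand_s0)
      cand_t1[bad] <- t1a[bad]; cand_s0[bad] <- s0a[bad]
      cand_sse <- rowSums((cand_s0 * gfun(cand_t1, idx)$g - Ya)^2)
      acc <- need & is.finite(cand_sse) & cand_sse < cura
      t1_new[acc] <- cand_t1[acc]; s0_new[acc] <- cand_s0[acc]
      trial[acc] <- cand_sse[acc]
      la[acc] <- pmax(la[acc] / 3, 1e-12)
      la[need & !acc] <- pmin(la[need & !acc] * 10, 1e8)
      improved <- improved | acc
    }
    rel <- (cura - trial) / pmax(cura, .Machine$double.xmin)
    t1[idx] <- t1_new; s0[idx] <- s0_new
    cur[idx] <- trial; lambda[idx] <- la
    active[idx] <- improved & rel >= opts$tol
  }
  list(t1 = t1, s0 = s0, rss = cur)
}

despot1_init <- function(Y, angles_rad_eff, tr_ms, opts) {
  # regression of S/sin(fa) on S/tan(fa); slope = E1
  sn <- sin(angles_rad_eff); tn <- tan(angles_rad_eff)
  Z <- Y / sn; X <- Y / tn
  xm <- rowMeans(X); zm <- rowMeans(Z)
  sxx <- rowSums((X - xm)^2)
  sxz <- rowSums((X - xm) * (Z - zm))
  slope <- sxz / pmax(sxx, 1e-300)
  slope <- pmin(pmax(slope, 1e-6), 1 - 1e-9)
  t1 <- -tr_ms / log(slope)
  s0 <- (zm - slope * xm) / (1 - slope)
  t1 <- pmin(pmax(t1, opts$t1_bounds_ms[1]), opts$t1_bounds_ms[2])
  list(t1 = t1, s0 = pmax(s0, 0))
}

#' Fit the VFA signal model voxel by voxel
#'
#' Deterministic bounded least-squares fit of the SPGR model in (T1, S0) at
#' every voxel, initialized by the linearized DESPOT1 regression. With a
#' correction map the effective flip angle `f * a` enters both the
#' initialization and the model, giving the B1-corrected T1 map; without one
#' `f = 1` and the map is tagged `VFA` (uncorrected).
#'
#' @param series A [vfa_series()] (at least 3 flip angles).
#' @param f_map Optional [correction_factor_map()] on the series grid; voxels
#'   with undefined `f` are marked invalid.
#' @param options A [fit_options()].
#' @return A [t1_map()] with method `"VFA"` or `"VFA_B1"`.
#' @export
fit_vfa <- function(series, f_map = NULL, options = fit_options()) {
  stopifnot(inherits(series, "vfa_series"))
  if (length(series$flip_angles_deg) < 3) {
    stop("VFA fitting needs at least 3 flip angles", call. = FALSE)
  }
  d <- series_grid_dim(series)
  Y <- series_matrix(series)
  corrected <- !is.null(f_map)
  f <- if (corrected) as.vector(f_map$f) else rep(1, nrow(Y))
  if (corrected) stopifnot(identical(dim(f_map$f), d))
  usable <- apply(Y, 1, max) >= options$min_signal & is.finite(f) & f > 0
  alpha <- series$flip_angles_deg * pi / 180
  t1v <- rep(NA_real_, nrow(Y)); s0v <- rep(NA_real_, nrow(Y))
  rssv <- rep(NA_real_, nrow(Y))
  if (any(usable)) {
    Yu <- Y[usable, , drop = FALSE]
    fe <- f[usable]
    A <- outer(fe, alpha)               # effective angles, rad
    init <- if (options$init_strategy == "linearized") {
      despot1_init(Yu, A, series$tr_ms, options)
    } else {
      list(t1 = rep(mean(options$t1_bounds_ms), nrow(Yu)),
           s0 = apply(Yu, 1, max))
    }
    sinA <- sin(A); cosA <- cos(A)
    gfun <- function(t1, rows) {
      sA <- sinA[rows, , drop = FALSE]; cA <- cosA[rows, , drop = FALSE]
      e1 <- exp(-series$tr_ms / t1)
      den <- 1 - e1 * cA
      g <- sA * (1 - e1) / den
      dg_de1 <- sA * (cA - 1) / den^2
      de1_dt1 <- e1 * series$tr_ms / t1^2
      list(g = g, dg_dt1 = dg_de1 * de1_dt1)
    }
    fit <- lm_fit_maps(Yu, gfun, init$t1, init$s0, options)
    t1v[usable] <- fit$t1; s0v[usable] <- fit$s0; rssv[usable] <- fit$rss
  }
  finalize_t1_map(t1v, s0v, rssv, d, options,
                  method = if (corrected) "VFA_B1" else "VFA",
                  voxel_size_mm = series$volumes[[1]]$voxel_size_mm)
}

#' Fit the IR magnitude signal model voxel by voxel
#'
#' Deterministic bounded least-squares fit of the magnitude IR model in
#' (T1, S0), with the inversion angle fixed at the protocol value. The
#' magnitude model is fitted directly; no polarity restoration is attempted.
#' Initialization: T1 from the TI nearest the per-voxel signal minimum via
#' `TI / ln 2`, S0 from the longest-TI signal.
#'
#' @param series An [ir_series()] (at least 4 inversion times).
#' @param options A [fit_options()].
#' @return A [t1_map()] with method `"IR"`.
#' @export
fit_ir <- function(series, options = fit_options()) {
  stopifnot(inherits(series, "ir_series"))
  if (length(series$ti_ms) < 4) {
    stop("IR fitting needs at least 4 inversion times", call. = FALSE)
  }
  d <- series_grid_dim(series)
  Y <- series_matrix(series)
  usable <- apply(Y, 1, max) >= options$min_signal
  ti <- series$ti_ms; td <- series$td_ms
  ca <- cos(series$inv_flip_deg * pi / 180)
  t1v <- rep(NA_real_, nrow(Y)); s0v <- rep(NA_real_, nrow(Y))
  rssv <- rep(NA_real_, nrow(Y))
  if (any(usable)) {
    Yu <- Y[usable, , drop = FALSE]
    init <- if (options$init_strategy == "linearized") {
      ti_min <- ti[apply(Yu, 1, which.min)]
      list(t1 = pmin(pmax(ti_min / log(2), options$t1_bounds_ms[1]),
                     options$t1_bounds_ms[2]),
           s0 = Yu[, length(ti)])
    } else {
      list(t1 = rep(mean(options$t1_bounds_ms), nrow(Yu)),
           s0 = Yu[, length(ti)])
    }
    TI <- matrix(ti, nrow(Yu), length(ti), byrow = TRUE)
    gfun <- function(t1, rows) {
      TIa <- TI[rows, , drop = FALSE]
      u <- exp(-td / t1)                       # nvox
      v <- exp(-TIa / t1)                      # nvox x k
      q <- ca * (1 - u) * v + 1 - v
      sq <- sign(q); sq[sq == 0] <- 1
      dv <- v * TIa / t1^2
      du <- u * td / t1^2
      dq <- ca * (-du * v + (1 - u) * dv) - dv
      list(g = abs(q), dg_dt1 = sq * dq)
    }
    fit <- lm_fit_maps(Yu, gfun, init$t1, init$s0, options)
    t1v[usable] <- fit$t1; s0v[usable] <- fit$s0; rssv[usable] <- fit$rss
  }
  finalize_t1_map(t1v, s0v, rssv, d, options, method = "IR",
                  voxel_size_mm = series$volumes[[1]]$voxel_size_mm)
}

finalize_t1_map <- function(t1v, s0v, rssv, d, options, method, voxel_size_mm) {
  valid <- is.finite(t1v) &
    t1v > options$t1_bounds_ms[1] & t1v < options$t1_bounds_ms[2]
  t1v[!valid] <- NA_real_
  t1_map(array(t1v, d), array(s0v, d), array(rssv, d), method = method,
         valid_mask = array(valid, d), voxel_size_mm = voxel_size_mm)
}
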