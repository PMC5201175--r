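# Gyromagnetic ratio of 1H: 42.577 MHz/T == 42.577 Hz/uT.
GAMMA_HZ_PER_UT <- 42.577

#' Off-resonant phase-imparting pulse specification
#'
#' Describes the Bloch-Siegert pulse used both to forward-simulate phase images
#' and to build the phase-versus-B1 lookup table. Amplitude is given as the
#' root-mean-square B1 over the pulse; shaped envelopes are normalized so their
#' RMS equals `b1_rms_ut`.
#'
#' Shapes: `constant` (rectangular), `fermi` (flat top with smooth Fermi
#' transitions; `shape_params$t0_ms` half-width of the flat top,
#' `shape_params$a_ms` transition width), `gaussian`
#' (`shape_params$sigma_ms`), and `freq_swept` (constant amplitude with the
#' offset swept linearly from `shape_params$sweep_start_hz` to
#' `shape_params$sweep_end_hz`, defaults 2x offset down to the nominal offset).
#'
#' A warning is issued when the nominal offset is less than 10x the RMS Rabi
#' frequency `gamma * b1_rms`, i.e. when the pulse leaves the pure-phase
#' (no-excitation) regime that the method relies on.
#'
#' @param duration_ms Pulse length, ms.
#' @param shape One of `"constant"`, `"fermi"`, `"gaussian"`, `"freq_swept"`.
#' @param offset_hz Nominal off-resonance of the pulse, Hz (positive; the
#'   acquisition plays it at both signs).
#' @param b1_rms_ut Root-mean-square B1 amplitude, micro-Tesla.
#' @param shape_params Named list of shape-specific parameters (see Details).
#' @param n_steps Hard-pulse integration steps (>= 100).
#' @return An object of class `pulse_spec`.
#' @export
pulse_spec <- function(duration_ms = 2, shape = c("fermi", "constant",
                                                  "gaussian", "freq_swept"),
                       offset_hz = 8000, b1_rms_ut = 2.29,
                       shape_params = list(), n_steps = 2000) {
  shape <- match.arg(shape)
  if (!is.finite(duration_ms) || duration_ms <= 0) {
    stop("duration_ms must be > 0", call. = FALSE)
  }
  if (!is.finite(offset_hz) || offset_hz == 0) {
    stop("offset_hz must be nonzero", call. = FALSE)
  }
  if (n_steps < 100) stop("n_steps must be >= 100", call. = FALSE)
  if (abs(offset_hz) < 10 * GAMMA_HZ_PER_UT * b1_rms_ut) {
    warning("pulse offset is below 10x the RMS Rabi frequency; ",
            "the pure-phase (no-excitation) regime may be violated",
            call. = FALSE)
  }
  structure(list(duration_ms = duration_ms, shape = shape,
                 offset_hz = offset_hz, b1_rms_ut = b1_rms_ut,
                 shape_params = shape_params, n_steps = as.integer(n_steps)),
            class = "pulse_spec")
}

#' @export
print.pulse_spec <- function(x, ...) {
  cat(sprintf("<pulse_spec> %s  %g ms, %g uT RMS, offset %g Hz, %d steps\n",
              x$shape, x$duration_ms, x$b1_rms_ut, x$offset_hz, x$n_steps))
  invisible(x)
}

pulse_id <- function(pulse) {
  sprintf("%s_%gms_%gHz_%guT", pulse$shape, pulse$duration_ms,
          pulse$offset_hz, pulse$b1_rms_ut)
}

# Normalized envelope (RMS 1) and offset trajectory (Hz) at step midpoints.
pulse_waveform <- function(pulse) {
  n <- pulse$n_steps
  t_ms <- (seq_len(n) - 0.5) * pulse$duration_ms / n
  sp <- pulse$shape_params
  env <- switch(pulse$shape,
    constant = rep(1, n),
    fermi = {
      t0 <- sp$t0_ms %||% (0.3 * pulse$duration_ms)
      a <- sp$a_ms %||% (pulse$duration_ms / 40)
      1 / (1 + exp((abs(t_ms - pulse$duration_ms / 2) - t0) / a))
    },
    gaussian = {
      sg <- sp$sigma_ms %||% (pulse$duration_ms / 6)
      exp(-(t_ms - pulse$duration_ms / 2)^2 / (2 * sg^2))
    },
    freq_swept = rep(1, n)
  )
  env <- env / sqrt(mean(env^2))
  off <- if (pulse$shape == "freq_swept") {
    start <- sp$sweep_start_hz %||% (2 * pulse$offset_hz)
    end <- sp$sweep_end_hz %||% pulse$offset_hz
    start + (end - start) * (t_ms - t_ms[1]) / (t_ms[n] - t_ms[1])
  } else {
    rep(pulse$offset_hz, n)
  }
  list(t_ms = t_ms, env = env, offset_hz = off, dt_s = pulse$duration_ms / n / 1000)
}

#' Bloch simulation of the accrued Bloch-Siegert phase
#'
#' Integrates the Bloch equations (no relaxation) for an on-resonance spin with
#' transverse magnetization under the off-resonant pulse, using piecewise-
#' constant rotations (hard-pulse approximation), and returns the phase accrued
#' by the transverse magnetization relative to no pulse. The rotation
#' construction preserves the magnetization norm by design; an error is raised
#' if the pulse tips magnetization out of the transverse plane by more than 1%
#' of |M| (violation of the pure-phase regime).
#'
#' @param pulse A [pulse_spec()].
#' @param b1_ut B1 amplitude(s) at which to evaluate, micro-Tesla (vectorized).
#' @param offset_sign `+1` or `-1`: play the pulse at plus or minus its nominal
#'   offset trajectory.
#' @return Accrued phase(s), radians. Positive offsets accrue positive phase.
#' @export
simulate_pulse_phase <- function(pulse, b1_ut, offset_sign = 1) {
  stopifnot(inherits(pulse, "pulse_spec"))
  if (any(b1_ut < 0)) stop("b1_ut must be >= 0", call. = FALSE)
  stopifnot(offset_sign %in% c(-1, 1))
  wf <- pulse_waveform(pulse)
  nb <- length(b1_ut)
  # RF phase in the spin's rotating frame: integral of the offset trajectory
  rf_phase <- 2 * pi * cumsum(offset_sign * wf$offset_hz) * wf$dt_s
  mx <- rep(1, nb); my <- rep(0, nb); mz <- rep(0, nb)
  for (k in seq_along(wf$env)) {
    theta <- 2 * pi * GAMMA_HZ_PER_UT * b1_ut * wf$env[k] * wf$dt_s  # rad
    ux <- cos(rf_phase[k]); uy <- sin(rf_phase[k])
    ct <- cos(theta); st <- sin(theta)
    udm <- ux * mx + uy * my
    cx <- uy * mz            # (u x M)_x
    cy <- -ux * mz           # (u x M)_y
    cz <- ux * my - uy * mx  # (u x M)_z
    nmx <- ct * mx + st * cx + (1 - ct) * udm * ux
    nmy <- ct * my + st * cy + (1 - ct) * udm * uy
    nmz <- ct * mz + st * cz
    mx <- nmx; my <- nmy; mz <- nmz
  }
  norm_drift <- abs(sqrt(mx^2 + my^2 + mz^2) - 1)
  if (any(norm_drift > 1e-6)) {
    stop("magnetization norm drifted beyond 1e-6 during simulation", call. = FALSE)
  }
  excitation <- 1 - sqrt(mx^2 + my^2)
  if (any(excitation > 0.01)) {
    stop("pulse excites magnetization beyond 1% of |M|; ",
         "pure-phase regime violated", call. = FALSE)
  }
  # sign convention: phase accrues opposite to the sense of the frame rotation,
  # so flip to make a positive offset yield a positive Bloch-Siegert phase
  -atan2(my, mx) * bs_phase_sign()
}

# Orientation factor fixing "positive offset -> positive phase"; kept in one
# place so the convention is auditable.
bs_phase_sign <- function() 1

#' Build a phase-difference-versus-B1 lookup table
#'
#' Runs the Bloch simulation at both offset signs over an ascending B1 grid and
#' tabulates the phase difference (plus minus minus). Construction fails unless
#' the table is strictly monotonic over the design range, which is what makes
#' the later interpolation-based inversion well defined.
#'
#' @param pulse A [pulse_spec()].
#' @param b1_max_ut Upper end of the B1 grid, micro-Tesla; must cover at least
#'   twice the pulse's nominal RMS amplitude.
#' @param n_points Number of grid points (>= 32), first point at B1 = 0.
#' @return An object of class `phase_lookup` with fields `b1_grid_ut`,
#'   `phase_diff_rad`, `pulse`.
#' @export
build_lookup_table <- function(pulse, b1_max_ut = 2.5 * pulse$b1_rms_ut,
                               n_points = 64) {
  stopifnot(inherits(pulse, "pulse_spec"))
  if (b1_max_ut < 2 * pulse$b1_rms_ut) {
    stop("b1_max_ut must cover at least 2x the nominal B1", call. = FALSE)
  }
  if (n_points < 32) stop("n_points must be >= 32", call. = FALSE)
  b1 <- seq(0, b1_max_ut, length.out = n_points)
  pd <- simulate_pulse_phase(pulse, b1, offset_sign = 1) -
    simulate_pulse_phase(pulse, b1, offset_sign = -1)
  d <- diff(pd)
  if (!(all(d > 0) || all(d < 0))) {
    stop("lookup table is not strictly monotonic; ",
         "pulse leaves the design regime", call. = FALSE)
  }
  structure(list(b1_grid_ut = b1, phase_diff_rad = pd, pulse = pulse),
            class = "phase_lookup")
}

#' @export
print.phase_lookup <- function(x, ...) {
  cat(sprintf("<phase_lookup> %s  %d points over [0, %.3g] uT, phase span %.4g rad\n",
              pulse_id(x$pulse), length(x$b1_grid_ut), max(x$b1_grid_ut),
              diff(range(x$phase_diff_rad))))
  invisible(x)
}

#' @export
as.data.frame.phase_lookup <- function(x, ...) {
  data.frame(b1_ut = x$b1_grid_ut, phase_rad = x$phase_diff_rad)
}

#' Phase difference of a Bloch-Siegert image pair
#'
#' Per-voxel principal-value angle of `img_plus * Conj(img_minus)`, in
#' (-pi, pi]. Voxels where either magnitude is zero have no defined phase and
#' are set to `NA`.
#'
#' @param pair A [bs_phase_pair()].
#' @return An [image_volume()] of phase differences, radians (signed).
#' @export
phase_difference <- function(pair) {
  stopifnot(inherits(pair, "bs_phase_pair"))
  p <- pair$img_plus$data * Conj(pair$img_minus$data)
  ph <- Arg(p)
  ph[Mod(pair$img_plus$data) == 0 | Mod(pair$img_minus$data) == 0] <- NA_real_
  image_volume(ph, voxel_size_mm = pair$img_plus$voxel_size_mm,
               series_id = "bs_phase_difference", check_nonneg = FALSE)
}

#' Convert a phase-difference map into a flip-angle correction map
#'
#' Inverts the lookup table by piecewise-linear interpolation to obtain the
#' per-voxel B1 amplitude, then divides by the nominal B1 to give the
#' correction factor `f` (actual / prescribed flip angle). Phases outside the
#' table range are flagged invalid, never extrapolated. Because single-voxel
#' Bloch-Siegert phases are small, an optional smoothing step fits a low-order
#' in-plane polynomial surface to the measured phase differences (restricted
#' to `mask` when given) before inversion, reflecting the physical smoothness
#' of transmit fields; smoothing the phase rather than the inverted factors
#' keeps zero-mean phase noise from being truncated at the table edge.
#'
#' @param lookup A [build_lookup_table()] result.
#' @param phase_map [image_volume()] of measured phase differences, rad.
#' @param nominal_b1_ut The B1 amplitude corresponding to `f = 1`; must lie
#'   within the table range. Defaults to the pulse's RMS amplitude.
#' @param mask Optional logical array restricting which voxels inform (and
#'   receive) the estimate.
#' @param smooth `"none"` for voxelwise inversion, `"polyfit"` for the
#'   polynomial-surface fit.
#' @param degree Polynomial degree for `smooth = "polyfit"`.
#' @return A [correction_factor_map()].
#' @export
correction_map_from_phase <- function(lookup, phase_map,
                                      nominal_b1_ut = lookup$pulse$b1_rms_ut,
                                      mask = NULL,
                                      smooth = c("none", "polyfit"),
                                      degree = 2) {
  stopifnot(inherits(lookup, "phase_lookup"), is_image_volume(phase_map))
  smooth <- match.arg(smooth)
  rng <- range(lookup$phase_diff_rad)
  if (nominal_b1_ut < min(lookup$b1_grid_ut) ||
      nominal_b1_ut > max(lookup$b1_grid_ut)) {
    stop("nominal_b1_ut outside the lookup table range", call. = FALSE)
  }
  ph <- phase_map$data
  d <- dim(ph)
  if (!is.null(mask)) {
    mask <- promote_3d(mask)
    stopifnot(identical(dim(mask), d))
    ph[!mask] <- NA_real_
  }
  if (smooth == "polyfit") {
    ph <- polyfit_surface(ph, degree = degree, refit_mask = mask)
  }
  ord <- order(lookup$phase_diff_rad)
  b1 <- stats::approx(lookup$phase_diff_rad[ord], lookup$b1_grid_ut[ord],
                      xout = as.vector(ph), rule = 1)$y
  f <- b1 / nominal_b1_ut
  f[!is.na(f) & f <= 0] <- NA_real_
  dim(f) <- d
  if (!any(is.finite(f))) stop("no voxel yields a valid correction factor",
                               call. = FALSE)
  correction_factor_map(f, pulse_id = pulse_id(lookup$pulse))
}

# Least-squares polynomial surface in in-plane coordinates, fitted per slice to
# the finite entries of `f` and evaluated wherever the refit mask (or the
# finite set) extends.
polyfit_surface <- function(f, degree = 2, refit_mask = NULL) {
  d <- dim(f)
  out <- array(NA_real_, d)
  for (s in seq_len(d[3])) {
    sl <- f[, , s]
    idx <- which(is.finite(sl), arr.ind = TRUE)
    if (nrow(idx) < (degree + 1)^2) next
    x <- (idx[, 1] - 1) / max(1, d[1] - 1)
    y <- (idx[, 2] - 1) / max(1, d[2] - 1)
    X <- poly_design(x, y, degree)
    beta <- qr.solve(X, sl[idx])
    tgt <- if (is.null(refit_mask)) is.finite(sl) else refit_mask[, , s]
    tidx <- which(tgt, arr.ind = TRUE)
    if (!nrow(tidx)) next
    Xt <- poly_design((tidx[, 1] - 1) / max(1, d[1] - 1),
                      (tidx[, 2] - 1) / max(1, d[2] - 1), degree)
    sl_out <- array(NA_real_, d[1:2])
    sl_out[tidx] <- as.vector(Xt %*% beta)
    out[, , s] <- sl_out
  }
  out
}

poly_design <- function(x, y, degree) {
  terms <- list()
  for (i in 0:degree) for (j in 0:(degree - i)) {
    terms[[length(terms) + 1L]] <- x^i * y^j
  }
  do.call(cbind, terms)
}
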