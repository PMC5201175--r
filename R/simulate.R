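#' Noise specification for simulated acquisitions
#'
#' Magnitude series use Rician noise (complex Gaussian added to the noiseless
#' signal, then the modulus), the standard statistics of magnitude MRI;
#' Bloch-Siegert pairs use complex Gaussian noise directly.
#'
#' @param model `"none"`, `"rician"`, or `"gaussian_complex"`.
#' @param sigma Noise standard deviation per real/imaginary channel, in signal
#'   units. The default 0.02 puts unit-amplitude tissue at SNR 50, a moderate
#'   level for clinical 3 T acquisitions.
#' @param seed Integer seed; simulations are pure functions of (inputs, seed).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(model = c("rician", "none", "gaussian_complex"),
                       sigma = 0.02, seed = 1L) {
  model <- match.arg(model)
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(model = model, sigma = sigma, seed = as.integer(seed)),
            class = "noise_spec")
}

no_noise <- function() noise_spec("none", 0, 0L)

#' SNR-calibrated per-series noise specifications
#'
#' The three sequences produce very different signal levels from the same
#' proton density (short-TR SPGR signals are a few percent of S0, IR
#' magnitudes approach S0), so a single absolute sigma cannot represent one
#' scanner. This helper sets each series' noise SD to
#' `median(noiseless foreground signal) / snr`, i.e. a common image SNR.
#'
#' @param gt A `ground_truth` phantom.
#' @param protocols List with `vfa`, `ir` protocol lists (see
#'   [vfa_protocol()], [ir_protocol()]).
#' @param snr Target image signal-to-noise ratio; `Inf` gives noiseless specs.
#' @param seed Seed stored in the returned specs.
#' @return List of [noise_spec()]s named `vfa`, `ir`, `bs`.
#' @export
acquisition_noise <- function(gt, protocols = list(vfa = vfa_protocol(),
                                                   ir = ir_protocol()),
                              snr = 50, seed = 1L) {
  stopifnot(inherits(gt, "ground_truth"))
  if (!is.finite(snr)) {
    z <- noise_spec("none", 0, seed)
    return(list(vfa = z, ir = z, bs = z))
  }
  stopifnot(snr > 0)
  fg <- gt$labels > 0L
  t1 <- gt$t1_true$data[fg]; s0 <- gt$s0_true$data[fg]
  f <- gt$f_true[fg]
  vfa_sig <- unlist(lapply(protocols$vfa$flip_angles_deg, function(a) {
    spgr_signal(t1, s0, a, pmax(f, 1e-6), protocols$vfa$tr_ms)
  }))
  ir_sig <- unlist(lapply(protocols$ir$ti_ms, function(ti) {
    ir_signal(t1, s0, ti, protocols$ir$td_ms, protocols$ir$inv_flip_deg)
  }))
  list(vfa = noise_spec("rician", stats::median(vfa_sig) / snr, seed),
       ir = noise_spec("rician", stats::median(ir_sig) / snr, seed),
       bs = noise_spec("gaussian_complex", stats::median(s0) / snr, seed))
}

add_rician <- function(arr, sigma) {
  if (sigma == 0) return(arr)
  n <- length(arr)
  sqrt((arr + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

#' Forward-simulate a variable flip angle acquisition
#'
#' Evaluates the SPGR steady-state signal at every voxel of the phantom for
#' each flip angle, using the ground-truth T1, amplitude and transmit field,
#' and applies Rician noise when requested.
#'
#' @param gt A `ground_truth` phantom.
#' @param protocol List with `flip_angles_deg`, `tr_ms`, and optionally
#'   `te_ms`; defaults to the 10-angle (2..20 degrees) TR = 7.9 ms protocol.
#' @param noise A [noise_spec()].
#' @return A [vfa_series()].
#' @export
simulate_vfa <- function(gt, protocol = vfa_protocol(), noise = no_noise()) {
  stopifnot(inherits(gt, "ground_truth"))
  t1 <- gt$t1_true$data; s0 <- gt$s0_true$data; f <- gt$f_true
  vols <- with_preserved_seed(noise$seed, {
    lapply(protocol$flip_angles_deg, function(a) {
      s <- array(0, dim(t1))
      on <- t1 > 0 & s0 > 0 & f > 0
      s[on] <- spgr_signal(t1[on], s0[on], a, f[on], protocol$tr_ms)
      if (noise$model == "rician") s <- array(add_rician(s, noise$sigma), dim(s))
      image_volume(s, gt$t1_true$voxel_size_mm,
                   series_id = sprintf("vfa_fa%02g", a))
    })
  })
  vfa_series(vols, protocol$flip_angles_deg, protocol$tr_ms,
             protocol$te_ms %||% NA_real_)
}

#' Default VFA protocol (10 flip angles 2..20 degrees, TR 7.9 ms, TE 4.6 ms)
#' @param flip_angles_deg,tr_ms,te_ms Override individual fields.
#' @return Protocol metadata list.
#' @export
vfa_protocol <- function(flip_angles_deg = seq(2, 20, by = 2), tr_ms = 7.9,
                         te_ms = 4.6) {
  list(flip_angles_deg = flip_angles_deg, tr_ms = tr_ms, te_ms = te_ms)
}

#' Default IR protocol (12 TIs from 25 to 10000 ms, predelay 2500 ms)
#' @param ti_ms,td_ms,inv_flip_deg Override individual fields.
#' @return Protocol metadata list.
#' @export
ir_protocol <- function(ti_ms = c(25, 50, 75, 100, 200, 300, 400, 500,
                                  1000, 2000, 4000, 10000),
                        td_ms = 2500, inv_flip_deg = 180) {
  list(ti_ms = ti_ms, td_ms = td_ms, inv_flip_deg = inv_flip_deg)
}

#' Forward-simulate an inversion recovery acquisition
#'
#' Evaluates the magnitude IR signal model at each inversion time and applies
#' Rician noise when requested.
#'
#' @param gt A `ground_truth` phantom.
#' @param protocol List with `ti_ms`, `td_ms`, `inv_flip_deg`; see
#'   [ir_protocol()].
#' @param noise A [noise_spec()].
#' @return An [ir_series()].
#' @export
simulate_ir <- function(gt, protocol = ir_protocol(), noise = no_noise()) {
  stopifnot(inherits(gt, "ground_truth"))
  t1 <- gt$t1_true$data; s0 <- gt$s0_true$data
  vols <- with_preserved_seed(noise$seed + 1L, {
    lapply(protocol$ti_ms, function(ti) {
      s <- array(0, dim(t1))
      on <- t1 > 0 & s0 > 0
      s[on] <- ir_signal(t1[on], s0[on], ti, protocol$td_ms,
                         protocol$inv_flip_deg)
      if (noise$model == "rician") s <- array(add_rician(s, noise$sigma), dim(s))
      image_volume(s, gt$t1_true$voxel_size_mm,
                   series_id = sprintf("ir_ti%05g", ti))
    })
  })
  ir_series(vols, protocol$ti_ms, protocol$td_ms, protocol$inv_flip_deg)
}

#' Forward-simulate a Bloch-Siegert phase-image pair
#'
#' Gives every voxel the phase the Bloch simulation predicts for its local B1
#' (`f_true` times the nominal amplitude) at each offset sign, with the
#' ground-truth amplitude as magnitude, plus optional complex Gaussian noise.
#' Background voxels (`f_true = 0`) accrue no shift.
#'
#' @param gt A `ground_truth` phantom.
#' @param pulse A [pulse_spec()].
#' @param noise A [noise_spec()] (`gaussian_complex` or `none`).
#' @param nominal_b1_ut B1 amplitude corresponding to `f = 1`.
#' @return A [bs_phase_pair()].
#' @export
simulate_bs_pair <- function(gt, pulse = pulse_spec(), noise = no_noise(),
                             nominal_b1_ut = pulse$b1_rms_ut) {
  stopifnot(inherits(gt, "ground_truth"), inherits(pulse, "pulse_spec"))
  f <- gt$f_true; s0 <- gt$s0_true$data
  b1 <- as.vector(f) * nominal_b1_ut
  ub <- sort(unique(b1))
  ph_plus <- simulate_pulse_phase(pulse, ub, offset_sign = 1)
  ph_minus <- simulate_pulse_phase(pulse, ub, offset_sign = -1)
  idx <- match(b1, ub)
  mk <- function(ph_tab, tag) {
    ph <- array(ph_tab[idx], dim(f))
    img <- s0 * exp(1i * ph)
    img[s0 <= 0] <- 0 + 0i
    image_volume(img, gt$t1_true$voxel_size_mm, is_complex = TRUE,
                 series_id = tag)
  }
  plus <- mk(ph_plus, "bs_plus"); minus <- mk(ph_minus, "bs_minus")
  if (noise$model %in% c("gaussian_complex", "rician") && noise$sigma > 0) {
    pair <- with_preserved_seed(noise$seed + 2L, {
      n <- length(plus$data)
      p <- plus$data + complex(real = stats::rnorm(n, 0, noise$sigma),
                               imaginary = stats::rnorm(n, 0, noise$sigma))
      m <- minus$data + complex(real = stats::rnorm(n, 0, noise$sigma),
                                imaginary = stats::rnorm(n, 0, noise$sigma))
      list(p = array(p, dim(plus$data)), m = array(m, dim(minus$data)))
    })
    plus <- image_volume(pair$p, plus$voxel_size_mm, is_complex = TRUE,
                         series_id = "bs_plus")
    minus <- image_volume(pair$m, minus$voxel_size_mm, is_complex = TRUE,
                          series_id = "bs_minus")
  }
  bs_phase_pair(plus, minus, abs(pulse$offset_hz))
}

# Integer in-plane translation of all ground-truth fields (session jitter).
shift_ground_truth <- function(gt, jitter) {
  jitter <- as.integer(round(jitter))
  d <- dim(gt$labels)
  if (any(abs(jitter) >= d[1:2])) stop("jitter larger than grid", call. = FALSE)
  shift2 <- function(a) {
    out <- array(0, dim(a))
    src_r <- seq_len(d[1]) - jitter[1]; src_c <- seq_len(d[2]) - jitter[2]
    ok_r <- src_r >= 1 & src_r <= d[1]; ok_c <- src_c >= 1 & src_c <= d[2]
    out[which(ok_r), which(ok_c), ] <- a[src_r[ok_r], src_c[ok_c], , drop = FALSE]
    out
  }
  gt2 <- gt
  gt2$t1_true <- image_volume(shift2(gt$t1_true$data), gt$t1_true$voxel_size_mm,
                              series_id = "t1_true")
  gt2$s0_true <- image_volume(shift2(gt$s0_true$data), gt$s0_true$voxel_size_mm,
                              series_id = "s0_true")
  gt2$f_true <- shift2(gt$f_true)
  lab <- shift2(gt$labels); storage.mode(lab) <- "integer"
  gt2$labels <- lab
  gt2
}

#' Simulate a test-retest session pair
#'
#' Produces two independent-noise realizations of the VFA, IR, and
#' Bloch-Siegert acquisitions; the second session can be translated in-plane
#' by `jitter` voxels (emulating repositioning between scans) and can carry
#' its own transmit field (shim and coil loading differ between sessions).
#'
#' @param gt A `ground_truth` phantom.
#' @param protocols List with elements `vfa`, `ir` (protocol lists) and
#'   `pulse` (a [pulse_spec()]).
#' @param noise A single [noise_spec()] applied to every series, or a list of
#'   per-series specs named `vfa`, `ir`, `bs` (see [acquisition_noise()]);
#'   session seeds are derived from the spec seeds.
#' @param jitter Length-2 integer in-plane translation of session 2, voxels.
#' @param b1_range_session2 Optional `c(f_min, f_max)` replacing the phantom's
#'   transmit-field range in session 2.
#' @return List of two session bundles, each with `gt`, `vfa`, `ir`, `bs`.
#' @export
simulate_testretest <- function(gt, protocols = list(vfa = vfa_protocol(),
                                                     ir = ir_protocol(),
                                                     pulse = pulse_spec()),
                                noise = no_noise(), jitter = c(0L, 0L),
                                b1_range_session2 = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  if (inherits(noise, "noise_spec")) {
    noise <- list(vfa = noise, ir = noise, bs = noise)
  }
  stopifnot(all(c("vfa", "ir", "bs") %in% names(noise)))
  gt2 <- gt
  if (!is.null(b1_range_session2)) {
    spec2 <- gt$spec; spec2$b1_range <- b1_range_session2
    f2 <- eval_b1_field(spec2)
    f2[gt$labels == 0L] <- 0
    gt2$f_true <- f2
    gt2$spec <- spec2
  }
  if (any(jitter != 0)) gt2 <- shift_ground_truth(gt2, jitter)
  reseed <- function(ns, offset) { ns$seed <- ns$seed + offset; ns }
  session <- function(g, offset) {
    list(gt = g,
         vfa = simulate_vfa(g, protocols$vfa, reseed(noise$vfa, offset)),
         ir = simulate_ir(g, protocols$ir, reseed(noise$ir, offset + 7L)),
         bs = simulate_bs_pair(g, protocols$pulse, reseed(noise$bs, offset + 13L)))
  }
  list(session1 = session(gt, 0L), session2 = session(gt2, 101L))
}
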