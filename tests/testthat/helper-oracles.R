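# Shared fixtures and independent oracles used across the suite.

GAMMA <- 42.577  # 1H gyromagnetic ratio, Hz/uT

# Analytic far-off-resonance Bloch-Siegert phase for a constant pulse:
# phi = omega1^2 / (2 * omega_off) * T, with omega1 = 2*pi*gamma*b1.
analytic_bs_phase <- function(b1_ut, offset_hz, duration_ms) {
  (2 * pi * GAMMA * b1_ut)^2 / (2 * 2 * pi * offset_hz) * duration_ms / 1000
}

# The spec's far-off-resonance constant-pulse example violates the
# pulse_spec 10x-Rabi regime invariant on purpose, so building it warns.
constant_pulse_10ut <- function() {
  suppressWarnings(pulse_spec(duration_ms = 2, shape = "constant",
                              offset_hz = 4000, b1_rms_ut = 10))
}

# A comfortably in-regime constant pulse for quadratic-law checks
# (offset = 8000 Hz >= 20 * gamma * b1 for b1 <= ~9.4 uT).
constant_pulse_far <- function(b1_rms_ut = 2) {
  pulse_spec(duration_ms = 2, shape = "constant", offset_hz = 8000,
             b1_rms_ut = b1_rms_ut)
}

# Single-voxel ground truth wrapper for signal-level tests.
uniform_gel_gt <- function(t1_ms, s0 = 1, f = 1, n = 16) {
  spec <- phantom_spec("gel_tubes", grid_shape = c(n, n, 1),
                       tube_t1_ms = t1_ms, s0 = s0,
                       b1_field = "linear_lr", b1_range = c(f, f))
  make_gel_phantom(spec)
}

# Independent per-voxel grid-search oracle for the VFA model: exhaustive
# scan over a fine T1 grid with the optimal S0 given T1 in closed form.
vfa_grid_search <- function(y, alpha_deg, tr_ms, f = 1,
                            t1_grid = seq(100, 4000, by = 0.5)) {
  a <- f * alpha_deg * pi / 180
  best_t1 <- NA_real_; best_rss <- Inf
  for (t1 in t1_grid) {
    e1 <- exp(-tr_ms / t1)
    g <- sin(a) * (1 - e1) / (1 - e1 * cos(a))
    s0 <- sum(g * y) / sum(g * g)
    rss <- sum((s0 * g - y)^2)
    if (rss < best_rss) { best_rss <- rss; best_t1 <- t1 }
  }
  best_t1
}

expect_rel_equal <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol * abs(expected)),
              label = sprintf("max rel err %.3g vs tol %.3g",
                              max(abs(object - expected) / abs(expected)), tol))
}
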