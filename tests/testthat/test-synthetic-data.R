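# Phantom generators and forward simulation.

test_that("gel phantom carries the IR-measured tube T1 values", {
  gt <- make_gel_phantom()
  truths <- c(322, 328, 835, 843, 1004, 1478, 1500, 1558)
  expect_equal(gt$spec$tube_t1_ms, truths)
  for (k in seq_along(truths)) {
    m <- gt_mask(gt, paste0("tube_", k))
    expect_gt(sum(m), 0)
    expect_true(all(gt$t1_true$data[m] == truths[k]))
  }
})

test_that("tube masks are pairwise disjoint with positive counts (brute force)", {
  gt <- make_gel_phantom()
  masks <- lapply(1:8, function(k) gt_mask(gt, paste0("tube_", k)))
  # exhaustive voxel scan: each foreground voxel belongs to exactly one tube
  counts <- Reduce(`+`, lapply(masks, function(m) as.integer(m)))
  expect_true(all(counts %in% c(0L, 1L)))
  expect_true(all(vapply(masks, sum, integer(1)) > 0))
  expect_equal(sum(counts), sum(gt_mask(gt, "foreground")))
})

test_that("single tube with uniform field gives f_true = 1 everywhere on it", {
  spec <- phantom_spec("gel_tubes", tube_t1_ms = 1000,
                       b1_field = "uniform", b1_range = c(1, 1))
  gt <- make_gel_phantom(spec)
  fg <- gt_mask(gt, "foreground")
  expect_true(all(gt$f_true[fg] == 1))
  expect_true(all(gt$f_true[!fg] == 0))
})

test_that("breast phantom takes exactly the two tissue T1 values on foreground", {
  gt <- make_breast_phantom(phantom_spec("breast"), seed = 4)
  fg <- gt_mask(gt, "foreground")
  expect_setequal(unique(gt$t1_true$data[fg]), c(420, 1290))
  expect_true(all(gt$t1_true$data[gt_mask(gt, "AT")] == 420))
  expect_true(all(gt$t1_true$data[gt_mask(gt, "FGT")] == 1290))
  expect_true(all(gt$t1_true$data[!fg] == 0))
  # f_min = f_max = 1 -> f_true identically 1 on foreground
  gt1 <- make_breast_phantom(phantom_spec("breast", b1_range = c(1, 1)), seed = 4)
  expect_true(all(gt1$f_true[gt_mask(gt1, "foreground")] == 1))
})

test_that("linear_lr field hits its endpoints at the lateral edge columns", {
  spec <- phantom_spec("breast", b1_field = "linear_lr", b1_range = c(0.8, 1.1))
  f <- bst1map:::eval_b1_field(spec)
  expect_lt(max(abs(f[, 1, ] - 0.8)), 1e-9)
  expect_lt(max(abs(f[, dim(f)[2], ] - 1.1)), 1e-9)
  # interior strictly between, monotone across columns
  expect_true(all(diff(f[1, , 1]) > 0))
})

test_that("noiseless VFA signals match closed forms and a hand evaluation", {
  # T1 = TR, alpha = 90, f = 1, S0 = 1 -> S = 1 - exp(-1)
  expect_equal(spgr_signal(7.9, 1, 90, 1, 7.9), 1 - exp(-1), tolerance = 1e-12)
  # hand evaluation of the model at T1 = 1000 ms, TR = 7.9 ms, alpha = 10 deg
  e1 <- exp(-7.9 / 1000); a <- 10 * pi / 180
  hand <- sin(a) * (1 - e1) / (1 - e1 * cos(a))
  gt <- uniform_gel_gt(1000)
  ser <- simulate_vfa(gt, vfa_protocol(flip_angles_deg = c(5, 10, 15)))
  fg <- gt_mask(gt, "foreground")
  expect_equal(unique(ser$volumes[[2]]$data[fg]), hand, tolerance = 1e-12)
  # alpha = 0 rejected by the series invariant
  expect_error(simulate_vfa(gt, vfa_protocol(flip_angles_deg = c(0, 5, 10))),
               "\\(0, 90\\]")
})

test_that("noiseless IR signals match closed forms and the nulling oracle", {
  # TI = 10000 >> T1 = 400 and TD = 2500 -> S -> S0 within 1e-9 relative
  expect_equal(ir_signal(400, 1, 10000, 2500), 1, tolerance = 1e-9)
  # classic null: alpha = 180, TD >> T1 -> zero at TI = T1 * ln 2
  expect_lt(ir_signal(1000, 1, 1000 * log(2), 1e9), 1e-12)
  # finite predelay: null at TI = T1 * ln(2 - exp(-TD/T1)), found independently
  t1 <- 1300; td <- 2500
  root <- uniroot(function(ti) {
    v <- exp(-ti / t1)
    -1 * (1 - exp(-td / t1)) * v + 1 - v  # signed model, alpha = 180
  }, c(1, 5000), tol = 1e-10)$root
  expect_equal(root, t1 * log(2 - exp(-td / t1)), tolerance = 1e-8)
  expect_lt(ir_signal(t1, 1, root, td), 1e-9)
})

test_that("background phase difference is zero and f = 1 foreground is uniform", {
  gt <- uniform_gel_gt(1000, f = 1)
  pair <- simulate_bs_pair(gt, constant_pulse_far())
  pd <- phase_difference(pair)$data
  fg <- gt_mask(gt, "foreground")
  expect_true(all(is.na(pd[!fg])))  # zero magnitude -> no defined phase
  expect_equal(diff(range(pd[fg])), 0)
})

test_that("doubling f_true quadruples the phase difference within 2%", {
  pulse <- constant_pulse_far(b1_rms_ut = 1)
  g1 <- uniform_gel_gt(1000, f = 1)
  g2 <- uniform_gel_gt(1000, f = 2)
  p1 <- phase_difference(simulate_bs_pair(g1, pulse))$data
  p2 <- phase_difference(simulate_bs_pair(g2, pulse))$data
  fg <- gt_mask(g1, "foreground")
  ratio <- unique(p2[fg]) / unique(p1[fg])
  expect_lt(abs(ratio - 4) / 4, 0.02)
})

test_that("Rician background magnitude mean is sigma * sqrt(pi/2) within 5%", {
  spec <- phantom_spec("gel_tubes", grid_shape = c(128, 128, 1))
  gt <- make_gel_phantom(spec)
  ser <- simulate_vfa(gt, vfa_protocol(flip_angles_deg = c(5, 10, 15)),
                      noise_spec("rician", sigma = 0.02, seed = 11))
  bg <- !gt_mask(gt, "foreground")
  expect_gte(sum(bg), 1e4)
  m <- mean(ser$volumes[[1]]$data[bg])
  expect_lt(abs(m - 0.02 * sqrt(pi / 2)) / (0.02 * sqrt(pi / 2)), 0.05)
})

test_that("generators and simulators are pure functions of (inputs, seed)", {
  spec <- phantom_spec("breast")
  a <- make_breast_phantom(spec, seed = 3)
  b <- make_breast_phantom(spec, seed = 3)
  expect_identical(a$labels, b$labels)
  ns <- noise_spec("rician", 0.01, seed = 9)
  s1 <- simulate_vfa(a, vfa_protocol(), ns)
  s2 <- simulate_vfa(b, vfa_protocol(), ns)
  expect_identical(lapply(s1$volumes, `[[`, "data"),
                   lapply(s2$volumes, `[[`, "data"))
  s3 <- simulate_vfa(a, vfa_protocol(), noise_spec("rician", 0.01, seed = 10))
  expect_false(identical(s1$volumes[[1]]$data, s3$volumes[[1]]$data))
  # simulation must not disturb the caller's RNG stream
  set.seed(123); before <- .Random.seed
  invisible(simulate_ir(a, ir_protocol(), ns))
  expect_identical(.Random.seed, before)
})

test_that("test-retest bundles honor jitter, seeding, and session fields", {
  gt <- make_breast_phantom(phantom_spec("breast"), seed = 2)
  protos <- list(vfa = vfa_protocol(flip_angles_deg = c(5, 10, 15)),
                 ir = ir_protocol(ti_ms = c(100, 500, 1000, 4000)),
                 pulse = constant_pulse_far())
  # jitter 0, no noise -> sessions voxel-identical
  tr0 <- simulate_testretest(gt, protos, noise_spec("none", 0))
  expect_identical(tr0$session1$vfa$volumes[[1]]$data,
                   tr0$session2$vfa$volumes[[1]]$data)
  # same seed -> bit-identical bundles; different seed -> different noise
  n1 <- noise_spec("rician", 0.01, seed = 5)
  trA <- simulate_testretest(gt, protos, n1)
  trB <- simulate_testretest(gt, protos, n1)
  expect_identical(trA$session1$ir$volumes[[1]]$data,
                   trB$session1$ir$volumes[[1]]$data)
  trC <- simulate_testretest(gt, protos, noise_spec("rician", 0.01, seed = 6))
  expect_false(identical(trA$session1$ir$volumes[[1]]$data,
                         trC$session1$ir$volumes[[1]]$data))
  # the two sessions of one bundle carry independent noise
  expect_false(identical(trA$session1$ir$volumes[[1]]$data,
                         trA$session2$ir$volumes[[1]]$data))
  # jitter translates session 2's ground truth
  trJ <- simulate_testretest(gt, protos, noise_spec("none", 0), jitter = c(2, 1))
  expect_identical(trJ$session2$gt$labels[3:10, 4:10, 1],
                   gt$labels[1:8, 3:9, 1])
  expect_error(simulate_testretest(gt, protos, noise_spec("none", 0),
                                   jitter = c(1000, 0)), "jitter")
})

test_that("SNR-calibrated per-tube VFA T1 SDs are the order of the printed SDs", {
  # Monte-Carlo under the calibrated noise: per-tube SDs of fitted VFA T1
  # should be tens of ms (printed SDs run 8..87 ms), not ~1 ms or ~1000 ms.
  gt <- make_gel_phantom(phantom_spec("gel_tubes", b1_range = c(1, 1)))
  noise <- acquisition_noise(gt, list(vfa = vfa_protocol(), ir = ir_protocol()),
                             snr = 50, seed = 21)
  ser <- simulate_vfa(gt, vfa_protocol(), noise$vfa)
  fit <- fit_vfa(ser)
  sds <- vapply(1:8, function(k) {
    roi_mean(fit, gt_mask(gt, paste0("tube_", k)))$sd_t1_ms
  }, numeric(1))
  expect_true(all(sds > 1), info = paste(round(sds, 1), collapse = ", "))
  expect_true(all(sds < 300), info = paste(round(sds, 1), collapse = ", "))
})
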