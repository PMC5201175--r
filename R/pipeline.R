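#' Default study pulse protocol
#'
#' The phase-imparting pulse used by the study runners: a 2 ms Fermi pulse at
#' the acquisition's 2.29 uT RMS amplitude, with a 1.5 kHz offset. At this
#' amplitude the RMS Rabi frequency is about 97.5 Hz, so a 1.5 kHz offset
#' keeps a 15x margin on the pure-phase regime while accruing enough phase
#' (about 0.08 rad pair difference at nominal B1) for the correction factors
#' to be recovered reliably from noisy images; the generic [pulse_spec()]
#' default keeps the more conservative 8 kHz offset.
#'
#' @param offset_hz,b1_rms_ut,duration_ms Override individual fields.
#' @return A [pulse_spec()].
#' @export
study_pulse <- function(offset_hz = 1500, b1_rms_ut = 2.29, duration_ms = 2) {
  pulse_spec(duration_ms = duration_ms, shape = "fermi",
             offset_hz = offset_hz, b1_rms_ut = b1_rms_ut)
}

# Derive the correction map for one simulated session.
session_correction_map <- function(bs, lookup, body_mask,
                                   nominal_b1_ut = lookup$pulse$b1_rms_ut) {
  ph <- phase_difference(bs)
  correction_map_from_phase(lookup, ph, nominal_b1_ut = nominal_b1_ut,
                            mask = body_mask, smooth = "polyfit", degree = 2)
}

write_study_outputs <- function(outdir, tables, maps, config, seed) {
  if (is.null(outdir)) return(invisible(NULL))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]], file.path(outdir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  for (nm in names(maps)) {
    m <- maps[[nm]]
    vol <- if (inherits(m, "t1_map")) {
      image_volume(ifelse(m$valid_mask, m$t1_ms, 0), m$voxel_size_mm,
                   series_id = nm)
    } else if (inherits(m, "correction_factor_map")) {
      image_volume(ifelse(is.finite(m$f), m$f, 0), c(1, 1, 1), series_id = nm)
    } else m
    write_volume(vol, file.path(outdir, paste0(nm, ".nii.gz")))
  }
  manifest <- list(config = config, seed = seed,
                   config_hash = rlang::hash(list(config, seed)),
                   package_version = as.character(utils::packageVersion("bst1map")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Run the gel-phantom accuracy study
#'
#' Simulates (or accepts) VFA, IR, and Bloch-Siegert acquisitions of the
#' 8-tube gel phantom, fits the three T1 maps (IR gold standard, uncorrected
#' VFA, B1-corrected VFA), summarizes each tube ROI, and reports per-tube
#' means, SDs and percent errors in the layout of the phantom accuracy table.
#'
#' @param spec A gel-tube [phantom_spec()].
#' @param pulse A [pulse_spec()]; defaults to [study_pulse()].
#' @param snr Target image SNR for all series (see [acquisition_noise()]);
#'   `Inf` runs noiselessly.
#' @param seed Seed for all randomness.
#' @param options [fit_options()].
#' @param outdir Optional output directory for CSV tables, NIfTI maps and a
#'   reproducibility manifest.
#' @return List with `table` (per-tube tibble), `maps` (the three [t1_map()]s
#'   and the correction map), and `gt`.
#' @export
run_phantom_study <- function(spec = phantom_spec("gel_tubes"),
                              pulse = study_pulse(),
                              snr = 50, seed = 1L,
                              options = fit_options(),
                              outdir = NULL) {
  gt <- make_gel_phantom(spec)
  fg <- gt_mask(gt, "foreground")
  protos <- list(vfa = vfa_protocol(), ir = ir_protocol())
  noise <- acquisition_noise(gt, protos, snr = snr, seed = seed)
  vfa <- simulate_vfa(gt, protos$vfa, noise$vfa)
  ir <- simulate_ir(gt, protos$ir, noise$ir)
  bs <- simulate_bs_pair(gt, pulse, noise$bs)
  lookup <- build_lookup_table(pulse)
  f_map <- session_correction_map(bs, lookup, fg)
  map_ir <- fit_ir(ir, options)
  map_vfa <- fit_vfa(vfa, NULL, options)
  map_vfa_b1 <- fit_vfa(vfa, f_map, options)
  tubes <- grep("^tube_", gt$levels, value = TRUE)
  rows <- purrr::map_dfr(tubes, function(tb) {
    m <- gt_mask(gt, tb)
    s_ir <- roi_mean(map_ir, m, tb)
    s_v <- roi_mean(map_vfa, m, tb)
    s_b <- roi_mean(map_vfa_b1, m, tb)
    tibble::tibble(
      tube = tb,
      t1_true_ms = gt$spec$tube_t1_ms[match(tb, tubes)],
      ir_mean_ms = s_ir$mean_t1_ms, ir_sd_ms = s_ir$sd_t1_ms,
      vfa_mean_ms = s_v$mean_t1_ms, vfa_sd_ms = s_v$sd_t1_ms,
      pct_err_vfa = percent_error(s_v$mean_t1_ms, s_ir$mean_t1_ms),
      vfa_b1_mean_ms = s_b$mean_t1_ms, vfa_b1_sd_ms = s_b$sd_t1_ms,
      pct_err_vfa_b1 = percent_error(s_b$mean_t1_ms, s_ir$mean_t1_ms))
  })
  maps <- list(t1_ir = map_ir, t1_vfa = map_vfa, t1_vfa_b1 = map_vfa_b1,
               f_map = f_map)
  write_study_outputs(outdir, list(phantom_table = rows), maps,
                      config = list(spec = unclass(spec),
                                    pulse = unclass(pulse), snr = snr),
                      seed = seed)
  list(table = rows, maps = maps, gt = gt)
}

# Measure one simulated session: segmentation from the IR nulling image, the
# three fits, and per-tissue ROI means.
measure_session <- function(sess, lookup, ir_proto, options,
                            null_ti_ms = 500) {
  body <- sess$gt$labels > 0L
  null_idx <- which.min(abs(ir_proto$ti_ms - null_ti_ms))
  at <- segment_adipose(sess$ir$volumes[[null_idx]], body)
  fgt <- segment_fibroglandular(at, body)
  masks <- tissue_masks(at, fgt, body)
  f_map <- session_correction_map(sess$bs, lookup, body)
  map_ir <- fit_ir(sess$ir, options)
  map_vfa <- fit_vfa(sess$vfa, NULL, options)
  map_b1 <- fit_vfa(sess$vfa, f_map, options)
  tiss <- function(mask, roi) {
    dplyr::bind_rows(roi_mean(map_ir, mask, roi),
                     roi_mean(map_vfa, mask, roi),
                     roi_mean(map_b1, mask, roi))
  }
  list(summary = dplyr::bind_rows(tiss(masks$at_mask, "AT"),
                                  tiss(masks$fgt_mask, "FGT")),
       masks = masks, maps = list(IR = map_ir, VFA = map_vfa, VFA_B1 = map_b1))
}

#' Run the healthy test-retest cohort study
#'
#' Simulates a cohort of two-tissue breast phantoms, two sessions per subject
#' with independent noise, a small repositioning shift, and session-specific
#' left-right transmit ramps; segments each session from its IR nulling image;
#' fits IR, uncorrected VFA and B1-corrected VFA maps; and produces the
#' accuracy report (percent error, CCC, subject-level bootstrap) and the
#' test-retest reproducibility report per tissue.
#'
#' Subjects without appreciable fibroglandular tissue (`n_without_fgt`) keep
#' their adipose measurements but are excluded from the fibroglandular
#' analyses, mirroring the bookkeeping of mixed-composition cohorts.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_without_fgt Subjects excluded from the fibroglandular analyses.
#' @param seed Master seed; all subject/session randomness derives from it.
#' @param snr Target image SNR for every series (see [acquisition_noise()]).
#' @param b1_range Baseline transmit ramp `c(f_min, f_max)`.
#' @param b1_session_jitter Half-range of the uniform perturbation applied to
#'   each session's ramp endpoints.
#' @param jitter In-plane translation of session 2, voxels.
#' @param grid_shape Phantom grid.
#' @param pulse A [pulse_spec()].
#' @param options [fit_options()].
#' @param n_boot Bootstrap resamples for the accuracy report.
#' @param outdir Optional output directory.
#' @param verbose Log per-tissue record counts.
#' @return List with `cohort` (long tibble of per-session ROI means),
#'   `accuracy` (per tissue), `bootstrap` (per tissue), `repro` (per tissue
#'   and method), and `counts`.
#' @export
run_cohort_study <- function(n_subjects = 16, n_without_fgt = 3, seed = 1L,
                             snr = 50,
                             b1_range = c(0.8, 1.1),
                             b1_session_jitter = 0.05,
                             jitter = c(1L, 0L),
                             grid_shape = c(48, 48, 1),
                             pulse = study_pulse(),
                             options = fit_options(),
                             n_boot = 1000,
                             outdir = NULL, verbose = FALSE) {
  if (n_subjects < 2) stop("reproducibility needs at least 2 subjects",
                           call. = FALSE)
  stopifnot(n_without_fgt >= 0, n_without_fgt <= n_subjects)
  lookup <- build_lookup_table(pulse)
  draws <- with_preserved_seed(seed, {
    list(at_t1 = stats::rnorm(n_subjects, 420, 25),
         fgt_t1 = stats::rnorm(n_subjects, 1290, 90),
         d1 = matrix(stats::runif(2 * n_subjects, -b1_session_jitter,
                                  b1_session_jitter), ncol = 2),
         d2 = matrix(stats::runif(2 * n_subjects, -b1_session_jitter,
                                  b1_session_jitter), ncol = 2))
  })
  ir_proto <- ir_protocol()
  cohort <- purrr::map_dfr(seq_len(n_subjects), function(i) {
    spec <- phantom_spec("breast", grid_shape = grid_shape,
                         tissue_t1_ms = c(AT = draws$at_t1[i],
                                          FGT = draws$fgt_t1[i]),
                         b1_range = b1_range + draws$d1[i, ])
    gt <- make_breast_phantom(spec, seed = seed + 1000L + i)
    protos <- list(vfa = vfa_protocol(), ir = ir_proto, pulse = pulse)
    tr <- simulate_testretest(
      gt, protocols = protos,
      noise = acquisition_noise(gt, protos, snr = snr,
                                seed = seed + 1000L * i),
      jitter = jitter,
      b1_range_session2 = b1_range + draws$d2[i, ])
    purrr::map_dfr(1:2, function(s) {
      ms <- measure_session(tr[[s]], lookup, ir_proto, options)
      dplyr::mutate(ms$summary, subject_id = i, session = s, .before = 1)
    })
  })
  has_fgt <- cohort$subject_id > n_without_fgt | cohort$roi != "FGT"
  cohort <- cohort[has_fgt, ]
  wide <- tidyr::pivot_wider(
    dplyr::select(cohort, "subject_id", "session", "roi", "method",
                  "mean_t1_ms"),
    names_from = "method", values_from = "mean_t1_ms")
  counts <- dplyr::count(dplyr::distinct(wide, .data$subject_id,
                                         .data$session, .data$roi),
                         .data$roi, name = "n_records")
  if (verbose) {
    for (k in seq_len(nrow(counts))) {
      message(sprintf("%s: %d T1 values (%d subjects x 2 sessions)",
                      counts$roi[k], counts$n_records[k],
                      counts$n_records[k] / 2L))
    }
  }
  acc_list <- lapply(split(wide, wide$roi), function(w) {
    paired <- tibble::tibble(subject_id = w$subject_id,
                             vfa_t1_ms = w$VFA, vfa_b1_t1_ms = w$VFA_B1,
                             ir_t1_ms = w$IR)
    accuracy_report(paired, n_boot = n_boot, seed = seed)
  })
  accuracy <- purrr::map_dfr(names(acc_list), function(r) {
    dplyr::mutate(acc_list[[r]], roi = r, .before = 1)
  })
  bootstrap <- purrr::map_dfr(names(acc_list), function(r) {
    dplyr::mutate(glance_accuracy(acc_list[[r]]), roi = r, .before = 1)
  })
  repro <- purrr::map_dfr(split(wide, wide$roi), function(w) {
    ws <- tidyr::pivot_wider(w, id_cols = "subject_id",
                             names_from = "session",
                             values_from = c("VFA", "VFA_B1"))
    dplyr::bind_rows(
      repro_report(ws$VFA_1, ws$VFA_2, roi = w$roi[1], method = "VFA"),
      repro_report(ws$VFA_B1_1, ws$VFA_B1_2, roi = w$roi[1],
                   method = "VFA_B1"))
  })
  write_study_outputs(outdir,
                      list(cohort = cohort, accuracy = accuracy,
                           bootstrap = bootstrap, reproducibility = repro),
                      maps = list(),
                      config = list(n_subjects = n_subjects,
                                    n_without_fgt = n_without_fgt,
                                    snr = snr,
                                    b1_range = b1_range,
                                    b1_session_jitter = b1_session_jitter,
                                    jitter = jitter,
                                    grid_shape = grid_shape,
                                    pulse = unclass(pulse)),
                      seed = seed)
  list(cohort = cohort, accuracy = accuracy, bootstrap = bootstrap,
       repro = repro, counts = counts)
}

#' Run the patient ROI illustration study
#'
#' Adds a circular tumor to the breast phantom, simulates one session, and
#' reports per-ROI (tumor, adipose, fibroglandular) mean T1, SD, and percent
#' error versus the IR gold standard for the uncorrected and B1-corrected VFA
#' maps, in the layout of the patient table.
#'
#' @param tumor_t1_ms Ground-truth tumor T1, ms.
#' @param tumor_radius_frac Tumor radius as a fraction of the grid.
#' @param spec A breast [phantom_spec()].
#' @param roi_masks Optional named list of logical masks (`tumor`, `AT`,
#'   `FGT`) overriding the synthetic ground-truth ROIs (the route for
#'   externally drawn ROIs).
#' @param pulse,snr,options,outdir,seed As in [run_phantom_study()].
#' @return List with `table` (per-ROI tibble), `maps`, and `gt`.
#' @export
run_patient_study <- function(tumor_t1_ms = 1364, tumor_radius_frac = 0.08,
                              spec = phantom_spec("breast"),
                              roi_masks = NULL,
                              pulse = study_pulse(),
                              snr = 50,
                              options = fit_options(),
                              outdir = NULL, seed = 1L) {
  gt <- make_breast_phantom(spec, seed = seed)
  d <- dim(gt$labels)
  rr <- matrix(seq_len(d[1]), d[1], d[2])
  cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  tum2d <- (rr - d[1] * 0.45)^2 + (cc - d[2] * 0.55)^2 <=
    (tumor_radius_frac * min(d[1:2]))^2
  tumor <- array(FALSE, d)
  for (s in seq_len(d[3])) tumor[, , s] <- tum2d & gt$labels[, , s] > 0L
  if (!is.null(roi_masks)) {
    if (is.null(roi_masks$tumor) || !any(roi_masks$tumor)) {
      stop("tumor ROI mask is empty", call. = FALSE)
    }
  } else if (!any(tumor)) {
    stop("tumor ROI mask is empty", call. = FALSE)
  }
  gt$labels[tumor] <- 3L
  gt$levels <- c(gt$levels, "tumor")
  gt$t1_true$data[tumor] <- tumor_t1_ms
  gt$s0_true$data[tumor] <- 0.9
  body <- gt$labels > 0L
  protos <- list(vfa = vfa_protocol(), ir = ir_protocol())
  noise <- acquisition_noise(gt, protos, snr = snr, seed = seed)
  vfa <- simulate_vfa(gt, protos$vfa, noise$vfa)
  ir <- simulate_ir(gt, protos$ir, noise$ir)
  bs <- simulate_bs_pair(gt, pulse, noise$bs)
  lookup <- build_lookup_table(pulse)
  f_map <- session_correction_map(bs, lookup, body)
  map_ir <- fit_ir(ir, options)
  map_vfa <- fit_vfa(vfa, NULL, options)
  map_b1 <- fit_vfa(vfa, f_map, options)
  masks <- roi_masks %||% list(tumor = gt_mask(gt, "tumor"),
                               AT = gt_mask(gt, "AT"),
                               FGT = gt_mask(gt, "FGT"))
  rows <- purrr::map_dfr(names(masks), function(r) {
    m <- masks[[r]]
    if (!any(m)) stop("ROI mask '", r, "' is empty", call. = FALSE)
    s_ir <- roi_mean(map_ir, m, r)
    s_v <- roi_mean(map_vfa, m, r)
    s_b <- roi_mean(map_b1, m, r)
    tibble::tibble(roi = r,
                   ir_mean_ms = s_ir$mean_t1_ms, ir_sd_ms = s_ir$sd_t1_ms,
                   vfa_mean_ms = s_v$mean_t1_ms, vfa_sd_ms = s_v$sd_t1_ms,
                   pct_err_vfa = percent_error(s_v$mean_t1_ms, s_ir$mean_t1_ms),
                   vfa_b1_mean_ms = s_b$mean_t1_ms, vfa_b1_sd_ms = s_b$sd_t1_ms,
                   pct_err_vfa_b1 = percent_error(s_b$mean_t1_ms,
                                                  s_ir$mean_t1_ms))
  })
  maps <- list(t1_ir = map_ir, t1_vfa = map_vfa, t1_vfa_b1 = map_b1,
               f_map = f_map)
  write_study_outputs(outdir, list(patient_table = rows), maps,
                      config = list(tumor_t1_ms = tumor_t1_ms,
                                    spec = unclass(spec),
                                    pulse = unclass(pulse), snr = snr),
                      seed = seed)
  list(table = rows, maps = maps, gt = gt)
}
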