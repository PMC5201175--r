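#' Variable flip angle (SPGR) series
#'
#' Ordered spoiled-gradient-echo magnitude volumes, one per flip angle, with
#' the fixed TR/TE of the acquisition. Flip angles must be strictly increasing
#' and lie in (0, 90] degrees.
#'
#' @param volumes List of [image_volume()]s, one per flip angle, same grid.
#' @param flip_angles_deg Strictly increasing flip angles, degrees.
#' @param tr_ms Repetition time, ms.
#' @param te_ms Echo time, ms (carried for provenance; the signal model takes
#'   TE much shorter than T2*).
#' @return An object of class `vfa_series`.
#' @export
vfa_series <- function(volumes, flip_angles_deg, tr_ms, te_ms = NA_real_) {
  check_volume_list(volumes, length(flip_angles_deg), "flip angles")
  flip_angles_deg <- as.numeric(flip_angles_deg)
  if (any(!is.finite(flip_angles_deg)) || any(flip_angles_deg <= 0) ||
      any(flip_angles_deg > 90)) {
    stop("flip angles must lie in (0, 90] degrees", call. = FALSE)
  }
  if (any(diff(flip_angles_deg) <= 0)) {
    stop("flip angles must be strictly increasing", call. = FALSE)
  }
  if (!is.finite(tr_ms) || tr_ms <= 0) stop("tr_ms must be > 0", call. = FALSE)
  structure(list(volumes = volumes, flip_angles_deg = flip_angles_deg,
                 tr_ms = tr_ms, te_ms = te_ms),
            class = "vfa_series")
}

#' Inversion recovery series
#'
#' Ordered IR-TSE magnitude volumes, one per inversion time, with the predelay
#' and inversion pulse flip angle of the preparation.
#'
#' @param volumes List of [image_volume()]s, one per TI, same grid.
#' @param ti_ms Strictly increasing positive inversion times, ms.
#' @param td_ms Predelay before the inversion pulse, ms.
#' @param inv_flip_deg Inversion pulse flip angle, degrees (nominally 180).
#' @return An object of class `ir_series`.
#' @export
ir_series <- function(volumes, ti_ms, td_ms, inv_flip_deg = 180) {
  check_volume_list(volumes, length(ti_ms), "inversion times")
  ti_ms <- as.numeric(ti_ms)
  if (any(!is.finite(ti_ms)) || any(ti_ms <= 0)) {
    stop("inversion times must be positive", call. = FALSE)
  }
  if (any(diff(ti_ms) <= 0)) {
    stop("inversion times must be strictly increasing", call. = FALSE)
  }
  if (!is.finite(td_ms) || td_ms <= 0) stop("td_ms must be > 0", call. = FALSE)
  structure(list(volumes = volumes, ti_ms = ti_ms, td_ms = td_ms,
                 inv_flip_deg = inv_flip_deg),
            class = "ir_series")
}

#' Bloch-Siegert phase-image pair
#'
#' Complex images acquired with the off-resonant phase-imparting pulse applied
#' at opposite frequency offsets; the phase difference of the pair isolates the
#' Bloch-Siegert shift.
#'
#' @param img_plus,img_minus Complex [image_volume()]s at the +/- offsets.
#' @param offset_hz Positive nominal frequency offset, Hz.
#' @return An object of class `bs_phase_pair`.
#' @export
bs_phase_pair <- function(img_plus, img_minus, offset_hz) {
  stopifnot(is_image_volume(img_plus), is_image_volume(img_minus))
  if (!img_plus$is_complex || !img_minus$is_complex) {
    stop("both images of a Bloch-Siegert pair must be complex", call. = FALSE)
  }
  if (!identical(dim(img_plus$data), dim(img_minus$data))) {
    stop("Bloch-Siegert pair shapes do not match", call. = FALSE)
  }
  if (!is.finite(offset_hz) || offset_hz <= 0) {
    stop("offset_hz must be > 0", call. = FALSE)
  }
  structure(list(img_plus = img_plus, img_minus = img_minus,
                 offset_hz = offset_hz),
            class = "bs_phase_pair")
}

check_volume_list <- function(volumes, n, what) {
  if (!is.list(volumes) || !all(vapply(volumes, is_image_volume, logical(1)))) {
    stop("`volumes` must be a list of image_volume objects", call. = FALSE)
  }
  if (length(volumes) != n) {
    stop(sprintf("volume count (%d) does not match number of %s (%d)",
                 length(volumes), what, n), call. = FALSE)
  }
  dims <- lapply(volumes, function(v) dim(v$data))
  if (length(unique(dims)) > 1L) {
    stop("all volumes in a series must share one grid", call. = FALSE)
  }
  invisible(TRUE)
}

#' Assemble a series from volumes plus metadata
#'
#' Dispatches on the metadata fields: `flip_angles_deg` builds a [vfa_series()],
#' `ti_ms` an [ir_series()], and `offset_hz` (with exactly two complex volumes)
#' a [bs_phase_pair()]. This is the entry point used when loading NIfTI stacks
#' with a JSON sidecar.
#'
#' @param volumes List of [image_volume()]s.
#' @param metadata Named list of acquisition metadata.
#' @return A validated series object.
#' @export
series_from_volumes <- function(volumes, metadata) {
  md <- metadata
  if (!is.null(md$flip_angles_deg)) {
    return(vfa_series(volumes, md$flip_angles_deg, tr_ms = md$tr_ms,
                      te_ms = md$te_ms %||% NA_real_))
  }
  if (!is.null(md$ti_ms)) {
    return(ir_series(volumes, md$ti_ms, td_ms = md$td_ms,
                     inv_flip_deg = md$inv_flip_deg %||% 180))
  }
  if (!is.null(md$offset_hz)) {
    if (length(volumes) != 2L) {
      stop("a Bloch-Siegert pair needs exactly two volumes", call. = FALSE)
    }
    return(bs_phase_pair(volumes[[1]], volumes[[2]], md$offset_hz))
  }
  stop("metadata does not identify a VFA, IR, or Bloch-Siegert series",
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

series_grid_dim <- function(series) dim(series$volumes[[1]]$data)

# Stack a series' volumes into an (nvox x nvol) matrix of magnitudes.
series_matrix <- function(series) {
  vapply(series$volumes, function(v) as.vector(Mod(v$data)),
         numeric(prod(series_grid_dim(series))))
}

#' Per-voxel T1 map with fit diagnostics
#'
#' @param t1_ms,s0,rss Arrays on the source grid: fitted T1 (ms), amplitude,
#'   and residual sum of squares. Invalid voxels carry `NA` in `t1_ms`.
#' @param method One of `"VFA"`, `"VFA_B1"`, `"IR"`.
#' @param valid_mask Logical array marking voxels with a usable fit.
#' @param voxel_size_mm Voxel spacing, mm.
#' @return An object of class `t1_map`.
#' @export
t1_map <- function(t1_ms, s0, rss, method, valid_mask,
                   voxel_size_mm = c(1, 1, 1)) {
  method <- match.arg(method, c("VFA", "VFA_B1", "IR"))
  t1_ms <- promote_3d(t1_ms); s0 <- promote_3d(s0); rss <- promote_3d(rss)
  valid_mask <- promote_3d(valid_mask)
  stopifnot(identical(dim(t1_ms), dim(s0)),
            identical(dim(t1_ms), dim(valid_mask)))
  bad <- valid_mask & (!is.finite(t1_ms) | t1_ms <= 0)
  if (any(bad)) stop("valid voxels must carry finite positive T1", call. = FALSE)
  t1_ms[!valid_mask] <- NA_real_
  structure(list(t1_ms = t1_ms, s0 = s0, rss = rss, method = method,
                 valid_mask = valid_mask,
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "t1_map")
}

#' @export
print.t1_map <- function(x, ...) {
  v <- x$t1_ms[x$valid_mask]
  cat(sprintf("<t1_map> method %s  dims %s  valid %d/%d  median T1 %.0f ms\n",
              x$method, paste(dim(x$t1_ms), collapse = "x"),
              sum(x$valid_mask), length(x$valid_mask),
              if (length(v)) stats::median(v) else NA_real_))
  invisible(x)
}

#' Flip-angle correction factor map
#'
#' Per-voxel ratio `f` of actual to prescribed flip angle; `f = 1` is nominal
#' excitation. Voxels without a usable estimate carry `NA`.
#'
#' @param f Array of positive factors (`NA` where undefined).
#' @param pulse_id Identifier of the pulse/lookup used to derive the map.
#' @return An object of class `correction_factor_map`.
#' @export
correction_factor_map <- function(f, pulse_id = "") {
  f <- promote_3d(f)
  if (any(is.finite(f) & f <= 0)) {
    stop("correction factors must be > 0 wherever defined", call. = FALSE)
  }
  structure(list(f = f, pulse_id = as.character(pulse_id)),
            class = "correction_factor_map")
}
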