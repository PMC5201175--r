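#' Segment adipose tissue from the IR nulling image
#'
#' At an inversion time near the fibroglandular null the IR magnitude image is
#' bright in adipose tissue and dark in fibroglandular tissue, so a single
#' intensity threshold inside the body separates the two. The default strategy
#' is Otsu's threshold on the within-body intensities (delegated to
#' `EBImage::otsu`); the alternative thresholds at a fixed fraction of the
#' within-body maximum.
#'
#' @param ir_null_volume [image_volume()]: the IR magnitude image at the
#'   nulling TI (nominally 500 ms).
#' @param body_mask Logical array delimiting the body (skin and chest wall
#'   removed); defaults to all voxels.
#' @param strategy `"otsu"` or `"fraction"`.
#' @param fraction Threshold as a fraction of the within-body maximum, for
#'   `strategy = "fraction"`.
#' @return Logical adipose mask (subset of the body mask).
#' @export
segment_adipose <- function(ir_null_volume, body_mask = NULL,
                            strategy = c("otsu", "fraction"), fraction = 0.5) {
  stopifnot(is_image_volume(ir_null_volume))
  strategy <- match.arg(strategy)
  img <- Mod(ir_null_volume$data)
  if (is.null(body_mask)) body_mask <- array(TRUE, dim(img))
  body_mask <- promote_3d(body_mask)
  stopifnot(identical(dim(body_mask), dim(img)))
  if (!any(body_mask)) stop("body mask is empty", call. = FALSE)
  vals <- img[body_mask]
  lo <- min(vals); hi <- max(vals)
  if (hi <= 0 || hi - lo <= .Machine$double.eps * max(1, hi)) {
    stop("no adipose tissue detectable: nulling image has no contrast",
         call. = FALSE)
  }
  thr <- switch(strategy,
    otsu = {
      scaled <- (vals - lo) / (hi - lo)
      lo + (hi - lo) * EBImage::otsu(matrix(scaled, nrow = 1), range = c(0, 1))
    },
    fraction = fraction * hi
  )
  body_mask & img > thr
}

#' Segment fibroglandular tissue as the body complement of adipose
#'
#' @param at_mask Logical adipose mask.
#' @param body_mask Logical body mask (skin/chest wall excluded) on the same
#'   grid.
#' @return Logical fibroglandular mask, `body & !at`.
#' @export
segment_fibroglandular <- function(at_mask, body_mask) {
  at_mask <- promote_3d(at_mask); body_mask <- promote_3d(body_mask)
  if (!identical(dim(at_mask), dim(body_mask))) {
    stop("masks are on different grids", call. = FALSE)
  }
  body_mask & !at_mask
}

#' Validated adipose/fibroglandular/body mask bundle
#'
#' @param at_mask,fgt_mask,body_mask Logical arrays on one grid; adipose and
#'   fibroglandular must be disjoint and contained in the body.
#' @return An object of class `tissue_masks`.
#' @export
tissue_masks <- function(at_mask, fgt_mask, body_mask) {
  at_mask <- promote_3d(at_mask); fgt_mask <- promote_3d(fgt_mask)
  body_mask <- promote_3d(body_mask)
  stopifnot(identical(dim(at_mask), dim(fgt_mask)),
            identical(dim(at_mask), dim(body_mask)))
  if (any(at_mask & fgt_mask)) {
    stop("adipose and fibroglandular masks overlap", call. = FALSE)
  }
  if (any((at_mask | fgt_mask) & !body_mask)) {
    stop("tissue masks extend outside the body mask", call. = FALSE)
  }
  structure(list(at_mask = at_mask, fgt_mask = fgt_mask,
                 body_mask = body_mask),
            class = "tissue_masks")
}

#' Summarize a T1 map over a region of interest
#'
#' Mean and sample standard deviation of the fitted T1 over the valid voxels
#' of the mask; invalid fits are excluded, and an empty valid intersection is
#' an error rather than a silent `NaN`.
#'
#' @param t1_map A [t1_map()].
#' @param mask Logical array on the map grid.
#' @param roi Region label for the output row.
#' @return A one-row tibble: `roi`, `method`, `mean_t1_ms`, `sd_t1_ms`,
#'   `n_voxels`.
#' @export
roi_mean <- function(t1_map, mask, roi = "ROI") {
  stopifnot(inherits(t1_map, "t1_map"))
  mask <- promote_3d(mask)
  stopifnot(identical(dim(mask), dim(t1_map$t1_ms)))
  sel <- mask & t1_map$valid_mask
  if (!any(sel)) stop("no valid voxels in ROI '", roi, "'", call. = FALSE)
  v <- t1_map$t1_ms[sel]
  tibble::tibble(roi = roi, method = t1_map$method,
                 mean_t1_ms = mean(v),
                 sd_t1_ms = stats::sd(v),
                 n_voxels = length(v))
}
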