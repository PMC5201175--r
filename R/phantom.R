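#' Digital phantom specification
#'
#' Describes either the 8-tube gel phantom (Eurospin-style tubes submerged in
#' water, T1 spanning roughly 300-1600 ms) or a two-tissue breast phantom
#' (an adipose shell enclosing fibroglandular blobs), together with the
#' transmit-field pattern used as ground truth.
#'
#' @param kind `"gel_tubes"` or `"breast"`.
#' @param grid_shape Length-3 integer grid (rows, cols, slices), at least 8x8x1.
#' @param tube_t1_ms Gel tubes: per-tube T1, ms. Defaults to the IR-measured
#'   values of the eight tubes (322, 328, 835, 843, 1004, 1478, 1500, 1558).
#' @param tissue_t1_ms Breast: named `c(AT = , FGT = )` T1 values, ms.
#'   Defaults 420 (adipose) and 1290 (fibroglandular).
#' @param s0 Per-tube amplitude (gel, recycled) or named `c(AT = , FGT = )`
#'   amplitudes (breast).
#' @param b1_field `"uniform"`, `"linear_lr"` (left-right ramp across image
#'   columns), or `"polynomial"` (quadratic in the column coordinate).
#' @param b1_range `c(f_min, f_max)` of the correction-factor field; the
#'   default `c(0.8, 1.1)` mirrors the magnitude of left-right transmit
#'   variation seen in bilateral breast imaging at 3 T.
#' @param fgt_fraction Breast only: approximate fibroglandular fraction of the
#'   foreground, in (0, 1).
#' @param voxel_size_mm Voxel spacing, mm.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("gel_tubes", "breast"),
                         grid_shape = if (match.arg(kind) == "gel_tubes")
                           c(64, 64, 1) else c(48, 48, 1),
                         tube_t1_ms = c(322, 328, 835, 843, 1004, 1478, 1500, 1558),
                         tissue_t1_ms = c(AT = 420, FGT = 1290),
                         s0 = NULL,
                         b1_field = c("linear_lr", "uniform", "polynomial"),
                         b1_range = c(0.8, 1.1),
                         fgt_fraction = 0.3,
                         voxel_size_mm = c(1.33, 1.33, 4)) {
  kind <- match.arg(kind)
  b1_field <- match.arg(b1_field)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape[1:2] < 8L) || grid_shape[3] < 1L) {
    stop("grid must be at least 8x8x1", call. = FALSE)
  }
  if (kind == "gel_tubes") {
    if (any(tube_t1_ms <= 0)) stop("tube T1 values must be > 0", call. = FALSE)
    if (is.null(s0)) s0 <- rep(1, length(tube_t1_ms))
    s0 <- rep_len(s0, length(tube_t1_ms))
  } else {
    if (any(tissue_t1_ms <= 0)) stop("tissue T1 values must be > 0", call. = FALSE)
    if (!all(c("AT", "FGT") %in% names(tissue_t1_ms))) {
      stop("tissue_t1_ms must name AT and FGT", call. = FALSE)
    }
    if (is.null(s0)) s0 <- c(AT = 1, FGT = 0.8)
    if (!is.finite(fgt_fraction) || fgt_fraction <= 0 || fgt_fraction >= 1) {
      stop("fgt_fraction must lie in (0, 1)", call. = FALSE)
    }
  }
  if (b1_range[1] <= 0 || b1_range[2] < b1_range[1]) {
    stop("b1_range must be positive with f_min <= f_max", call. = FALSE)
  }
  structure(list(kind = kind, grid_shape = grid_shape,
                 tube_t1_ms = tube_t1_ms, tissue_t1_ms = tissue_t1_ms,
                 s0 = s0, b1_field = b1_field, b1_range = b1_range,
                 fgt_fraction = fgt_fraction, voxel_size_mm = voxel_size_mm),
            class = "phantom_spec")
}

# Evaluate the ground-truth correction-factor field on the full grid.
eval_b1_field <- function(spec) {
  d <- spec$grid_shape
  f <- array(1, d)
  if (spec$b1_field == "uniform" ||
      isTRUE(all.equal(spec$b1_range[1], spec$b1_range[2]))) {
    f[] <- spec$b1_range[1]
    if (spec$b1_field == "uniform") f[] <- mean(spec$b1_range)
    return(f)
  }
  x <- if (d[2] > 1) (seq_len(d[2]) - 1) / (d[2] - 1) else rep(0, d[2])
  prof <- switch(spec$b1_field,
    linear_lr = spec$b1_range[1] + diff(spec$b1_range) * x,
    polynomial = spec$b1_range[1] + diff(spec$b1_range) * x^2
  )
  aperm(array(prof, c(d[2], d[1], d[3])), c(2, 1, 3))
}

new_ground_truth <- function(t1, s0, f, labels, levels, spec) {
  fg <- labels > 0L
  stopifnot(all(t1[fg] > 0))
  structure(list(
    t1_true = image_volume(t1, spec$voxel_size_mm, series_id = "t1_true"),
    s0_true = image_volume(s0, spec$voxel_size_mm, series_id = "s0_true"),
    f_true = f,     # plain array; 0 outside the object (no spins, no shift)
    labels = labels, levels = levels, spec = spec),
    class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s  grid %s  regions: %s\n", x$spec$kind,
              paste(dim(x$labels), collapse = "x"),
              paste(x$levels[-1], collapse = ", ")))
  invisible(x)
}

#' Region mask of a ground-truth phantom
#'
#' @param gt A ground-truth object from [make_gel_phantom()] or
#'   [make_breast_phantom()].
#' @param region Region name as listed in `gt$levels` (e.g. `"tube_3"`,
#'   `"AT"`, `"FGT"`), or `"foreground"`.
#' @return Logical array.
#' @export
gt_mask <- function(gt, region) {
  if (region == "foreground") return(gt$labels > 0L)
  i <- match(region, gt$levels)
  if (is.na(i)) stop("unknown region: ", region, call. = FALSE)
  gt$labels == (i - 1L)
}

#' Generate the gel-tube phantom
#'
#' Lays out circular tubes (disjoint, background zero) on the grid, assigns
#' each tube its specified T1 and amplitude, and evaluates the ground-truth
#' transmit field.
#'
#' @param spec A [phantom_spec()] with `kind = "gel_tubes"`.
#' @return A `ground_truth` object with `t1_true`, `s0_true`, `f_true` and a
#'   labeled region array (`tube_1` ... in `levels`).
#' @export
make_gel_phantom <- function(spec = phantom_spec("gel_tubes")) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$kind != "gel_tubes") stop("spec is not a gel-tube phantom", call. = FALSE)
  d <- spec$grid_shape
  nt <- length(spec$tube_t1_ms)
  ncell <- ceiling(sqrt(nt))
  if (ncell * 2 + 1 > min(d[1:2])) {
    stop("more tubes than fit on the grid", call. = FALSE)
  }
  # tubes at the centers of an ncell x ncell cell layout
  cw <- d[1] / ncell; ch <- d[2] / ncell
  radius <- 0.32 * min(cw, ch)
  labels <- array(0L, d)
  rr <- matrix(seq_len(d[1]), d[1], d[2])
  cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  for (k in seq_len(nt)) {
    i <- (k - 1) %/% ncell; j <- (k - 1) %% ncell
    cy <- (i + 0.5) * cw + 0.5; cx <- (j + 0.5) * ch + 0.5
    disk <- (rr - cy)^2 + (cc - cx)^2 <= radius^2
    if (!any(disk)) stop("tube ", k, " does not fit on the grid", call. = FALSE)
    for (s in seq_len(d[3])) labels[, , s][disk] <- k
  }
  t1 <- array(0, d); s0 <- array(0, d)
  for (k in seq_len(nt)) {
    t1[labels == k] <- spec$tube_t1_ms[k]
    s0[labels == k] <- spec$s0[k]
  }
  f <- eval_b1_field(spec)
  f[labels == 0L] <- 0
  new_ground_truth(t1, s0, f, labels,
                   c("background", paste0("tube_", seq_len(nt))), spec)
}

#' Generate the two-tissue breast phantom
#'
#' Builds an elliptical adipose shell enclosing procedurally placed
#' fibroglandular blobs (volume fraction approximately `fgt_fraction`), with
#' zero background and the specified ground-truth transmit field. Geometry is
#' deterministic given the spec and `seed`.
#'
#' @param spec A [phantom_spec()] with `kind = "breast"`.
#' @param seed Integer controlling blob placement.
#' @return A `ground_truth` object with regions `AT` and `FGT`.
#' @export
make_breast_phantom <- function(spec = phantom_spec("breast"), seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$kind != "breast") stop("spec is not a breast phantom", call. = FALSE)
  d <- spec$grid_shape
  rr <- matrix(seq_len(d[1]), d[1], d[2])
  cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2
  ry <- 0.42 * d[1]; rx <- 0.42 * d[2]
  body2d <- ((rr - cy) / ry)^2 + ((cc - cx) / rx)^2 <= 1
  # fibroglandular blobs: union of ellipses around the body center
  fgt2d <- array(FALSE, d[1:2])
  n_blob <- 3L
  centers <- with_preserved_seed(seed, {
    cbind(cy + stats::runif(n_blob, -0.18, 0.18) * d[1],
          cx + stats::runif(n_blob, -0.18, 0.18) * d[2],
          stats::runif(n_blob, 0.7, 1.3))
  })
  # scale blob radii so the fibroglandular fraction approaches the target
  base_r <- sqrt(spec$fgt_fraction * sum(body2d) / (pi * n_blob))
  for (b in seq_len(n_blob)) {
    rb <- base_r * centers[b, 3]
    fgt2d <- fgt2d | ((rr - centers[b, 1])^2 + (cc - centers[b, 2])^2 <= rb^2)
  }
  fgt2d <- fgt2d & body2d
  if (!any(fgt2d) || !any(body2d & !fgt2d)) {
    stop("degenerate breast geometry: a tissue compartment is empty", call. = FALSE)
  }
  labels <- array(0L, d)
  for (s in seq_len(d[3])) {
    sl <- labels[, , s]
    sl[body2d & !fgt2d] <- 1L
    sl[fgt2d] <- 2L
    labels[, , s] <- sl
  }
  t1 <- array(0, d); s0 <- array(0, d)
  t1[labels == 1L] <- spec$tissue_t1_ms[["AT"]]
  t1[labels == 2L] <- spec$tissue_t1_ms[["FGT"]]
  s0[labels == 1L] <- spec$s0[["AT"]]
  s0[labels == 2L] <- spec$s0[["FGT"]]
  f <- eval_b1_field(spec)
  f[labels == 0L] <- 0
  new_ground_truth(t1, s0, f, labels, c("background", "AT", "FGT"), spec)
}

# Run `expr` under a given RNG seed without disturbing the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
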