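#' Image volume container
#'
#' A minimal carrier for a 2D/3D scalar or complex field with voxel spacing,
#' used by every pipeline stage. Data are stored as a 3D array indexed
#' `(row, col, slice)`, 1-based; 2D input is promoted to a single-slice volume.
#'
#' @param data Numeric or complex array (2D or 3D).
#' @param voxel_size_mm Length-3 positive numeric, voxel spacing in mm.
#' @param is_complex Logical; defaults to `is.complex(data)`.
#' @param series_id Free-text identifier for the acquisition series.
#' @param check_nonneg If `TRUE`, require all finite values to be non-negative
#'   (the invariant for acquired magnitude images; phase and difference maps
#'   are legitimately signed and skip the check).
#'
#' @return An object of class `image_volume`: a list with elements `data`,
#'   `voxel_size_mm`, `is_complex`, `series_id`.
#' @export
image_volume <- function(data, voxel_size_mm = c(1, 1, 1),
                         is_complex = is.complex(data),
                         series_id = "", check_nonneg = !is_complex) {
  if (!is.array(data) && !is.matrix(data)) {
    stop("`data` must be a 2D or 3D array", call. = FALSE)
  }
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L) {
    stop("`data` must have 2 or 3 dimensions", call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0)) {
    stop("`voxel_size_mm` must be three positive numbers", call. = FALSE)
  }
  if (is_complex && !is.complex(data)) data <- data + 0i
  if (check_nonneg && !is_complex) {
    vals <- data[is.finite(data)]
    if (length(vals) && any(vals < 0)) {
      stop("magnitude image contains negative values", call. = FALSE)
    }
  }
  structure(
    list(data = data, voxel_size_mm = voxel_size_mm,
         is_complex = isTRUE(is_complex), series_id = as.character(series_id)),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s  dims %s  voxel %s mm  %s\n",
              if (nzchar(x$series_id)) x$series_id else "(unnamed)",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size_mm, 3), collapse = "x"),
              if (x$is_complex) "complex" else "real"))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

is_image_volume <- function(x) inherits(x, "image_volume")

# Paths of the paired real/imaginary files used to store a complex volume.
complex_paths <- function(path) {
  stem <- sub("(\\.nii(\\.gz)?)$", "", path)
  ext <- substring(path, nchar(stem) + 1L)
  if (!nzchar(ext)) ext <- ".nii.gz"
  c(real = paste0(stem, "_real", ext), imag = paste0(stem, "_imag", ext))
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/2 file into an [image_volume()]. Complex volumes are stored
#' as paired `_real`/`_imag` files (NIfTI containers written here carry real
#' payloads only); pass `expect_complex = TRUE` and the stem path to read the
#' pair back as one complex volume.
#'
#' @param path File path (for complex data, the stem path whose `_real`/`_imag`
#'   siblings exist).
#' @param expect_complex Read a paired-complex volume.
#' @param signed Allow negative values in a real volume (phase maps, difference
#'   maps). Acquired magnitude images keep the default `FALSE`, which enforces
#'   the non-negativity invariant.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, expect_complex = FALSE, signed = FALSE) {
  if (expect_complex) {
    cp <- complex_paths(path)
    if (!file.exists(cp["real"]) || !file.exists(cp["imag"])) {
      if (file.exists(path)) {
        stop("complex volume requested but only a magnitude file is present: ",
             path, call. = FALSE)
      }
      stop("complex volume pair not found for: ", path, call. = FALSE)
    }
    re <- read_raw_nifti(cp[["real"]])
    im <- read_raw_nifti(cp[["imag"]])
    if (!identical(dim(re$data), dim(im$data))) {
      stop("real/imaginary volumes have different shapes", call. = FALSE)
    }
    z <- complex(real = re$data, imaginary = im$data)
    dim(z) <- dim(re$data)  # complex() drops the dim attribute
    return(image_volume(z, voxel_size_mm = re$vox,
                        is_complex = TRUE, series_id = basename(path)))
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read_raw_nifti(path)
  image_volume(raw$data, voxel_size_mm = raw$vox, series_id = basename(path),
               check_nonneg = !signed)
}

read_raw_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nii <- tryCatch(oro.nifti::readNIfTI(path, reorient = FALSE),
                  error = function(e) stop("not a readable NIfTI file: ", path,
                                           call. = FALSE))
  dat <- promote_3d(nii@.Data)
  attributes(dat) <- list(dim = dim(dat))
  pd <- oro.nifti::pixdim(nii)[2:4]
  vox <- ifelse(is.finite(pd) & pd > 0, pd, 1)
  list(data = dat, vox = vox)
}

promote_3d <- function(a) {
  d <- dim(a)
  if (is.null(d)) d <- length(a)
  if (length(d) == 1L) d <- c(d, 1L)
  if (length(d) == 2L) d <- c(d, 1L)
  if (length(d) > 3L) {
    if (prod(d[-(1:3)]) != 1L) stop("volume has more than 3 non-trivial dimensions",
                                    call. = FALSE)
    d <- d[1:3]
  }
  dim(a) <- d
  a
}

#' Write a NIfTI volume
#'
#' Writes an [image_volume()] to disk. Real data go to `path` directly; complex
#' data are split into `_real`/`_imag` sibling files (the stem `path` is the
#' handle [read_volume()] accepts with `expect_complex = TRUE`).
#'
#' @param vol An [image_volume()].
#' @param path Destination path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly usable as the read handle.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_image_volume(vol))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  if (file.access(dir, 2L) != 0L) stop("directory not writable: ", dir, call. = FALSE)
  if (vol$is_complex) {
    cp <- complex_paths(path)
    write_plain_nifti(Re(vol$data), vol$voxel_size_mm, cp[["real"]])
    write_plain_nifti(Im(vol$data), vol$voxel_size_mm, cp[["imag"]])
    return(invisible(path))
  }
  write_plain_nifti(vol$data, vol$voxel_size_mm, path)
  invisible(path)
}

write_plain_nifti <- function(arr, vox, path) {
  img <- oro.nifti::nifti(arr, datatype = 64)  # FLOAT64: lossless for doubles
  oro.nifti::pixdim(img)[2:4] <- vox
  gz <- grepl("\\.gz$", path)
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  oro.nifti::writeNIfTI(img, stem, gzipped = gz)
}
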