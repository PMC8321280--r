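#' Construct a grayscale slice object
#'
#' A `gray_image` is a numeric matrix (rows = image rows, 1-based (row, col)
#' indexing) carrying a declared `value_range` attribute — the (min, max) of
#' its encoding, e.g. `c(0, 255)` for 8-bit rasters or `c(0, 1)` after
#' [normalize_image()].
#'
#' @param pixels numeric matrix of intensities.
#' @param value_range length-2 numeric, declared (min, max) of the encoding.
#' @return a `gray_image` object.
#' @export
gray_image <- function(pixels, value_range) {
  stopifnot(is.matrix(pixels), is.numeric(pixels),
            nrow(pixels) >= 1L, ncol(pixels) >= 1L,
            length(value_range) == 2L, value_range[2] >= value_range[1])
  if (any(pixels < value_range[1] - 1e-9 | pixels > value_range[2] + 1e-9))
    stop("pixel values outside the declared value_range")
  structure(pixels, value_range = as.numeric(value_range),
            class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  vr <- attr(x, "value_range")
  cat(sprintf("<gray_image %d x %d, value_range [%g, %g]>\n",
              nrow(x), ncol(x), vr[1], vr[2]))
  invisible(x)
}

#' @rdname gray_image
#' @param x object to query.
#' @export
value_range <- function(x) attr(x, "value_range")

# strip gray_image attributes down to a plain matrix
as_plain_matrix <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Coerce to a binary mask
#'
#' Binary masks are logical matrices aligned pixel-for-pixel with the image
#' they annotate.
#'
#' @param x logical or 0/1 numeric matrix.
#' @return logical matrix.
#' @export
as_binary_mask <- function(x) {
  stopifnot(is.matrix(x))
  if (is.logical(x)) return(unname(x))
  if (!all(x %in% c(0, 1))) stop("mask values must be exactly 0 or 1")
  m <- x == 1
  attributes(m) <- list(dim = dim(x))
  m
}

luminance_rec601 <- c(0.299, 0.587, 0.114)

#' Read a 2-D slice from PNG, TIFF, or NIfTI
#'
#' Raster inputs (PNG, TIFF) are returned on the 8-bit scale with
#' `value_range` `(0, 255)`; RGB(A) rasters are collapsed to one luminance
#' channel with the Rec.601 weights (0.299, 0.587, 0.114). NIfTI volumes are
#' sliced axially (third axis) at `slice_index` and keep their native
#' intensity range.
#'
#' @param path file path (`.png`, `.tif`/`.tiff`, `.nii`/`.nii.gz`).
#' @param slice_index 1-based axial slice index; required for 3-D volumes.
#' @return a [gray_image()].
#' @export
read_slice <- function(path, slice_index = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': file not found")
  low <- tolower(path)
  if (grepl("\\.png$", low)) {
    px <- png::readPNG(path)
  } else if (grepl("\\.tiff?$", low)) {
    px <- tiff::readTIFF(path)
  } else if (grepl("\\.nii(\\.gz)?$", low)) {
    vol <- RNifti::readNifti(path)
    arr <- as.array(vol)
    if (length(dim(arr)) == 3L) {
      if (is.null(slice_index))
        stop("slice_index is required for a 3-D volume")
      if (slice_index < 1L || slice_index > dim(arr)[3])
        stop("slice_index ", slice_index, " out of range 1..", dim(arr)[3])
      arr <- arr[, , slice_index]
    } else if (length(dim(arr)) != 2L) {
      stop("unsupported NIfTI dimensionality: ", length(dim(arr)))
    }
    rng <- range(arr)
    if (rng[1] == rng[2]) rng <- c(rng[1], rng[1] + 1)  # constant slice
    return(gray_image(unname(arr), value_range = rng))
  } else {
    stop("unsupported format for '", path, "' (expected PNG, TIFF, or NIfTI)")
  }
  if (length(dim(px)) == 3L) {
    nch <- dim(px)[3]
    if (nch >= 3L) {
      px <- px[, , 1] * luminance_rec601[1] + px[, , 2] * luminance_rec601[2] +
        px[, , 3] * luminance_rec601[3]
    } else {
      px <- px[, , 1]
    }
  }
  gray_image(unname(px) * 255, value_range = c(0, 255))
}

#' Write a binary mask as an 8-bit PNG (foreground 255, background 0)
#'
#' @param mask logical matrix.
#' @param path output path; the parent directory must exist.
#' @return invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  mask <- as_binary_mask(mask)
  if (!dir.exists(dirname(path)))
    stop("cannot write '", path, "': parent directory does not exist")
  png::writePNG(mask * 1.0, target = path)
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#'
#' Pixels above half intensity are foreground, so the 0/255 encoding
#' round-trips exactly.
#'
#' @param path PNG/TIFF mask path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  img <- read_slice(path)
  m <- as_plain_matrix(img) > 127.5
  m
}

#' Rescale a slice linearly onto [0, 1]
#'
#' Maps the declared `value_range` linearly to `(0, 1)`, which fixes the
#' scale of the region-growing tolerance. Constant images (degenerate range)
#' map to all zeros: a constant slice carries no segmentable signal.
#'
#' @param img a [gray_image()].
#' @return a [gray_image()] with `value_range` `(0, 1)`. Idempotent on
#'   already-normalized images.
#' @export
normalize_image <- function(img) {
  vr <- value_range(img)
  px <- as_plain_matrix(img)
  if (diff(range(px)) == 0 && vr[1] == vr[2]) {
    return(gray_image(px * 0, value_range = c(0, 1)))
  }
  if (vr[2] == vr[1]) stop("value_range is degenerate but image is not constant")
  if (diff(range(px)) == 0) {
    # constant image with a declared non-degenerate range: no signal
    return(gray_image(px * 0, value_range = c(0, 1)))
  }
  out <- (px - vr[1]) / (vr[2] - vr[1])
  gray_image(pmin(pmax(out, 0), 1), value_range = c(0, 1))
}

#' Resize a slice to the 256x256 working resolution
#'
#' Bilinear interpolation; values are clipped back to the declared range.
#' Inputs already at the target size are returned unchanged.
#'
#' @param img a [gray_image()].
#' @param size target (rows, cols); default `c(256, 256)`.
#' @return a [gray_image()] of the target size.
#' @export
resize_to_working <- function(img, size = c(256L, 256L)) {
  vr <- value_range(img)
  px <- as_plain_matrix(img)
  if (all(dim(px) == size)) return(gray_image(px, vr))
  out <- EBImage::resize(px, w = size[1], h = size[2], filter = "bilinear")
  out <- matrix(as.numeric(out), size[1], size[2])
  gray_image(pmin(pmax(out, vr[1]), vr[2]), value_range = vr)
}

#' Map a working-resolution mask back to the native slice shape
#'
#' Nearest-neighbor resampling, so the output stays strictly binary.
#'
#' @param mask logical matrix (typically 256x256).
#' @param original_shape target (rows, cols).
#' @return logical matrix of shape `original_shape`.
#' @export
mask_to_original <- function(mask, original_shape) {
  mask <- as_binary_mask(mask)
  if (all(dim(mask) == original_shape)) return(mask)
  out <- EBImage::resize(mask * 1.0, w = original_shape[1],
                         h = original_shape[2], filter = "none")
  matrix(as.numeric(out) >= 0.5, original_shape[1], original_shape[2])
}
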