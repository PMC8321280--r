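#' Otsu threshold of a slice
#'
#' Threshold maximizing between-class variance over a 256-bin histogram of
#' the image on its declared value range. Constant images return the
#' constant.
#'
#' @param img a [gray_image()].
#' @return scalar threshold on the image's intensity scale.
#' @export
otsu_threshold <- function(img) {
  vr <- value_range(img)
  px <- as_plain_matrix(img)
  if (diff(range(px)) == 0) return(px[1])
  as.numeric(EBImage::otsu(EBImage::Image(px), range = vr, levels = 256))
}

#' Keep only the largest connected foreground component
#'
#' Components are 8-connected; ties between equal-size components keep the
#' one whose first pixel comes earliest in row-major order. An empty mask is
#' returned unchanged.
#'
#' @param mask logical matrix.
#' @return logical matrix with at most one component.
#' @export
largest_blob <- function(mask) {
  mask <- as_binary_mask(mask)
  lab <- label_components_cpp(mask, 8L)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  # labels are assigned in row-major first-encounter order, so which.max's
  # first-maximum rule is exactly the declared tie-break
  keep <- which.max(sizes)
  lab == keep
}

#' Fill enclosed holes in a binary mask
#'
#' Background regions not connected (4-connectivity) to the image border
#' become foreground; border-connected background is untouched, so
#' foreground never shrinks and the operation is idempotent.
#'
#' @param mask logical matrix.
#' @return logical matrix, a superset of `mask`.
#' @export
fill_holes <- function(mask) {
  fill_holes_cpp(as_binary_mask(mask))
}

disk_brush <- function(radius) {
  EBImage::makeBrush(2L * radius + 1L, shape = "disc")
}

#' Strip the skull from a normalized slice
#'
#' Runs the morphological skull-stripping sequence: Otsu threshold, opening
#' with a disk, dilation with the same disk, largest-component selection,
#' closing, and hole filling; all non-brain pixels of the input are then
#' zeroed. The skull ring, when separated from the brain by a dark gap,
#' forms a smaller connected component and is discarded by the
#' largest-component step.
#'
#' @param img a [gray_image()] normalized to `(0, 1)` (see
#'   [normalize_image()]).
#' @param selem_radius disk structuring-element radius in pixels (default 3
#'   at the 256x256 working resolution).
#' @return a list of class `strip_result`: `stripped` ([gray_image()] with
#'   non-brain pixels set to 0), `brain_mask` (logical matrix, at most one
#'   connected component), `otsu_threshold` (scalar). If thresholding plus
#'   opening leaves no foreground, the mask and stripped image are empty and
#'   a warning is raised.
#' @export
strip_skull <- function(img, selem_radius = 3L) {
  vr <- value_range(img)
  if (!isTRUE(all.equal(vr, c(0, 1))))
    stop("strip_skull expects a normalized image; call normalize_image() first")
  stopifnot(selem_radius >= 1L)
  px <- as_plain_matrix(img)
  thr <- otsu_threshold(img)
  bw <- (px > thr) * 1.0
  se <- disk_brush(selem_radius)
  bw <- EBImage::opening(bw, se)
  if (sum(bw) == 0) {
    warning("no tissue foreground after thresholding and opening")
    empty <- matrix(FALSE, nrow(px), ncol(px))
    return(structure(list(stripped = gray_image(px * 0, vr),
                          brain_mask = empty, otsu_threshold = thr),
                     class = "strip_result"))
  }
  bw <- EBImage::dilate(bw, se)
  bw <- largest_blob(matrix(as.numeric(bw) > 0.5, nrow(px), ncol(px)))
  bw <- EBImage::closing(bw * 1.0, se)
  bw <- fill_holes(matrix(as.numeric(bw) > 0.5, nrow(px), ncol(px)))
  stripped <- px
  stripped[!bw] <- 0
  structure(list(stripped = gray_image(stripped, vr),
                 brain_mask = bw, otsu_threshold = thr),
            class = "strip_result")
}

#' @export
print.strip_result <- function(x, ...) {
  cat(sprintf("<strip_result: brain mask %d px, Otsu threshold %.4f>\n",
              sum(x$brain_mask), x$otsu_threshold))
  invisible(x)
}
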