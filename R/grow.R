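#' Region-growing parameters
#'
#' @param tolerance maximal absolute intensity difference, on the
#'   `[0, 1]`-normalized scale, between a candidate pixel and the reference
#'   mean for acceptance. Default 0.1, the setting at which homogeneous
#'   tumor regions are captured whole.
#' @param connectivity pixel neighborhood, 4 or 8 (default 8).
#' @param criterion `"running_mean"` (classic seeded region growing: the
#'   reference is the mean of the region accepted so far, initialized to the
#'   seed's reference intensity) or `"fixed_seed"` (the reference stays at
#'   the seed's reference intensity, making the result an exact
#'   connected-component flood fill).
#' @param max_region_fraction stop growing once the region exceeds this
#'   fraction of the image area; guards against flood-out on near-uniform
#'   slices (default 0.5).
#' @return a list of class `grow_params`.
#' @export
grow_params <- function(tolerance = 0.1, connectivity = 8L,
                        criterion = c("running_mean", "fixed_seed"),
                        max_region_fraction = 0.5) {
  criterion <- match.arg(criterion)
  stopifnot(tolerance >= 0, tolerance <= 1,
            connectivity %in% c(4L, 8L),
            max_region_fraction > 0, max_region_fraction <= 1)
  structure(list(tolerance = tolerance, connectivity = as.integer(connectivity),
                 criterion = criterion,
                 max_region_fraction = max_region_fraction),
            class = "grow_params")
}

#' A seed point for region growing
#'
#' @param row,col 1-based pixel position.
#' @param reference_intensity starting reference on the `[0, 1]` scale,
#'   normally the mean intensity of the seed's tile.
#' @return a list of class `seed_point`.
#' @export
seed_point <- function(row, col, reference_intensity) {
  stopifnot(row >= 1L, col >= 1L,
            reference_intensity >= 0, reference_intensity <= 1)
  structure(list(row = as.integer(row), col = as.integer(col),
                 reference_intensity = reference_intensity),
            class = "seed_point")
}

#' Grow a candidate region of interest from a seed
#'
#' Breadth-first expansion from the seed: a frontier pixel `p` is accepted
#' when `|I(p) - mu| <= tolerance`, where `mu` is either the running mean of
#' the accepted region or the fixed seed reference (see [grow_params()]).
#' Each pixel is tested once, at first encounter, so the FIFO frontier makes
#' the running-mean result deterministic. Pixels outside `allowed` (e.g.
#' stripped-out background) are never accepted.
#'
#' @param img a [gray_image()] normalized to `(0, 1)`.
#' @param seed a [seed_point()], inside the image.
#' @param params a [grow_params()].
#' @param allowed optional logical matrix of admissible pixels (typically
#'   the brain mask); default all pixels.
#' @return a list of class `candidate_roi`: `mask` (logical matrix), `seed`,
#'   `params`, `n_pixels`, `degenerate` (TRUE when the region is empty or a
#'   single pixel), and `metrics` (NULL until scored).
#' @export
region_grow <- function(img, seed, params = grow_params(), allowed = NULL) {
  px <- as_plain_matrix(img)
  if (seed$row > nrow(px) || seed$col > ncol(px))
    stop("seed position (", seed$row, ",", seed$col, ") outside image")
  if (is.null(allowed)) {
    allowed <- matrix(TRUE, nrow(px), ncol(px))
  } else {
    allowed <- as_binary_mask(allowed)
    stopifnot(all(dim(allowed) == dim(px)))
  }
  max_px <- max(1L, as.integer(floor(params$max_region_fraction * length(px))))
  mask <- region_grow_cpp(px, seed$row, seed$col, seed$reference_intensity,
                          params$tolerance, params$connectivity,
                          params$criterion == "running_mean", max_px, allowed)
  n <- sum(mask)
  structure(list(mask = mask, seed = seed, params = params,
                 n_pixels = n, degenerate = n <= 1L, metrics = NULL),
            class = "candidate_roi")
}

#' @export
print.candidate_roi <- function(x, ...) {
  cat(sprintf("<candidate_roi: %d px from seed (%d,%d), ref %.3f%s>\n",
              x$n_pixels, x$seed$row, x$seed$col,
              x$seed$reference_intensity,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Fill holes inside a grown region
#'
#' Tumors with a dark core grow only as a bright rim; filling the enclosed
#' holes recovers the core. Monotone (output covers input) and idempotent.
#'
#' @param roi a `candidate_roi` from [region_grow()].
#' @return the roi with `mask` hole-filled and `n_pixels` recomputed.
#' @export
postprocess_roi <- function(roi) {
  roi$mask <- fill_holes(roi$mask)
  roi$n_pixels <- sum(roi$mask)
  roi$degenerate <- roi$n_pixels <= 1L
  roi
}
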