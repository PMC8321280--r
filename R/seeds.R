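#' Tile mean intensities of the working image
#'
#' Partitions the image into non-overlapping `block_size` x `block_size`
#' tiles (1024 tiles of 8x8 pixels at the 256x256 working resolution) and
#' records, per tile, its origin, its center pixel, and the arithmetic mean
#' of its intensities. Tiles are listed in row-major tile order.
#'
#' @param img a [gray_image()] whose height and width are divisible by
#'   `block_size`.
#' @param block_size tile side length in pixels (default 8).
#' @return data frame with one row per tile: `tile` (row-major index),
#'   `origin_row`, `origin_col` (1-based top-left pixel), `center_row`,
#'   `center_col` (origin + `block_size %/% 2 - 1`, i.e. origin + 3 for 8x8
#'   tiles), `mean_intensity`.
#' @export
compute_block_stats <- function(img, block_size = 8L) {
  px <- as_plain_matrix(img)
  h <- nrow(px); w <- ncol(px)
  stopifnot(block_size >= 1L)
  if (h %% block_size != 0L || w %% block_size != 0L)
    stop("image dimensions (", h, "x", w, ") not divisible by block_size ",
         block_size, "; resize first")
  tr <- (seq_len(h) - 1L) %/% block_size
  tc <- (seq_len(w) - 1L) %/% block_size
  sums <- rowsum(px, tr)                 # sum over pixel rows within tile row
  sums <- t(rowsum(t(sums), tc))         # then over pixel cols within tile col
  means <- sums / block_size^2           # (h/bs) x (w/bs), [tile_row, tile_col]
  nth <- h %/% block_size; ntw <- w %/% block_size
  origin_row <- rep(seq_len(nth), each = ntw)
  origin_col <- rep(seq_len(ntw), times = nth)
  off <- block_size %/% 2L - 1L          # center offset: +3 for 8x8 tiles
  data.frame(
    tile = seq_len(nth * ntw),
    origin_row = (origin_row - 1L) * block_size + 1L,
    origin_col = (origin_col - 1L) * block_size + 1L,
    center_row = (origin_row - 1L) * block_size + 1L + off,
    center_col = (origin_col - 1L) * block_size + 1L + off,
    mean_intensity = as.numeric(t(means))  # row-major tile order
  )
}

#' Select the brightest tiles as seed points
#'
#' Returns the `k` tiles of greatest mean intensity as seed points at the
#' tile centers, ordered by descending mean; ties break by row-major tile
#' order. The tile mean becomes the seed's reference intensity for region
#' growing.
#'
#' @param stats data frame from [compute_block_stats()], possibly
#'   pre-filtered (e.g. to tiles inside the brain mask).
#' @param k number of seeds (default 5).
#' @return data frame with columns `rank`, `row`, `col`,
#'   `reference_intensity`; at most `k` rows.
#' @export
select_seeds <- function(stats, k = 5L) {
  stopifnot(k >= 1L)
  if (is.null(stats) || nrow(stats) == 0L)
    stop("no tiles to select seeds from")
  ord <- order(-stats$mean_intensity, stats$tile)
  top <- stats[head(ord, k), , drop = FALSE]
  data.frame(rank = seq_len(nrow(top)),
             row = top$center_row,
             col = top$center_col,
             reference_intensity = top$mean_intensity)
}
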