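# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own primitives.

# shift a logical matrix by (dr, dc), padding with FALSE
shift_mask <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr); cs <- seq_len(nc)
  rsrc <- rs - dr; csrc <- cs - dc
  ok_r <- rsrc >= 1 & rsrc <= nr; ok_c <- csrc >= 1 & csrc <= nc
  out[rs[ok_r], cs[ok_c]] <- m[rsrc[ok_r], csrc[ok_c]]
  out
}

neighbor_offsets <- function(connectivity) {
  if (connectivity == 4) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
            c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
}

# grow a logical region by one step of `connectivity` neighbors
dilate_once <- function(m, connectivity) {
  out <- m
  for (off in neighbor_offsets(connectivity))
    out <- out | shift_mask(m, off[1], off[2])
  out
}

# connected component of `eligible` containing `seed_rc`; empty if the seed
# pixel itself is ineligible
oracle_flood_fill <- function(eligible, seed_rc, connectivity) {
  reg <- matrix(FALSE, nrow(eligible), ncol(eligible))
  if (!eligible[seed_rc[1], seed_rc[2]]) return(reg)
  reg[seed_rc[1], seed_rc[2]] <- TRUE
  repeat {
    grown <- dilate_once(reg, connectivity) & eligible
    if (all(grown == reg)) break
    reg <- grown
  }
  reg
}

# component sizes by repeated flood fill; returns list(labels, sizes)
oracle_label <- function(mask, connectivity) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (mask[r, c] && lab[r, c] == 0L) {
      nxt <- nxt + 1L
      comp <- oracle_flood_fill(mask, c(r, c), connectivity)
      lab[comp] <- nxt
    }
  }
  list(labels = lab, sizes = if (nxt == 0L) integer() else tabulate(lab[lab > 0L]))
}

# hole filling by border flood fill over 4-connected background
oracle_fill_holes <- function(mask) {
  bg <- !mask
  border <- matrix(FALSE, nrow(mask), ncol(mask))
  border[1, ] <- TRUE; border[nrow(mask), ] <- TRUE
  border[, 1] <- TRUE; border[, ncol(mask)] <- TRUE
  reach <- bg & border
  repeat {
    grown <- dilate_once(reach, 4) & bg
    if (all(grown == reach)) break
    reach <- grown
  }
  mask | !reach
}

# per-pixel enumeration of confusion counts and all eight metrics
oracle_metrics <- function(pred, ref) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] && ref[i]) tp <- tp + 1L
    else if (pred[i] && !ref[i]) fp <- fp + 1L
    else if (!pred[i] && ref[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  N <- tp + fp + fn + tn
  mse <- sum((pred * 255 - ref * 255)^2) / N
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       acc = (tp + tn) / N,
       iou = if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn),
       dss = if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn),
       sn = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
       sp = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
       ef = if (tp + fn == 0) NA_real_ else fp / (tp + fn),
       of = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
       psnr = if (mse == 0) Inf else 10 * log10(255^2 / mse))
}

# exhaustive 256-bin Otsu: maximal between-class variance over all splits
oracle_otsu_max_variance <- function(px, range = c(0, 1)) {
  bins <- pmin(255L, pmax(0L, as.integer(floor(
    (px - range[1]) / (range[2] - range[1]) * 256))))
  h <- tabulate(bins + 1L, nbins = 256L)
  p <- h / sum(h)
  levels <- range[1] + (seq_len(256) - 0.5) / 256 * (range[2] - range[1])
  best <- -Inf
  for (t in 1:255) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:t] * levels[1:t]) / w0
    mu1 <- sum(p[(t + 1):256] * levels[(t + 1):256]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) best <- v
  }
  best
}

# between-class variance achieved by thresholding px at thr
between_class_variance <- function(px, thr) {
  lo <- px <= thr; hi <- !lo
  if (!any(lo) || !any(hi)) return(0)
  w0 <- mean(lo); w1 <- 1 - w0
  w0 * w1 * (mean(px[lo]) - mean(px[hi]))^2
}

random_mask <- function(nr, nc, p = 0.5) matrix(runif(nr * nc) < p, nr, nc)
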