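#' Pixelwise confusion counts between a predicted and a reference mask
#'
#' TP counts tumor pixels correctly detected, FP normal pixels marked as
#' tumor, FN tumor pixels missed, TN normal pixels left alone; the four
#' counts always sum to the image area.
#'
#' @param pred,ref logical matrices of identical shape.
#' @return list with integer `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(pred, ref) {
  pred <- as_binary_mask(pred); ref <- as_binary_mask(ref)
  if (!all(dim(pred) == dim(ref)))
    stop("mask shapes differ: ", paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(ref), collapse = "x"))
  tp <- sum(pred & ref)
  fp <- sum(pred & !ref)
  fn <- sum(!pred & ref)
  list(tp = tp, fp = fp, fn = fn, tn = length(pred) - tp - fp - fn)
}

#' Extra fraction: FP / (TP + FN)
#'
#' False detections normalized by the reference size; lower is better and
#' values above 1 are possible. Undefined for an empty reference.
#'
#' @param c confusion counts from [confusion()].
#' @return non-negative scalar.
#' @export
extra_fraction <- function(c) {
  if (c$tp + c$fn == 0) stop("extra fraction undefined: reference mask is empty")
  c$fp / (c$tp + c$fn)
}

#' Overlap fraction: TP / (TP + FN)
#'
#' Numerically identical to sensitivity. Undefined for an empty reference.
#'
#' @param c confusion counts from [confusion()].
#' @return fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(c) {
  if (c$tp + c$fn == 0) stop("overlap fraction undefined: reference mask is empty")
  c$tp / (c$tp + c$fn)
}

#' Dice similarity score: 2 TP / (2 TP + FP + FN)
#'
#' Spatial-overlap measure; symmetric in its two masks. When both masks are
#' empty (tp = fp = fn = 0) the score is 1 by convention (perfect
#' agreement).
#'
#' @param c confusion counts from [confusion()].
#' @return fraction in `[0, 1]`.
#' @export
dice <- function(c) {
  denom <- 2 * c$tp + c$fp + c$fn
  if (denom == 0) return(1)
  2 * c$tp / denom
}

#' Full eight-metric evaluation report
#'
#' Computes accuracy, IoU (Jaccard), Dice, sensitivity, specificity, extra
#' fraction, overlap fraction, and PSNR between two binary masks. Percent
#' metrics are stored as fractions; PSNR uses the standard
#' `10 log10(255^2 / MSE)` on masks encoded 0/255 and is `Inf` for
#' identical masks. Metrics with an empty-denominator (empty reference for
#' ef/of/sn, full reference for sp) are reported as `NA`.
#'
#' @param pred,ref logical matrices of identical shape.
#' @return list of class `metric_report` with fields `acc`, `iou`, `dss`,
#'   `sn`, `sp`, `ef`, `of`, `psnr`, plus the `counts`.
#' @export
full_report <- function(pred, ref) {
  cc <- confusion(pred, ref)
  N <- cc$tp + cc$fp + cc$fn + cc$tn
  iou <- if (cc$tp + cc$fp + cc$fn == 0) 1 else cc$tp / (cc$tp + cc$fp + cc$fn)
  sn <- if (cc$tp + cc$fn == 0) NA_real_ else cc$tp / (cc$tp + cc$fn)
  sp <- if (cc$tn + cc$fp == 0) NA_real_ else cc$tn / (cc$tn + cc$fp)
  ef <- if (cc$tp + cc$fn == 0) NA_real_ else cc$fp / (cc$tp + cc$fn)
  mse <- (cc$fp + cc$fn) * 255^2 / N
  psnr <- if (mse == 0) Inf else 10 * log10(255^2 / mse)
  structure(list(acc = (cc$tp + cc$tn) / N, iou = iou, dss = dice(cc),
                 sn = sn, sp = sp, ef = ef, of = sn, psnr = psnr,
                 counts = cc),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report: Acc %.1f%%  IoU %.3f  DSS %.3f  Sn %.1f%%  Sp %.1f%%  EF %.3f  OF %.3f  PSNR %s>\n",
    100 * x$acc, x$iou, x$dss, 100 * x$sn, 100 * x$sp, x$ef, x$of,
    if (is.infinite(x$psnr)) "Inf" else sprintf("%.2f dB", x$psnr)))
  invisible(x)
}
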