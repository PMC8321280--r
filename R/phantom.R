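#' Specification of a synthetic brain-slice phantom
#'
#' The phantom emulates the structure of an axial FLAIR slice: dark
#' background, a bright elliptical skull ring, a mid-intensity brain
#' ellipse separated from the ring by a dark CSF gap, and a hyperintense
#' circular tumor — the brightest interior structure, as gliomas appear on
#' FLAIR. With `core_dark`, the tumor center is dark so only its rim is
#' hyperintense, exercising the hole-filling rescue. Default intensities
#' (background 0, skull 0.8, brain 0.45, tumor 0.9) make Otsu separate
#' tissue from background while the skull ring stays brighter than brain,
#' forcing the stripping stage to discard it by component size.
#'
#' @param size (rows, cols), default 256x256.
#' @param brain_axes ellipse semi-axes (row, col) in pixels.
#' @param skull_thickness ring thickness in pixels.
#' @param skull_gap dark gap between brain ellipse and ring, in pixels.
#' @param tumor_center (row, col) of the tumor disk.
#' @param tumor_radius disk radius in pixels.
#' @param brain_intensity,skull_intensity,tumor_intensity tissue levels in
#'   `[0, 1]`; the tumor must be brighter than brain.
#' @param core_dark if TRUE, the inner half-radius of the tumor is dark
#'   (`core_intensity`), while the ground truth still covers the full disk.
#' @param core_intensity intensity of the dark core.
#' @param noise_sigma standard deviation of additive Gaussian noise; the
#'   image is clipped to `[0, 1]` afterwards.
#' @param rng_seed integer seed making the noise reproducible.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(256L, 256L),
                         brain_axes = c(88, 72),
                         skull_thickness = 5,
                         skull_gap = 8,
                         tumor_center = c(104, 148),
                         tumor_radius = 14,
                         brain_intensity = 0.45,
                         skull_intensity = 0.8,
                         tumor_intensity = 0.9,
                         core_dark = FALSE,
                         core_intensity = 0.15,
                         noise_sigma = 0.02,
                         rng_seed = 0L) {
  spec <- structure(list(size = as.integer(size), brain_axes = brain_axes,
                         skull_thickness = skull_thickness,
                         skull_gap = skull_gap,
                         tumor_center = tumor_center,
                         tumor_radius = tumor_radius,
                         brain_intensity = brain_intensity,
                         skull_intensity = skull_intensity,
                         tumor_intensity = tumor_intensity,
                         core_dark = isTRUE(core_dark),
                         core_intensity = core_intensity,
                         noise_sigma = noise_sigma,
                         rng_seed = as.integer(rng_seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  problems <- character()
  cen <- (spec$size + 1) / 2
  a <- spec$brain_axes[1]; b <- spec$brain_axes[2]
  # tumor disk inside the brain ellipse: the scaled center distance plus the
  # radius over the smaller semi-axis must stay below 1
  d <- sqrt(((spec$tumor_center[1] - cen[1]) / a)^2 +
              ((spec$tumor_center[2] - cen[2]) / b)^2)
  if (d + spec$tumor_radius / min(a, b) > 1)
    problems <- c(problems, "tumor disk extends outside the brain ellipse")
  if (spec$tumor_intensity <= spec$brain_intensity)
    problems <- c(problems, "tumor_intensity must exceed brain_intensity")
  if (spec$skull_gap < 1)
    problems <- c(problems, "skull ring must be separated from the brain (skull_gap >= 1)")
  if (a + spec$skull_gap + spec$skull_thickness > min(cen) - 1 ||
      b + spec$skull_gap + spec$skull_thickness > min(cen) - 1)
    problems <- c(problems, "skull ring does not fit inside the image")
  if (length(problems) > 0)
    stop("invalid phantom_spec: ", paste(problems, collapse = "; "))
  invisible(spec)
}

# squared normalized ellipse distance field around the image center
ellipse_field <- function(size, semi_axes) {
  cen <- (size + 1) / 2
  r <- (seq_len(size[1]) - cen[1]) / semi_axes[1]
  c <- (seq_len(size[2]) - cen[2]) / semi_axes[2]
  outer(r^2, c^2, `+`)
}

#' Generate a phantom slice with ground truth
#'
#' Deterministic for a fixed `rng_seed`. With `noise_sigma = 0` and
#' `core_dark = FALSE` the image takes exactly four distinct values
#' (background, skull, brain, tumor).
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (a normalized [gray_image()]), `tumor_truth`
#'   and `brain_truth` (logical matrices; the brain truth covers the brain
#'   ellipse including the tumor, not the skull ring), and `skull_truth`
#'   (the ring pixels, for stripping tests).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  size <- spec$size
  a <- spec$brain_axes[1]; b <- spec$brain_axes[2]
  brain <- ellipse_field(size, c(a, b)) <= 1
  inner <- c(a + spec$skull_gap, b + spec$skull_gap)
  outer_ax <- inner + spec$skull_thickness
  skull <- ellipse_field(size, outer_ax) <= 1 & ellipse_field(size, inner) > 1
  rr <- outer((seq_len(size[1]) - spec$tumor_center[1])^2,
              (seq_len(size[2]) - spec$tumor_center[2])^2, `+`)
  tumor <- rr <= spec$tumor_radius^2
  img <- matrix(0, size[1], size[2])
  img[skull] <- spec$skull_intensity
  img[brain] <- spec$brain_intensity
  img[tumor] <- spec$tumor_intensity
  if (spec$core_dark) {
    core <- rr <= (spec$tumor_radius / 2)^2
    img[core] <- spec$core_intensity
  }
  if (spec$noise_sigma > 0) {
    old <- .Random.seed_save()
    set.seed(spec$rng_seed)
    img <- img + matrix(rnorm(length(img), 0, spec$noise_sigma),
                        size[1], size[2])
    .Random.seed_restore(old)
    img <- pmin(pmax(img, 0), 1)
  }
  list(image = gray_image(img, value_range = c(0, 1)),
       tumor_truth = tumor, brain_truth = brain, skull_truth = skull)
}

# save/restore the global RNG state so phantom generation does not disturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a reproducible suite of randomized phantoms
#'
#' Draws, per phantom, a tumor radius uniformly from `radius_range`, a tumor
#' intensity from `intensity_range`, and a tumor center uniform over the
#' positions keeping the disk inside the brain ellipse; per-phantom noise
#' seeds derive deterministically from `master_seed`.
#'
#' @param n number of phantoms.
#' @param base_spec a [phantom_spec()] supplying everything not randomized.
#' @param master_seed integer seed for the whole suite.
#' @param radius_range tumor radius range in pixels (default 10-18).
#' @param intensity_range tumor intensity range (default 0.78-0.95, keeping
#'   at least 0.3 contrast above the default brain intensity 0.45).
#' @return list of `n` phantom lists as from [generate_phantom()], each with
#'   its `spec` attached.
#' @export
generate_suite <- function(n, base_spec = phantom_spec(), master_seed = 0L,
                           radius_range = c(10, 18),
                           intensity_range = c(0.78, 0.95)) {
  stopifnot(n >= 1L)
  old <- .Random.seed_save()
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max, n)
  radii <- runif(n, radius_range[1], radius_range[2])
  intens <- runif(n, intensity_range[1], intensity_range[2])
  cen <- (base_spec$size + 1) / 2
  a <- base_spec$brain_axes[1]; b <- base_spec$brain_axes[2]
  centers <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    repeat {  # rejection-sample a center keeping the disk inside the ellipse
      u <- runif(2, -1, 1)
      cand <- cen + u * c(a, b)
      d <- sqrt(((cand[1] - cen[1]) / a)^2 + ((cand[2] - cen[2]) / b)^2)
      if (d + radii[i] / min(a, b) <= 0.95) { centers[i, ] <- cand; break }
    }
  }
  .Random.seed_restore(old)
  lapply(seq_len(n), function(i) {
    spec <- base_spec
    spec$tumor_center <- round(centers[i, ])
    spec$tumor_radius <- radii[i]
    spec$tumor_intensity <- intens[i]
    spec$rng_seed <- seeds[i]
    ph <- generate_phantom(spec)
    ph$spec <- spec
    ph
  })
}
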