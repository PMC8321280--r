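test_that("Otsu threshold separates a bimodal image and matches the exhaustive search", {
  set.seed(11)
  px <- matrix(sample(c(0.2, 0.8), 400, replace = TRUE), 20, 20)
  img <- gray_image(px, c(0, 1))
  thr <- otsu_threshold(img)
  expect_gt(thr, 0.2)
  expect_lte(thr, 0.8)
  # thresholding at thr separates the two populations exactly
  expect_true(all(px[px <= thr] == 0.2))
  expect_true(all(px[px > thr] == 0.8))
  # achieved between-class variance attains the exhaustive 256-bin maximum
  # (up to the bin-center discretization of the histogram oracle)
  expect_gte(between_class_variance(px, thr),
             0.99 * oracle_otsu_max_variance(px))
  # two-pixel image {0, 1}: one pixel lands on each side
  two <- gray_image(matrix(c(0, 1), 1, 2), c(0, 1))
  t2 <- otsu_threshold(two)
  expect_true(0 <= t2 && t2 < 1)
  # constant image returns the constant
  expect_equal(otsu_threshold(gray_image(matrix(0.3, 4, 4), c(0, 1))), 0.3)
})

test_that("Otsu variance is maximal on random continuous images", {
  set.seed(21)
  for (i in 1:10) {
    px <- matrix(c(rnorm(150, 0.3, 0.05), rnorm(106, 0.7, 0.05)), 16, 16)
    px <- pmin(pmax(px, 0), 1)
    thr <- otsu_threshold(gray_image(px, c(0, 1)))
    expect_gte(between_class_variance(px, thr),
               0.99 * oracle_otsu_max_variance(px))
  }
})

test_that("largest_blob keeps exactly the biggest 8-connected component", {
  m <- matrix(FALSE, 10, 10)
  m[2:4, 2:5] <- TRUE         # 12 px
  m[8:9, 8:9] <- TRUE         # 4 px, diagonal-separated from the first
  out <- largest_blob(m)
  expect_true(all(out[2:4, 2:5]))
  expect_false(any(out[8:9, 8:9]))
  # idempotence, single-component identity, empty case
  expect_identical(largest_blob(out), out)
  expect_identical(largest_blob(matrix(FALSE, 5, 5)), matrix(FALSE, 5, 5))
  # random masks: result is the maximal-size component of an independent labeling
  set.seed(31)
  for (i in 1:20) {
    rm <- random_mask(12, 12, 0.35)
    got <- largest_blob(rm)
    lab <- oracle_label(rm, 8)
    if (length(lab$sizes) == 0) {
      expect_false(any(got))
    } else {
      expect_equal(sum(got), max(lab$sizes))
      # the kept pixels form one oracle component
      kept <- unique(lab$labels[got])
      expect_length(kept, 1)
      expect_equal(sum(lab$labels == kept), sum(got))
    }
  }
})

test_that("largest_blob ties break toward the row-major-first component", {
  m <- matrix(FALSE, 6, 6)
  m[1:2, 1:2] <- TRUE  # first in row-major order
  m[5:6, 5:6] <- TRUE  # same size
  out <- largest_blob(m)
  expect_true(all(out[1:2, 1:2]))
  expect_false(any(out[5:6, 5:6]))
})

test_that("fill_holes fills enclosed background only, monotonically and idempotently", {
  # ring with a center hole -> solid block
  ring <- matrix(FALSE, 7, 7)
  ring[2:6, 2:6] <- TRUE; ring[4, 4] <- FALSE
  filled <- fill_holes(ring)
  expect_true(filled[4, 4])
  expect_true(all(filled[2:6, 2:6]))
  # solid mask unchanged; idempotence
  expect_identical(fill_holes(filled), filled)
  # bay open to the border stays background
  bay <- matrix(FALSE, 7, 7)
  bay[1:5, 2:6] <- TRUE; bay[1:3, 4] <- FALSE
  expect_identical(fill_holes(bay), bay)
  # random masks match the border-flood oracle, and output covers input
  set.seed(41)
  for (i in 1:20) {
    rm <- random_mask(15, 15, 0.45)
    got <- fill_holes(rm)
    expect_identical(got, oracle_fill_holes(rm))
    expect_true(all(got[rm]))
    # cross-check against EBImage's hole filler
    eb <- EBImage::fillHull(rm * 1.0)
    expect_identical(got, matrix(as.numeric(eb) > 0.5, 15, 15))
  }
})

test_that("strip_skull recovers the brain and discards a separated skull ring", {
  ph <- generate_phantom(phantom_spec(noise_sigma = 0))
  res <- strip_skull(ph$image)
  # recall of the true brain ellipse
  expect_gte(sum(res$brain_mask & ph$brain_truth) / sum(ph$brain_truth), 0.95)
  # ring entirely absent
  expect_equal(sum(res$brain_mask & ph$skull_truth), 0)
  # single connected component
  expect_equal(length(oracle_label(res$brain_mask, 8)$sizes), 1)
  # masked-identity invariant: stripped = img x mask
  px <- matrix(as.numeric(ph$image), 256, 256)
  out <- matrix(as.numeric(res$stripped), 256, 256)
  expect_equal(out[res$brain_mask], px[res$brain_mask])
  expect_true(all(out[!res$brain_mask] == 0))
})

test_that("strip_skull handles an all-zero slice as a degenerate case", {
  img <- gray_image(matrix(0, 64, 64), c(0, 1))
  norm <- normalize_image(gray_image(matrix(0, 64, 64), c(0, 255)))
  expect_warning(res <- strip_skull(norm), "no tissue")
  expect_false(any(res$brain_mask))
  expect_true(all(as.numeric(res$stripped) == 0))
})
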