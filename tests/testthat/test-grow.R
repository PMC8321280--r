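test_that("region_grow captures a homogeneous patch and stops at the background", {
  px <- matrix(0.2, 12, 12)
  px[4:8, 4:11] <- 0.9  # 40-pixel patch
  img <- gray_image(px, c(0, 1))
  roi <- region_grow(img, seed_point(5, 6, 0.9), grow_params(tolerance = 0.1))
  expect_equal(roi$n_pixels, 40)
  expect_true(all(roi$mask[4:8, 4:11]))
  expect_false(roi$degenerate)
  expect_true(roi$mask[5, 6])
})

test_that("zero tolerance with a fixed reference is an equality flood fill", {
  set.seed(5)
  px <- matrix(sample(c(0.3, 0.7), 100, replace = TRUE), 10, 10)
  img <- gray_image(px, c(0, 1))
  roi <- region_grow(img, seed_point(4, 4, px[4, 4]),
                     grow_params(tolerance = 0, criterion = "fixed_seed",
                                 max_region_fraction = 1))
  want <- oracle_flood_fill(px == px[4, 4], c(4, 4), 8)
  expect_identical(roi$mask, want)
})

test_that("a uniform image floods until the max_region_fraction cap", {
  img <- gray_image(matrix(0.5, 20, 20), c(0, 1))
  full <- region_grow(img, seed_point(10, 10, 0.5),
                      grow_params(max_region_fraction = 1))
  expect_equal(full$n_pixels, 400)
  capped <- region_grow(img, seed_point(10, 10, 0.5),
                        grow_params(max_region_fraction = 0.25))
  expect_lte(capped$n_pixels, 100)
  expect_gte(capped$n_pixels, 99)  # stops right at the cap
})

test_that("fixed_seed growing equals the BFS flood-fill oracle on random grids", {
  set.seed(55)
  for (i in 1:100) {
    px <- matrix(runif(256), 16, 16)
    sr <- sample(16, 1); sc <- sample(16, 1)
    tol <- runif(1, 0.02, 0.5)
    conn <- sample(c(4L, 8L), 1)
    # seed reference within tolerance of the seed pixel, so the declared
    # "component containing the seed" semantics applies
    ref <- min(1, max(0, px[sr, sc] + runif(1, -tol, tol)))
    roi <- region_grow(gray_image(px, c(0, 1)), seed_point(sr, sc, ref),
                       grow_params(tolerance = tol, connectivity = conn,
                                   criterion = "fixed_seed",
                                   max_region_fraction = 1))
    want <- oracle_flood_fill(abs(px - ref) <= tol, c(sr, sc), conn)
    expect_identical(roi$mask, want)
  }
})

test_that("fixed_seed growth is monotone in the tolerance", {
  set.seed(65)
  for (i in 1:20) {
    px <- matrix(runif(256), 16, 16)
    sr <- sample(16, 1); sc <- sample(16, 1)
    tols <- sort(runif(3, 0, 0.6))
    prev <- NULL
    for (tol in tols) {
      roi <- region_grow(gray_image(px, c(0, 1)),
                         seed_point(sr, sc, px[sr, sc]),
                         grow_params(tolerance = tol, criterion = "fixed_seed",
                                     max_region_fraction = 1))
      if (!is.null(prev)) expect_true(all(roi$mask[prev]))
      prev <- roi$mask
    }
  }
})

test_that("running-mean growing is deterministic and contains the seed", {
  set.seed(75)
  px <- matrix(runif(1024), 32, 32)
  img <- gray_image(px, c(0, 1))
  sp <- seed_point(16, 16, px[16, 16])
  a <- region_grow(img, sp, grow_params(tolerance = 0.2))
  b <- region_grow(img, sp, grow_params(tolerance = 0.2))
  expect_identical(a$mask, b$mask)
  expect_true(a$mask[16, 16])
  # the grown region is one connected component under the configured connectivity
  lab <- oracle_label(a$mask, 8)
  expect_equal(length(lab$sizes), 1)
})

test_that("excluded pixels are never accepted; excluded seed gives an empty degenerate region", {
  px <- matrix(0.5, 10, 10)
  img <- gray_image(px, c(0, 1))
  allowed <- matrix(TRUE, 10, 10); allowed[, 6:10] <- FALSE
  roi <- region_grow(img, seed_point(5, 3, 0.5),
                     grow_params(max_region_fraction = 1), allowed = allowed)
  expect_false(any(roi$mask[, 6:10]))
  expect_equal(roi$n_pixels, 50)
  # seed on an excluded (stripped-out) pixel
  off <- region_grow(img, seed_point(5, 8, 0.5),
                     grow_params(max_region_fraction = 1), allowed = allowed)
  expect_equal(off$n_pixels, 0)
  expect_true(off$degenerate)
  # seed outside the image errors
  expect_error(region_grow(img, seed_point(15, 3, 0.5)), "outside")
})

test_that("postprocess_roi fills a grown bright rim to include a dark core", {
  px <- matrix(0.1, 20, 20)
  px[5:15, 5:15] <- 0.9      # bright block
  px[8:12, 8:12] <- 0.2      # dark core: growth leaves a hole
  img <- gray_image(px, c(0, 1))
  roi <- region_grow(img, seed_point(6, 6, 0.9), grow_params(tolerance = 0.1))
  expect_false(any(roi$mask[9:11, 9:11]))
  filled <- postprocess_roi(roi)
  expect_true(all(filled$mask[8:12, 8:12]))
  expect_true(all(filled$mask[roi$mask]))
  expect_equal(filled$n_pixels, sum(filled$mask))
  # idempotent on a solid region
  expect_identical(postprocess_roi(filled)$mask, filled$mask)
})
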