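# Manifest parsing, ROI extraction, preprocessing and augmentation.

test_that("manifests parse from CSV and JSON with label mapping", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("image_id,center_x,center_y,radius,label",
               "a,10,12,5,normal",
               "b,20,22,6,fgr"), csv)
  m <- load_manifest(csv)
  expect_equal(m$image_id, c("a", "b"))
  expect_equal(m$label, c(0L, 1L))
  expect_equal(m$radius, c(5, 6))

  js <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(data.frame(
    image_id = "c", center_x = 1, center_y = 2, radius = 3,
    label = "fgr")), js)
  mj <- load_manifest(js)
  expect_equal(mj$label, 1L)

  empty <- tempfile(fileext = ".csv")
  writeLines("image_id,center_x,center_y,radius,label", empty)
  expect_equal(nrow(load_manifest(empty)), 0L)
})

test_that("manifest validation rejects bad columns, labels and radii", {
  bad_col <- tempfile(fileext = ".csv")
  writeLines(c("image_id,center_x,center_y,label", "a,1,2,normal"), bad_col)
  expect_error(load_manifest(bad_col), "radius")

  bad_lab <- tempfile(fileext = ".csv")
  writeLines(c("image_id,center_x,center_y,radius,label",
               "a,1,2,3,weird"), bad_lab)
  expect_error(load_manifest(bad_lab), "weird")

  bad_r <- tempfile(fileext = ".csv")
  writeLines(c("image_id,center_x,center_y,radius,label",
               "a,1,2,0,normal"), bad_r)
  expect_error(load_manifest(bad_r), "radius|positive")
})

test_that("ROI extraction crops, masks and zero-pads correctly", {
  img <- matrix(0.5, 60, 60)
  roi <- extract_roi(img, 30, 30, 10)
  expect_equal(dim(roi$pixels), c(21L, 21L))
  expect_true(all(roi$pixels[roi$mask] == 0.5))
  expect_true(all(roi$pixels[!roi$mask] == 0))

  # mask area matches brute-force circle rasterization exactly
  r <- 50
  img2 <- matrix(1, 201, 201)
  roi2 <- extract_roi(img2, 100, 100, r)
  brute <- 0L
  for (x in 0:200) for (y in 0:200) {
    if ((x - 100)^2 + (y - 100)^2 <= r^2) brute <- brute + 1L
  }
  expect_identical(sum(roi2$mask), brute)
  expect_lt(abs(sum(roi2$mask) - pi * r^2), r)

  # circle centered at the corner: padded region flagged outside
  roi3 <- extract_roi(img, 0, 0, 10)
  expect_equal(dim(roi3$pixels), c(21L, 21L))
  expect_false(any(roi3$mask[1:10, 1:10]))   # padded quadrant
  expect_true(all(roi3$pixels[!roi3$mask] == 0))

  expect_error(extract_roi(img, 200, 200, 10), "outside")
})

test_that("wavelet denoising preserves constants and reduces noise", {
  const <- matrix(0.4, 32, 32)
  expect_equal(denoise_wavelet(const), const)

  set.seed(7)
  noisy <- clamp_to_unit <- pmin(pmax(matrix(0.5 + rnorm(64 * 64, 0, 0.05),
                                             64, 64), 0), 1)
  den <- denoise_wavelet(noisy)
  expect_lt(var(as.vector(den)), var(as.vector(noisy)))
  expect_true(all(den >= 0 & den <= 1))

  # shrinkage removes most energy on the first pass
  den2 <- denoise_wavelet(den)
  d1 <- sqrt(sum((den - noisy)^2))
  d2 <- sqrt(sum((den2 - den)^2))
  expect_lt(d2, d1)
})

test_that("histogram equalization follows the masked CDF and is monotone", {
  # two-level image: half 0.2, half 0.8 -> CDF maps to 0.5 and 1.0
  img <- matrix(c(rep(0.2, 32), rep(0.8, 32)), 8, 8)
  eq <- equalize_hist(img)
  expect_equal(unique(eq[img == 0.2]), 0.5)
  expect_equal(unique(eq[img == 0.8]), 1.0)

  # already-uniform histogram is close to a fixed point (<= 1 bin width)
  u <- matrix((0:255) / 255, 16, 16)
  equ <- equalize_hist(u)
  expect_lt(max(abs(equ - u)), 1 / 256 + 1e-12)

  # monotonicity of the mapping
  set.seed(3)
  r <- matrix(runif(400), 20, 20)
  er <- equalize_hist(r)
  o <- order(as.vector(r))
  expect_true(all(diff(as.vector(er)[o]) >= -1e-12))

  expect_error(equalize_hist(r, matrix(FALSE, 20, 20)), "mask")
})

test_that("augmentation honors identity configs and seeds", {
  img <- seeded_image(48, 48, 11)
  ident <- augment_config(brightness_delta_range = c(0, 0),
                          contrast_factor_range = c(1, 1),
                          rotation_range_deg = c(0, 0),
                          crop_fraction = 1, n_augments_per_image = 3L)
  out <- augment(img, ident, seed = 5)
  for (v in out) expect_identical(v, img)

  cfg <- augment_config(n_augments_per_image = 2L)
  a1 <- augment(img, cfg, seed = 9)
  a2 <- augment(img, cfg, seed = 9)
  expect_identical(a1, a2)
  expect_false(identical(a1[[1]], img))
  for (v in a1) expect_true(all(v >= 0 & v <= 1))
})

test_that("rotation round-trips interior pixels within tolerance", {
  base <- gaussian_filter_image(seeded_image(64, 64, 21), 2)
  theta <- 13.7
  back <- rotate_image(rotate_image(base, theta), -theta)
  interior <- 20:44
  expect_lt(max(abs(back[interior, interior] - base[interior, interior])),
            0.02)
})

test_that("augmentation transforms the ROI mask consistently", {
  roi <- synthetic_roi("normal", seed = 31)
  cfg <- augment_config(n_augments_per_image = 2L)
  out <- augment(roi$pixels, cfg, seed = 13, mask = roi$mask)
  for (v in out) {
    expect_named(v, c("pixels", "mask"))
    expect_identical(dim(v$mask), dim(roi$mask))
    # conservative mask: transformed mask never exceeds a small dilation of
    # the original circular support
    expect_lte(sum(v$mask), sum(roi$mask) * 1.05)
  }
})
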