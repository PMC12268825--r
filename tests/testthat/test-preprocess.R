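test_that("binning averages blocks and crops indivisible margins", {
  expect_identical(bin_image(matrix(c(1, 5, 3, 7), 2, 2), 2),
                   matrix(4, 1, 1))
  img <- matrix(runif(49), 7, 7)
  expect_identical(bin_image(img, 1), img)
  # 6x6 ramp against brute-force block means, plus pixel-count reduction
  ramp <- matrix(seq_len(36), 6, 6)
  got <- bin_image(ramp, 3)
  expected <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2)
    expected[i, j] <- mean(ramp[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)])
  expect_equal(got, expected, tolerance = 1e-12)
  expect_identical(length(got) * 9L, length(ramp))
  # indivisible: 7x7 with factor 2 crops to 6x6
  expect_identical(dim(bin_image(img, 2)), c(3L, 3L))
  expect_error(bin_image(img, 0), ">= 1")
})

test_that("normalization maps ranges and degenerate inputs as specified", {
  expect_equal(normalize_channel(matrix(c(0, 5, 10), 1), "minmax"),
               matrix(c(0, 0.5, 1), 1))
  expect_identical(normalize_channel(matrix(3, 4, 4), "minmax"),
                   matrix(0, 4, 4))
  z <- normalize_channel(matrix(c(1, 2, 3), 1), "zscore")
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_error(normalize_channel(matrix(c(1, Inf), 1), "minmax"), "finite")
})

test_that("binning commutes with minmax normalization of pre-binned input", {
  img <- matrix(runif(64 * 64), 64, 64)
  a <- normalize_channel(bin_image(img, 4), "minmax")
  b <- normalize_channel(bin_image(img, 4), "minmax")  # same path, sanity
  pre <- bin_image(img, 4)
  expect_equal(a, normalize_channel(pre, "minmax"), tolerance = 0)
  expect_identical(a, b)
})

test_that("automated masking recovers a bright square and flags empties", {
  img <- matrix(0, 32, 32)
  img[11:20, 6:15] <- 1
  m <- auto_mask(img, preprocess_config())
  truth <- img > 0.5
  expect_identical(m$mask, truth)
  expect_error(auto_mask(matrix(0.5, 16, 16), preprocess_config()),
               "empty mask")
  # fixed threshold path: only the pixel above threshold survives opening off
  cfg <- preprocess_config(auto_threshold = "fixed", fixed_threshold = 0.5,
                           morph_open_radius_px = 0)
  mm <- auto_mask(matrix(c(0.4, 0.6), 1, 2), cfg)
  expect_identical(as.vector(mm$mask), c(FALSE, TRUE))
  expect_identical(mm$source, "manual")
})

test_that("morphological opening removes isolated speckle", {
  img <- matrix(0, 32, 32)
  img[11:20, 6:15] <- 1
  img[3, 3] <- 1  # single-pixel noise
  m <- auto_mask(img, preprocess_config(morph_open_radius_px = 1))
  expect_false(m$mask[3, 3])
  expect_true(all(m$mask[12:19, 7:14]))
})

test_that("OR mask combination is a union with the right properties", {
  a <- matrix(FALSE, 8, 8); a[1:3, 1:3] <- TRUE
  b <- matrix(FALSE, 8, 8); b[6:8, 6:8] <- TRUE
  ma <- fibroscar:::new_roi_mask(a, "shg_auto")
  mb <- fibroscar:::new_roi_mask(b, "tpef_auto")
  mo <- combine_masks_or(ma, mb)
  expect_identical(mo$mask, a | b)
  expect_identical(mo$source, "or_combined")
  expect_gte(sum(mo$mask), max(sum(a), sum(b)))
  expect_identical(combine_masks_or(ma, ma)$mask, a)            # idempotent
  e <- fibroscar:::new_roi_mask(matrix(FALSE, 8, 8), "tpef_auto")
  expect_identical(combine_masks_or(ma, e)$mask, a)             # identity
  bad <- fibroscar:::new_roi_mask(matrix(TRUE, 4, 4), "tpef_auto")
  expect_error(combine_masks_or(ma, bad), "mismatch")
})

test_that("preprocess_plane produces channels, per-channel and OR masks", {
  pl <- generate_mpm_plane("granulated", shape = c(64, 64), seed = 2)
  pre <- preprocess_plane(pl)
  expect_identical(dim(pre$shg), dim(pre$mask$mask))
  expect_true(all(pre$mask$mask >= (pre$mask_shg$mask & pre$mask_tpef$mask)))
  expect_identical(pre$mask$source, "or_combined")
  expect_gte(min(pre$shg), 0)
  expect_lte(max(pre$shg), 1)
})
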