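all_mask <- function(m) matrix(TRUE, nrow(m), ncol(m))

dimg <- function(levels, n_levels = max(levels)) {
  msk <- levels > 0
  structure(list(levels = levels, n_levels = n_levels, mask = msk),
            class = "discretized_image")
}

test_that("discretization follows the fixed-bin-number formula", {
  d <- discretize(matrix(c(0, 0.5, 1), 1, 3), matrix(TRUE, 1, 3), 2)
  expect_identical(as.vector(d$levels), c(1L, 2L, 2L))
  dc <- discretize(matrix(5, 3, 3), matrix(TRUE, 3, 3), 8)
  expect_true(all(dc$levels == 1L))
  # brute-force per-pixel application of the formula
  set.seed(11)
  img <- matrix(runif(100), 10, 10)
  msk <- matrix(runif(100) < 0.7, 10, 10); msk[1, 1] <- TRUE
  d8 <- discretize(img, msk, 8)
  mn <- min(img[msk]); mx <- max(img[msk])
  for (k in which(msk))
    expect_identical(d8$levels[k],
                     min(8L, as.integer(floor(8 * (img[k] - mn) / (mx - mn))) + 1L))
  expect_true(all(d8$levels[!msk] == 0L))
  expect_error(discretize(img, msk & FALSE, 8), "empty mask")
  expect_error(discretize(img, msk, 1), ">= 2")
})

test_that("GLRLM counts runs as defined, including the hand examples", {
  row5 <- dimg(matrix(c(1L, 1L, 2L, 2L, 2L), 1, 5))
  m <- compute_glrlm(row5, direction = "0")
  expect_equal(m[1, 2], 1)   # one run of level 1, length 2
  expect_equal(m[2, 3], 1)   # one run of level 2, length 3
  expect_equal(sum(m), 2)
  expect_equal(feature_sre(m), 13 / 72, tolerance = 1e-12)

  const4 <- dimg(matrix(2L, 4, 4), n_levels = 2)
  m0 <- compute_glrlm(const4, direction = "0")
  expect_equal(m0[2, 4], 4)  # four rows, each one run of length 4
  expect_equal(feature_sre(m0), 4 * (1 / 16) / 4, tolerance = 1e-12)

  # isolated single pixels: all runs length 1 -> SRE attains 1
  iso <- matrix(0L, 5, 5); iso[cbind(c(1, 3, 5), c(1, 3, 5))] <- 1L
  expect_equal(feature_sre(compute_glrlm(dimg(iso, 1), "0")), 1)
})

test_that("NGLDM dependence counts match the constant 3x3 hand example", {
  d <- dimg(matrix(1L, 3, 3), n_levels = 1)
  s <- compute_ngldm(d, alpha = 0)
  expect_equal(s[1, 4], 4)   # corners
  expect_equal(s[1, 6], 4)   # edges
  expect_equal(s[1, 9], 1)   # center
  expect_equal(feature_hdhge(s, 9), 289 / 9, tolerance = 1e-12)
  # single in-mask pixel: dependence 1, HDHGE = i^2
  lone <- matrix(0L, 4, 4); lone[2, 2] <- 3L
  s1 <- compute_ngldm(dimg(lone, 4), alpha = 0)
  expect_equal(s1[3, 1], 1)
  expect_equal(feature_hdhge(s1, 1), 9)
})

test_that("NGTDM strength matches the 2x2 hand computation", {
  d <- dimg(matrix(c(1L, 2L, 2L, 1L), 2, 2))
  ng <- compute_ngtdm(d)
  expect_equal(ng$s[1], 4 / 3, tolerance = 1e-12)
  expect_equal(ng$s[2], 4 / 3, tolerance = 1e-12)
  expect_equal(ng$p, c(0.5, 0.5))
  expect_equal(feature_texture_strength(ng), 2 / (1e-12 + 8 / 3),
               tolerance = 1e-9)
  # constant image: single level, zero numerator
  expect_equal(feature_texture_strength(compute_ngtdm(dimg(matrix(1L, 4, 4)))),
               0)
})

test_that("intensity range and local peak match their contracts", {
  img <- matrix(c(2, 7, 3, 9), 2, 2)
  msk <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  expect_identical(feature_intensity_range(img, msk), 5)  # {2,7,3}
  cst <- matrix(4, 6, 6)
  expect_identical(feature_intensity_range(cst, all_mask(cst)), 0)
  expect_identical(feature_local_intensity_peak(cst, all_mask(cst), 2), 4)
  expect_error(feature_intensity_range(img, msk & FALSE), "empty mask")
})

test_that("texture matrices satisfy their conservation invariants", {
  set.seed(21)
  for (rep in 1:10) {
    d <- oracle_fixture(sample(5:10, 1), sample(5:10, 1), sample(3:6, 1))
    nv <- sum(d$mask)
    P <- compute_glcm(d)
    if (sum(P) > 0) expect_equal(sum(P), 1, tolerance = 1e-12)
    m <- compute_glrlm(d)
    lens <- matrix(rep(seq_len(ncol(m)), each = nrow(m)), nrow(m))
    expect_equal(sum(m * lens), 4 * nv)    # each direction covers every pixel
    s <- compute_ngldm(d)
    expect_equal(sum(s), nv)
    ng <- compute_ngtdm(d)
    expect_equal(sum(ng$p), if (ng$n_valid > 0) 1 else 0, tolerance = 1e-12)
    z <- compute_zone_matrices(d)
    expect_equal(sum(z$szm$j * z$szm$n), nv)   # zone sizes cover the mask
    expect_equal(sum(z$dzm$n), sum(z$szm$n))   # same zones in both matrices
  }
})

test_that("fragmenting a run never decreases SRE", {
  # replacing one run of length 2k by two runs of length k increases the
  # short-run weight at fixed gray level
  for (k in c(1, 2, 4, 8)) {
    whole <- matrix(c(rep(1L, 2 * k), 0L), 1)
    split_ <- matrix(c(rep(1L, k), 0L, rep(1L, k)), 1)
    expect_gte(feature_sre(compute_glrlm(dimg(whole, 1), "0")),
               0)
    expect_gte(feature_sre(compute_glrlm(dimg(split_, 1), "0")),
               feature_sre(compute_glrlm(dimg(whole, 1), "0")))
  }
})

test_that("direction-aggregated features are invariant to 90-degree rotation", {
  set.seed(31)
  img <- matrix(runif(144), 12, 12)
  msk <- matrix(runif(144) < 0.85, 12, 12); msk[5, 5] <- TRUE
  rot <- function(m) t(m)[, nrow(m):1]  # 90-degree rotation
  f1 <- extract_channel_features(img, msk)
  f2 <- extract_channel_features(rot(img), rot(msk))
  expect_equal(f1, f2, tolerance = 1e-10)
})
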