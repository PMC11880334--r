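test_that("level quantization bins uniformly and handles constants", {
  expect_equal(as.vector(quantize_levels(matrix(c(0, 255), 1, 2), 2)), c(0, 1))
  expect_true(all(quantize_levels(matrix(7, 4, 4), 8) == 0))
  ramp <- matrix(seq(0, 255, length.out = 256), 16, 16)
  counts <- tabulate(quantize_levels(ramp, 8) + 1, 8)
  expect_lte(max(counts) - min(counts), 1) # near-equal occupancy
})

test_that("a 2x2 example matches the hand-enumerated pair set", {
  img <- matrix(c(0, 2, 1, 3), 2, 2) # rows: (0,1),(2,3)
  m <- compute_glcm(img, d = 1, angle = 0, symmetric = FALSE, G = 4)
  expected <- matrix(0, 4, 4)
  expected[1, 2] <- 0.5 # pair (0,1)
  expected[3, 4] <- 0.5 # pair (2,3)
  expect_equal(m$p, expected)
})

test_that("glcm equals the brute-force pair enumeration exactly", {
  set.seed(20)
  for (rep in 1:10) {
    img <- matrix(sample(0:7, 16 * 16, replace = TRUE), 16, 16)
    for (ang in c(0, 45, 90, 135)) {
      for (d in 1:2) {
        for (sym in c(TRUE, FALSE)) {
          m <- compute_glcm(img, d = d, angle = ang, symmetric = sym, G = 8)
          expect_equal(m$p, glcm_bruteforce(img, d, ang, sym, 8),
                       tolerance = 1e-15)
          expect_equal(sum(m$p), 1, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("contrast and correlation reproduce their closed-form anchors", {
  # constant image: all mass at (0,0)
  cst <- compute_glcm(matrix(0L, 6, 6), 1, 0, TRUE, G = 2)
  expect_equal(glcm_contrast(cst), 0)
  corr <- glcm_correlation(cst)
  expect_equal(as.numeric(corr), 0)
  expect_true(attr(corr, "degenerate"))
  # checkerboard: every horizontal pair differs by exactly one level
  cb <- outer(1:8, 1:8, function(r, c) (r + c) %% 2)
  m <- compute_glcm(cb, 1, 0, TRUE, G = 2)
  expect_equal(glcm_contrast(m), 1)
  expect_equal(as.numeric(glcm_correlation(m)), -1)
  # perfectly banded image: all pairs (k, k) along rows
  band <- matrix(rep(0:3, each = 8), 8, 4)
  mb0 <- compute_glcm(t(band), 1, 0, TRUE, G = 4) # all pairs on the diagonal
  expect_equal(as.numeric(glcm_correlation(mb0)), 1)
  expect_equal(glcm_contrast(mb0), 0)
  # transpose leaves contrast of a symmetric matrix unchanged
  set.seed(21)
  img <- matrix(sample(0:7, 100, replace = TRUE), 10, 10)
  ms <- compute_glcm(img, 1, 0, TRUE, G = 8)
  expect_equal(glcm_contrast(ms), sum(outer(0:7, 0:7, "-")^2 * t(ms$p)))
})

test_that("correlation stays within [-1, 1] on random images", {
  set.seed(22)
  for (rep in 1:20) {
    img <- matrix(sample(0:7, 64, replace = TRUE), 8, 8)
    for (ang in c(0, 45, 90, 135)) {
      r <- as.numeric(glcm_correlation(compute_glcm(img, 1, ang, TRUE, G = 8)))
      expect_gte(r, -1 - 1e-12)
      expect_lte(r, 1 + 1e-12)
    }
  }
})

test_that("feature vectors have 10 named values with documented structure", {
  luv <- rgb_to_luv(random_rgb(16, 16, seed = 23))
  fv <- feature_vector(luv)
  expect_length(fv, 10)
  expect_named(fv, c("src_L_contrastL", "src_L_corrL", "src_L_contrastL2",
                     "src_L_corrL2", "src_L_mean", "src_C_contrastL",
                     "src_C_corrL", "src_C_contrastL2", "src_C_corrL2",
                     "src_C_mean"))
  expect_true(all(fv[grep("contrast", names(fv))] >= 0))
  expect_equal(fv[["src_L_mean"]], mean(luv$L))
  # constant image: zero contrasts, degenerate correlations, means = values
  flat <- luv_image(matrix(50, 8, 8), matrix(2, 8, 8), matrix(-3, 8, 8))
  fvc <- feature_vector(flat)
  expect_equal(unname(fvc[c(1, 2, 3, 4)]), c(0, 0, 0, 0))
  expect_equal(fvc[["src_C_mean"]], sqrt(4 + 9))
})

test_that("offset averaging makes features invariant to transposition", {
  luv <- rgb_to_luv(random_rgb(12, 12, seed = 24))
  tluv <- luv_image(t(luv$L), t(luv$u), t(luv$v))
  expect_equal(feature_vector(luv), feature_vector(tluv), tolerance = 1e-12)
})

test_that("image smaller than the offset raises an argument error", {
  expect_error(compute_glcm(matrix(0L, 2, 2), d = 3, angle = 0), "offset")
})
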