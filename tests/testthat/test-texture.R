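test_that("quantization maps endpoints and degenerate ranges as specified", {
  expect_true(all(quantize_band(matrix(0.7, 5, 5)) == 0L))
  b <- matrix(runif(100, 0.2, 0.8), 10, 10)
  b[1] <- 0.2; b[100] <- 0.8
  q <- quantize_band(b, 64)
  expect_equal(q[1], 0L)
  expect_equal(q[100], 63L)
  expect_true(all(q >= 0 & q <= 63))
})

test_that("a linear ramp quantizes to a near-uniform level histogram", {
  ramp <- matrix(seq(0, 1, length.out = 64^2), 64, 64)
  q <- quantize_band(ramp, 64)
  h <- tabulate(q + 1L, nbins = 64)
  expect_lte(max(h) / min(h), 1.05)
})

test_that("single-window GLCM matches exhaustive pair enumeration", {
  w_const <- matrix(0L, 7, 7)
  P <- glcm_for_window(w_const, c(2, 2), gray_levels = 4)
  expect_equal(P[1, 1], 1)
  expect_equal(sum(P), 1)

  checker <- outer(1:6, 1:6, function(r, c) (r + c) %% 2)
  Pc <- glcm_for_window(checker, c(1, 1), gray_levels = 2)
  expect_equal(Pc[1, 2] + Pc[2, 1], 0)  # diagonal pairs share parity
  expect_equal(Pc[1, 1] + Pc[2, 2], 1)

  set.seed(21)
  for (i in 1:20) {
    w <- matrix(sample(0:7, 49, replace = TRUE), 7, 7)
    expect_equal(glcm_for_window(w, c(2, 2), gray_levels = 8),
                 bf_glcm(w, c(2, 2), 8), tolerance = 1e-14)
  }
  expect_error(glcm_for_window(matrix(0L, 2, 2), c(3, 3)), "no valid")
})

test_that("Haralick metrics match the brute-force double loop to 1e-10", {
  # degenerate single-cell matrix
  m0 <- haralick_metrics(glcm_for_window(matrix(2L, 7, 7), c(2, 2),
                                         gray_levels = 4))
  expect_equal(m0[["contrast"]], 0)
  expect_equal(m0[["dissimilarity"]], 0)
  expect_equal(m0[["entropy"]], 0)
  expect_equal(m0[["secondmoment"]], 1)
  expect_equal(m0[["homogeneity"]], 1)
  expect_equal(m0[["variance"]], 0)
  expect_equal(m0[["correlation"]], 1)

  P <- matrix(0, 2, 2); P[1, 1] <- 0.5; P[2, 2] <- 0.5
  expect_equal(haralick_metrics(P)[["entropy"]], log(2))

  set.seed(31)
  for (i in 1:120) {
    w <- matrix(sample(0:15, 49, replace = TRUE), 7, 7)
    P <- glcm_for_window(w, c(2, 2), gray_levels = 16)
    expect_equal(haralick_metrics(P), bf_haralick(P), tolerance = 1e-10)
  }
})

test_that("contrast and dissimilarity are invariant to a gray-level shift", {
  set.seed(5)
  w <- matrix(sample(0:9, 49, replace = TRUE), 7, 7)
  m1 <- haralick_metrics(glcm_for_window(w, c(2, 2), gray_levels = 16))
  m2 <- haralick_metrics(glcm_for_window(w + 4L, c(2, 2), gray_levels = 16))
  expect_equal(m1[["contrast"]], m2[["contrast"]])
  expect_equal(m1[["dissimilarity"]], m2[["dissimilarity"]])
  expect_equal(m1[["entropy"]], m2[["entropy"]])
})

test_that("plot texture aggregation matches brute-force window recomputation", {
  set.seed(8)
  nr <- 30; nc <- 30
  bands <- constant_band_list(0, nr, nc)
  for (b in names(bands)) bands[[b]] <- matrix(runif(nr * nc), nr, nc)
  mask <- matrix(0L, nr, nc)
  mask[4:27, 3:28] <- 1L
  sc <- make_flat_scene(bands, mask)
  tf <- texture_features_for_plot(sc, 1)
  expect_length(tf, 40)
  expect_identical(names(tf), TEXTURE_NAMES)

  cfg <- glcm_config()
  for (b in c("R", "NIR")) {
    q <- quantize_band(bands[[b]], cfg$gray_levels)
    acc <- NULL
    for (cr in 4:27) {
      for (cc in 3:28) {
        rows <- (cr - 3):(cr + 3); cols <- (cc - 3):(cc + 3)
        if (min(rows) < 1 || max(rows) > nr || min(cols) < 1 || max(cols) > nc) next
        if (!all(mask[rows, cols] == 1L)) next
        P <- bf_glcm(q[rows, cols], c(2, 2), cfg$gray_levels)
        acc <- rbind(acc, bf_haralick(P))
      }
    }
    expected <- colMeans(acc)
    metrics <- c("mean", "variance", "homogeneity", "contrast",
                 "dissimilarity", "entropy", "secondmoment", "correlation")
    got <- tf[paste(b, metrics, sep = "-")]
    expect_equal(unname(got), unname(expected), tolerance = 1e-9)
  }
})

test_that("constant scenes give zero contrast and unit second moment per band", {
  sc <- make_flat_scene(constant_band_list(0.4, 12, 12))
  tf <- texture_features_for_plot(sc, 1)
  for (b in c("R", "G", "B", "NIR", "RE")) {
    expect_equal(tf[[paste0(b, "-contrast")]], 0)
    expect_equal(tf[[paste0(b, "-secondmoment")]], 1)
    expect_equal(tf[[paste0(b, "-correlation")]], 1)
  }
})

test_that("plots without a full window are rejected", {
  mask <- matrix(0L, 12, 12); mask[1:4, 1:4] <- 1L
  sc <- make_flat_scene(constant_band_list(0.5, 12, 12), mask)
  expect_error(texture_features_for_plot(sc, 1), "window")
})

test_that("glcm_config validates its geometry", {
  expect_error(glcm_config(window = 6), "odd")
  expect_error(glcm_config(offset = c(7, 0)), "smaller")
  expect_error(glcm_config(gray_levels = 1), ">= 2")
})
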