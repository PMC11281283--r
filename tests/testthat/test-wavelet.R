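test_that("the forward transform matches the reference bior 1.3 convention", {
  # frozen oracle values computed with PyWavelets (symmetric mode) for 1:8
  f <- bior13_filters()
  x <- matrix(as.numeric(1:8), ncol = 1)
  cA <- as.vector(spaduav:::dwt_pass_dim1(x, f$dec_lo))
  cD <- as.vector(spaduav:::dwt_pass_dim1(x, f$dec_hi))
  expect_equal(cA, c(1.94454365, 1.94454365, 4.94974747, 7.77817459,
                     10.78337841, 10.78337841), tolerance = 1e-8)
  expect_equal(cD, c(0.70710678, -0.70710678, -0.70710678, -0.70710678,
                     -0.70710678, 0.70710678), tolerance = 1e-8)
  expect_equal(sum(f$dec_lo), sqrt(2))
})

test_that("a constant raster yields LL = 2c and zero detail", {
  sb <- dwt2_single_level(matrix(3, 10, 12))
  expect_setequal(names(sb), c("LL", "LH", "HL", "HH"))
  expect_true(all(abs(sb$LL - 6) < 1e-12))
  expect_true(all(abs(sb$LH) < 1e-12))
  expect_true(all(abs(sb$HL) < 1e-12))
  expect_true(all(abs(sb$HH) < 1e-12))
  # sub-band dimensions follow floor((n + 5) / 2)
  expect_equal(dim(sb$LL), c(7, 8))
})

test_that("analysis/synthesis is perfectly reconstructing on random rasters", {
  set.seed(17)
  for (i in 1:10) {
    x <- matrix(rnorm(32 * 32), 32, 32)
    rec <- idwt2_single_level(dwt2_single_level(x))
    expect_lt(max(abs(rec - x)), 1e-8)
  }
  # non-square even case
  x <- matrix(runif(24 * 40), 24, 40)
  expect_lt(max(abs(idwt2_single_level(dwt2_single_level(x)) - x)), 1e-8)
})

test_that("the transform is linear and detail energy vanishes for smooth input", {
  set.seed(4)
  x <- matrix(rnorm(100), 10, 10)
  a <- dwt2_single_level(x)
  b <- dwt2_single_level(3.5 * x)
  for (s in c("LL", "LH", "HL", "HH")) {
    expect_equal(b[[s]], 3.5 * a[[s]], tolerance = 1e-12)
  }
  smooth <- dwt2_single_level(matrix(5, 16, 16))
  expect_equal(sum(smooth$LH^2) + sum(smooth$HL^2) + sum(smooth$HH^2), 0)
})

test_that("rasters smaller than the filter support are rejected", {
  expect_error(dwt2_single_level(matrix(1, 4, 10)), "filter")
})

test_that("plot wavelet features: count, constant case, orientation selectivity", {
  sc <- make_flat_scene(constant_band_list(0.5, 16, 16))
  wf <- wavelet_features_for_plot(sc, 1)
  expect_length(wf, 20)
  expect_identical(names(wf), WAVELET_NAMES)
  for (b in c("R", "G", "B", "NIR", "RE")) {
    expect_equal(wf[[paste0(b, "_LL")]], 1.0, tolerance = 1e-12)
    expect_equal(wf[[paste0(b, "_LH")]], 0, tolerance = 1e-12)
    expect_equal(wf[[paste0(b, "_HH")]], 0, tolerance = 1e-12)
  }

  # horizontal stripes (alternating rows): energy goes to LH, not HL
  stripes <- matrix(rep(c(0.2, 0.8), 8), 16, 16)
  bands <- constant_band_list(0.5, 16, 16)
  bands$R <- stripes
  sc2 <- make_flat_scene(bands)
  wf2 <- wavelet_features_for_plot(sc2, 1, abs_detail = TRUE)
  expect_gt(wf2[["R_LH"]], 10 * wf2[["R_HL"]])
})

test_that("wavelet_features returns 20 columns for all 72 plots", {
  inp <- make_test_inputs(seed = 1, base_gsd = 8)
  wf <- wavelet_features(inp$scene)
  expect_equal(nrow(wf), 72)
  expect_identical(colnames(wf), c("plot_id", WAVELET_NAMES))
  expect_true(all(is.finite(as.matrix(wf[, -1]))))
})

test_that("a plot vanishing at sub-band resolution is an error", {
  mask <- matrix(0L, 16, 16)
  mask[1, 1] <- 2L  # single pixel that may vanish after downsampling
  mask[5:12, 5:12] <- 1L
  sc <- make_flat_scene(constant_band_list(0.5, 16, 16), mask)
  sb <- lapply(sc$bands, dwt2_single_level)
  ds <- spaduav:::mask_to_subband(sc$mask, dim(sb[[1]]$LL))
  if (!any(ds == 2L)) {
    expect_error(wavelet_features_for_plot(sc, 2), "vanished")
  } else {
    succeed("mask survived downsampling at this geometry")
  }
})
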