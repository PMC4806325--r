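# Filter-bank classes: hand limits, symmetry properties and direct-
# convolution oracles.

test_that("Laws energies vanish on constants, respond to ramps and match
           direct convolution", {
  cst <- slice_fixture(matrix(7, 8, 8))
  expect_true(all(laws_features(cst$grid, cst$mask) == 0))

  ramp <- slice_fixture(matrix(rep(1:10, each = 10), 10, 10))  # ramp along x
  lr <- laws_features(ramp$grid, ramp$mask)
  expect_gt(unname(lr["Laws_L5E5"]), 0)
  # S5 is a second-difference operator: annihilates the linear ramp away
  # from boundary reflections
  expect_lt(unname(lr["Laws_S5S5"]), unname(lr["Laws_L5E5"]) / 10)

  set.seed(31)
  img <- matrix(rnorm(81), 9, 9)
  msk <- matrix(runif(81) > 0.2, 9, 9)
  fx <- slice_fixture(img, msk)
  got <- laws_features(fx$grid, fx$mask)
  expect_equal(unname(got), oracle_laws(img, msk), tolerance = 1e-10)
})

test_that("edge frequency is linear in contrast and matches the pair
           enumerator", {
  cst <- slice_fixture(matrix(7, 6, 6))
  ef0 <- edge_frequency_features(cst$grid, cst$mask)
  expect_equal(unname(ef0[1:3]), c(0, 0, 0))
  expect_equal(unname(ef0["EdgeFreqCoarseness"]), 1)

  step1 <- matrix(0, 6, 12); step1[, 7:12] <- 50
  step2 <- matrix(0, 6, 12); step2[, 7:12] <- 100
  f1 <- slice_fixture(step1); f2 <- slice_fixture(step2)
  e1 <- edge_frequency_features(f1$grid, f1$mask)
  e2 <- edge_frequency_features(f2$grid, f2$mask)
  expect_equal(unname(e2["EdgeFreq1"] / e1["EdgeFreq1"]), 2, tolerance = 1e-12)

  set.seed(17)
  img <- matrix(rnorm(64), 8, 8)
  msk <- matrix(runif(64) > 0.15, 8, 8)
  fx <- slice_fixture(img, msk)
  expect_equal(unname(edge_frequency_features(fx$grid, fx$mask)),
               oracle_edge_freq(list(img), list(msk)), tolerance = 1e-10)
})

test_that("Gabor filters are orientation-selective and DC-free", {
  img <- matrix(rep(100 * sin(2 * pi * (1:16) / 4), each = 16), 16, 16)
  fx <- slice_fixture(img)                       # grating varying along x
  g <- gabor_features(fx$grid, fx$mask)
  expect_gt(unname(g["GaborEnergy0"] / g["GaborEnergy90"]), 5)
  # rotating the grating 90 degrees swaps the two energies
  fxT <- slice_fixture(t(img))
  gT <- gabor_features(fxT$grid, fxT$mask)
  expect_equal(unname(gT["GaborEnergy90"]), unname(g["GaborEnergy0"]),
               tolerance = 0.05)
  expect_equal(unname(gT["GaborEnergy0"]), unname(g["GaborEnergy90"]),
               tolerance = 0.05)
  # constant image: below 1e-6 of the input power
  cst <- slice_fixture(matrix(77, 16, 16))
  gc <- gabor_features(cst$grid, cst$mask)
  expect_lt(max(gc), 1e-6 * 77^2)
})

test_that("Haar subband energies satisfy Parseval and hand transforms", {
  # hand Haar: level-1 LL of [[a,a],[a,a]] is 2a under orthonormal scaling,
  # giving per-pixel LL energy a^2 and zero detail energy
  l1 <- radrepro:::haar_level(matrix(3, 2, 2))
  expect_equal(l1$LL[1, 1], 6)
  expect_equal(c(l1$LH[1, 1], l1$HL[1, 1], l1$HH[1, 1]), c(0, 0, 0))

  cst <- slice_fixture(matrix(4, 8, 8))
  wc <- wavelet_features(cst$grid, cst$mask)
  expect_equal(unname(wc[c("Wavelet_L1_LH", "Wavelet_L1_HL", "Wavelet_L1_HH",
                           "Wavelet_L2_LH", "Wavelet_L2_HL",
                           "Wavelet_L2_HH")]),
               rep(0, 6))
  expect_equal(unname(wc["Wavelet_L2_LL"]), 16)   # constant energy in LL

  # Parseval over the retained 2-level subbands on a full-mask square
  set.seed(12)
  X <- matrix(rnorm(64), 8, 8)
  fx <- slice_fixture(X)
  w <- wavelet_features(fx$grid, fx$mask)
  expect_equal(sum(w), mean(X^2), tolerance = 1e-10)
})

test_that("small ROIs disable level-2 wavelets but keep level 1", {
  sm <- slice_fixture(matrix(rnorm(9), 3, 3))
  w <- wavelet_features(sm$grid, sm$mask)
  expect_true(all(is.na(w[grepl("L2", names(w))])))
  expect_true(all(!is.na(w[grepl("L1", names(w))])))
})

test_that("LoG scale ladder behaves as specified", {
  ph <- generate_phantom(phantom_spec(tumor_radius = 8, texture_sd = 60,
                                      seed = 6))
  lf <- log_features(ph$volume, ph$mask)
  fo <- first_order_features(ph$volume, ph$mask)
  # s = 1 applies no preprocessing: Mean equals the first-order 3D mean
  expect_equal(unname(lf["LoG_Mean_s1"]), unname(fo["DensityMean3D"]),
               tolerance = 1e-12)

  cst <- slice_fixture(matrix(5, 10, 10))
  lc <- log_features(cst$grid, cst$mask)
  expect_equal(unname(lc[paste0("LoG_Mean_s", 2:4)]), rep(0, 3),
               tolerance = 1e-9)
  expect_equal(unname(lc[paste0("LoG_Uniformity_s", 1:4)]), rep(1, 4))

  # smoothing concentrates the white-noise response histogram
  set.seed(9)
  wn <- slice_fixture(matrix(rnorm(40 * 40, 0, 30), 40, 40))
  lw <- log_features(wn$grid, wn$mask)
  expect_gt(unname(lw["LoG_Uniformity_s4"]), unname(lw["LoG_Uniformity_s2"]))
})

test_that("spatial correlation matches its oracle and conventions", {
  flat <- slice_fixture(matrix(2, 6, 6))
  expect_equal(unname(spatial_correlation_features(flat$grid, flat$mask)),
               c(1, 1))
  set.seed(23)
  img <- matrix(rnorm(100), 10, 10)
  msk <- matrix(runif(100) > 0.1, 10, 10)
  fx <- slice_fixture(img, msk)
  expect_equal(unname(spatial_correlation_features(fx$grid, fx$mask)),
               oracle_spatial_corr(list(img), list(msk)), tolerance = 1e-10)
  # white noise decorrelates at lag 1
  set.seed(14)
  big <- voxel_grid(array(rnorm(3 * 60 * 60), c(3, 60, 60)), c(1, 1, 1))
  bm <- segmentation_mask(array(1L, c(3, 60, 60)), c(1, 1, 1))
  sc <- spatial_correlation_features(big, bm)
  expect_lt(max(abs(sc)), 0.05)
})
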