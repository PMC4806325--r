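# Matrix texture classes against hand-worked examples and independent
# brute-force oracles (pair / neighborhood / run enumeration).

test_that("GLCM reproduces hand-worked co-occurrence examples", {
  sp <- c(1, 1, 1)
  # constant ROI: single-cell matrix
  cst <- slice_fixture(matrix(5, 6, 6))
  f <- glcm_features(quantize_roi(cst$grid, cst$mask, 64L), min_pixels = 1L)
  expect_equal(unname(f["GLCM_Contrast"]), 0)
  expect_equal(unname(f["GLCM_Energy"]), 1)
  expect_equal(unname(f["GLCM_Entropy"]), 0)

  # [[1,1],[2,2]] levels, horizontal offset only: P = {(1,1): .5, (2,2): .5}
  lev <- array(0L, c(1, 2, 2)); lev[1, , ] <- matrix(c(1, 1, 2, 2), 2, byrow = TRUE)
  counts <- radrepro:::glcm_counts_slice(lev[1, , ], 2L, list(c(0L, 1L)))
  P <- matrix(counts / sum(counts), 2, 2)
  expect_equal(P, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  f2 <- radrepro:::glcm_from_matrix(P)
  expect_equal(unname(f2["GLCM_Contrast"]), 0)
  expect_equal(unname(f2["GLCM_Energy"]), 0.5)
  expect_equal(unname(f2["GLCM_Entropy"]), 1)   # 1 bit, logs base 2
})

test_that("all 17 GLCM features match the brute-force pair enumerator", {
  for (seed in c(42, 99)) {
    fx <- random_quantized_fixture(nz = 2, ny = 8, nx = 8, G = 6, seed = seed)
    got <- glcm_features(fx$q, min_pixels = 1L)
    exp <- oracle_glcm(fx$slices, fx$q$G, min_pixels = 1L)
    expect_equal(unname(got), exp, tolerance = 1e-10)
  }
})

test_that("direction-summed GLCM features are invariant to 90-degree
           in-plane rotation", {
  fx <- random_quantized_fixture(nz = 1, ny = 8, nx = 8, G = 6, seed = 5)
  rot_vals <- array(0, c(1, 8, 8)); rot_msk <- array(0L, c(1, 8, 8))
  rot_vals[1, , ] <- t(fx$grid$data[1, , ])[, 8:1]
  rot_msk[1, , ] <- t(fx$mask$data[1, , ])[, 8:1]
  q_rot <- quantize_roi(voxel_grid(rot_vals, c(1, 1, 1)),
                        segmentation_mask(rot_msk, c(1, 1, 1)), 6L)
  expect_equal(glcm_features(fx$q, min_pixels = 1L),
               glcm_features(q_rot, min_pixels = 1L), tolerance = 1e-10)
})

test_that("GTDM matches the brute-force neighborhood enumerator", {
  # 4x4 two-level checkerboard, worked by hand: every interior pixel sees a
  # neighborhood mean of 1.5
  chk <- matrix(((row(matrix(0, 4, 4)) + col(matrix(0, 4, 4))) %% 2) * 50, 4, 4)
  fxc <- slice_fixture(chk)
  qc <- quantize_roi(fxc$grid, fxc$mask, 2L)
  got <- gtdm_features(qc)
  exp <- oracle_gtdm(list(qc$levels[1, , ]), 2L)
  expect_equal(unname(got), exp, tolerance = 1e-10)
  expect_equal(unname(got["GTDM_Contrast"]), 0.125)

  for (seed in c(8, 21)) {
    fx <- random_quantized_fixture(nz = 2, ny = 8, nx = 8, G = 5, seed = seed)
    expect_equal(unname(gtdm_features(fx$q)),
                 oracle_gtdm(fx$slices, fx$q$G), tolerance = 1e-10)
  }
  # constant ROI: zero difference sums hit the epsilon guard
  cst <- slice_fixture(matrix(9, 5, 5))
  fc <- gtdm_features(quantize_roi(cst$grid, cst$mask, 64L))
  expect_equal(unname(fc["GTDM_Coarseness"]), 1e12)
  expect_equal(unname(fc["GTDM_Contrast"]), 0)
})

test_that("run-length features match hand counts and the run enumerator", {
  # 4x4 constant ROI, horizontal runs only: 4 runs of length 4 over 16 px
  cst <- slice_fixture(matrix(3, 4, 4))
  qc <- quantize_roi(cst$grid, cst$mask, 2L)
  expect_equal(unname(runlength_features(qc, directions = 1L)["RL_RP"]), 0.25)

  # checkerboard: horizontal and vertical runs all have length 1
  chk <- matrix(((row(matrix(0, 4, 4)) + col(matrix(0, 4, 4))) %% 2) * 10, 4, 4)
  fxc <- slice_fixture(chk)
  qk <- quantize_roi(fxc$grid, fxc$mask, 2L)
  hv <- runlength_features(qk, directions = 1:2)
  expect_equal(unname(hv["RL_SRE"]), 1)
  expect_equal(unname(hv["RL_LRE"]), 1)
  expect_equal(unname(hv["RL_RP"]), 1)

  for (seed in c(3, 77)) {
    fx <- random_quantized_fixture(nz = 2, ny = 7, nx = 8, G = 4, seed = seed)
    got <- runlength_features(fx$q)
    exp <- oracle_runlength(fx$slices, fx$q$G)
    expect_equal(unname(got), exp, tolerance = 1e-10)
  }
})

test_that("quantized texture classes are invariant under positive affine
           HU rescaling", {
  fx <- random_quantized_fixture(nz = 2, ny = 8, nx = 8, G = 6, seed = 13)
  resc <- voxel_grid(fx$grid$data * 2.5 - 300, c(1, 1, 1))
  q2 <- quantize_roi(resc, fx$mask, 6L)
  expect_equal(glcm_features(fx$q, min_pixels = 1L),
               glcm_features(q2, min_pixels = 1L), tolerance = 1e-12)
  expect_equal(gtdm_features(fx$q), gtdm_features(q2), tolerance = 1e-12)
  expect_equal(runlength_features(fx$q), runlength_features(q2),
               tolerance = 1e-12)
})

test_that("degenerate ROIs yield NA, never a crash or silent zero", {
  sp <- c(1, 1, 1)
  # single in-mask pixel: no co-occurrence pairs, no interior, one run
  one <- slice_fixture(matrix(1, 1, 1))
  q1 <- quantize_roi(one$grid, one$mask, 4L)
  expect_true(all(is.na(glcm_features(q1))))
  expect_true(all(is.na(gtdm_features(q1))))
  # an empty mask is rejected upstream
  g <- voxel_grid(array(0, c(2, 2, 2)), sp)
  expect_error(quantize_roi(g, segmentation_mask(array(0L, c(2, 2, 2)), sp),
                            G = 4L),
               "empty")
})
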