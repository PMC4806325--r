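# Size, shape, surface-shape and margin classes on analytic geometry.

ball_phantom <- function() {
  generate_phantom(phantom_spec(tumor_radius = 10, texture_sd = 0,
                                spiculation_amp = 0, seed = 2))
}

test_that("size features recover analytic sphere and ellipse measurements", {
  sp <- c(5, 0.7, 0.7)
  single <- segmentation_mask(array(1L, c(1, 1, 1)), sp)
  g1 <- voxel_grid(array(0, c(1, 1, 1)), sp)
  expect_equal(unname(size_features(g1, single)["Volume"]), 5 * 0.7 * 0.7)

  ph <- ball_phantom()
  sf <- size_features(ph$volume, ph$mask)
  expect_gte(unname(sf["Uni"]), 19); expect_lte(unname(sf["Uni"]), 21)
  expect_lt(abs(unname(sf["Volume"]) / 4188.79 - 1), 0.03)

  # 20 mm x 10 mm solid ellipse on one slice: Bi close to 200 mm^2
  d <- c(1, 60, 60); sp2 <- c(1, 0.5, 0.5)
  yy <- (1:60 - 30.5) * 0.5; xx <- (1:60 - 30.5) * 0.5
  ell <- outer(yy, xx, function(y, x) (x / 10)^2 + (y / 5)^2 <= 1)
  m <- segmentation_mask(array(ell * 1L, d), sp2)
  g <- voxel_grid(array(0, d), sp2)
  sfe <- size_features(g, m)
  expect_lt(abs(unname(sfe["Uni"]) / 20 - 1), 0.05)
  expect_lt(abs(unname(sfe["Bi"]) / 200 - 1), 0.05)
})

test_that("shape features hit their analytic limits", {
  ph <- ball_phantom()
  sf <- shape_features(ph$volume, ph$mask)
  expect_gt(unname(sf["CompactnessFactor3D"]), 0.9)
  expect_lt(unname(sf["CompactnessFactor3D"]), 1.1)
  expect_gt(unname(sf["RoundnessFactor2D"]), 0.9)
  expect_lt(unname(sf["RoundnessFactor2D"]), 1.05)
  expect_lt(unname(sf["Eccentricity"]), 0.35)     # near-isotropic disk slice
  expect_gte(unname(sf["Solidity"]), 0.97)
  expect_lte(unname(sf["Solidity"]), 1.0)

  # convex cube: solidity exactly 1, eccentricity 0 for the square slice
  cube <- array(0L, c(12, 16, 16)); cube[3:10, 4:13, 4:13] <- 1L
  cm <- segmentation_mask(cube, c(1, 1, 1))
  cg <- voxel_grid(array(0, c(12, 16, 16)), c(1, 1, 1))
  sfc <- shape_features(cg, cm)
  expect_gte(unname(sfc["Solidity"]), 0.97)
  expect_lte(unname(sfc["Solidity"]), 1.0)
  expect_lt(unname(sfc["Eccentricity"]), 1e-6)

  # a deep notch lowers solidity well below 1
  notch <- cube; notch[3:10, 8:9, 4:10] <- 0L
  sfn <- shape_features(cg, segmentation_mask(notch, c(1, 1, 1)))
  expect_lt(unname(sfn["Solidity"]), 0.95)
})

test_that("quickhull volumes are exact on known polytopes", {
  cube <- as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2)))
  expect_equal(radrepro:::quickhull_volume(cube), 8, tolerance = 1e-5)
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  expect_equal(radrepro:::quickhull_volume(oct), 4 / 3, tolerance = 1e-5)
  tetra <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(radrepro:::quickhull_volume(tetra), 1 / 6, tolerance = 1e-5)
  # interior points never change the hull
  set.seed(4)
  inner <- matrix(runif(300, 0.2, 1.8), 100, 3)
  expect_equal(radrepro:::quickhull_volume(rbind(cube, inner)), 8,
               tolerance = 1e-5)
  # degenerate (coplanar) input
  flat <- cbind(matrix(runif(20), 10, 2), 0)
  expect_true(is.na(radrepro:::quickhull_volume(flat)))
})

test_that("shape index concentrates at +1 for a ball and spreads for
           spiculated margins", {
  ph <- ball_phantom()
  si <- shape_index_histogram(ph$volume, ph$mask)
  expect_equal(sum(si), 1, tolerance = 1e-12)
  expect_gt(unname(si["ShapeIndex9"]), 0.8)

  spic <- generate_phantom(phantom_spec(tumor_radius = 10, texture_sd = 0,
                                        spiculation_amp = 0.35, seed = 7))
  si2 <- shape_index_histogram(spic$volume, spic$mask)
  expect_lt(unname(si2["ShapeIndex9"]), unname(si["ShapeIndex9"]))

  tiny <- segmentation_mask(array(c(1L, rep(0L, 26)), c(3, 3, 3)), c(1, 1, 1))
  tg <- voxel_grid(array(0, c(3, 3, 3)), c(1, 1, 1))
  expect_true(all(is.na(shape_index_histogram(tg, tiny))))
})

test_that("box-counting dimension reads ~2 for smooth surfaces", {
  cube <- array(0L, c(40, 40, 40)); cube[5:36, 5:36, 5:36] <- 1L
  cg <- voxel_grid(array(0, c(40, 40, 40)), c(1, 1, 1))
  fd_cube <- fractal_dimension(cg, segmentation_mask(cube, c(1, 1, 1)))
  expect_gt(unname(fd_cube), 1.9); expect_lt(unname(fd_cube), 2.1)

  ph <- ball_phantom()   # digital ball, radius 16 voxels
  fd_ball <- fractal_dimension(ph$volume, ph$mask)
  expect_gt(unname(fd_ball), 1.9); expect_lt(unname(fd_ball), 2.2)

  tiny <- segmentation_mask(array(c(1L, rep(0L, 26)), c(3, 3, 3)), c(1, 1, 1))
  tg <- voxel_grid(array(0, c(3, 3, 3)), c(1, 1, 1))
  expect_true(is.na(fractal_dimension(tg, tiny)))
})

test_that("sigmoid fits recover generated boundary profiles within 5%", {
  set.seed(5)
  d <- seq(-4, 4, by = 0.25)
  fits <- list()
  for (i in 1:50) {
    I <- -850 + 850 / (1 + exp(d / 1.0)) + rnorm(length(d), sd = 10)
    f <- fit_sigmoid(d, I)
    expect_true(f$ok)
    expect_lte(f$rel_residual, 0.5)
    fits[[i]] <- f
  }
  expect_lt(abs(median(vapply(fits, `[[`, numeric(1), "A")) / 850 - 1), 0.05)
  expect_lt(abs(median(vapply(fits, `[[`, numeric(1), "w")) / 1.0 - 1), 0.05)
  expect_lt(abs(median(vapply(fits, `[[`, numeric(1), "B")) / -850 - 1), 0.05)
})

test_that("margin features see the tumor edge and kernel blur", {
  ph <- ball_phantom()
  sg <- sigmoid_margin_features(ph$volume, ph$mask)
  expect_lt(abs(unname(sg["SigmoidAmplitude"]) / 850 - 1), 0.05)
  expect_lt(abs(unname(sg["SigmoidBaseline"]) / -850 - 1), 0.05)

  # flat noise volume: no edge, amplitude within 3 noise SDs of zero
  set.seed(8)
  fv <- voxel_grid(array(rnorm(20 * 30 * 30, 0, 10), c(20, 30, 30)), c(1, 1, 1))
  fm <- array(0L, c(20, 30, 30)); fm[6:15, 10:20, 10:20] <- 1L
  fs <- sigmoid_margin_features(fv, segmentation_mask(fm, c(1, 1, 1)))
  expect_lt(abs(unname(fs["SigmoidAmplitude"])), 30)

  # smooth reconstruction widens the fitted edge relative to sharp
  a <- acquire(ph$volume, ph$mask, acquisition_params(0, 10, seed = 5), 1)
  rl <- reconstruct(a$volume, a$mask, imaging_setting(1.25, "sharp"))
  rs <- reconstruct(a$volume, a$mask, imaging_setting(1.25, "smooth"))
  wl <- sigmoid_margin_features(rl$volume, rl$mask)["SigmoidWidth"]
  ws <- sigmoid_margin_features(rs$volume, rs$mask)["SigmoidWidth"]
  expect_gt(unname(ws), unname(wl))
})

test_that("first-order statistics use population moments and stated
           conventions", {
  sp <- c(1, 1, 1)
  two <- slice_fixture(matrix(c(1, 3, 1, 3), 2, 2))
  fo <- first_order_features(two$grid, two$mask)
  expect_equal(unname(fo["DensityMean3D"]), 2)
  expect_equal(unname(fo["DensitySD3D"]), 1)      # population, not n-1
  flat <- slice_fixture(matrix(6, 3, 3))
  ff <- first_order_features(flat$grid, flat$mask)
  expect_equal(unname(ff[1:4]), c(6, 0, 0, 0))
  # single-slice mask: 2D equals 3D
  expect_equal(unname(fo[5:8]), unname(fo[1:4]))
})
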