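#' Compute the full 89-feature vector for one segmented tumor
#'
#' Runs every registered feature class on a (volume, mask) pair. Matrix
#' texture classes (GLCM, GTDM, run length) share one 64-level equal-width
#' quantization of the in-mask intensities; texture offsets are in-plane
#' and accumulated over axial slices. Features whose minimum ROI
#' requirements are not met come back as `NA` ("not available") with the
#' reason recorded in the `note` column — degenerate ROIs never crash and
#' are never silently reported as 0.
#'
#' @param grid A [voxel_grid()].
#' @param mask Aligned non-empty [segmentation_mask()].
#' @param registry The feature registry (defaults to [feature_registry()]).
#' @param G Gray levels for the quantized texture classes.
#' @param sigmoid_width Sigmoid band half-width, mm.
#' @param sigmoid_normals Surface normals sampled for the sigmoid fits.
#' @return A tibble with one row per registry feature: `feature`, `class`,
#'   `dim`, `value`, `note`.
#' @export
compute_features <- function(grid, mask, registry = feature_registry(),
                             G = 64L, sigmoid_width = 4,
                             sigmoid_normals = 30L) {
  check_aligned(grid, mask)
  check_nonempty(mask)
  cr <- crop_to_mask(grid, mask, sigmoid_width)
  grid <- cr$grid; mask <- cr$mask
  q <- quantize_roi(grid, mask, G)

  run_class <- function(fun, nm) {
    tryCatch(fun(), error = function(e) {
      out <- na_vector(nm)
      attr(out, "note") <- conditionMessage(e)
      out
    })
  }
  parts <- list(
    run_class(function() size_features(grid, mask),
              c("Uni", "Bi", "Volume")),
    run_class(function() shape_features(grid, mask),
              c("CompactnessFactor3D", "RoundnessFactor2D", "Eccentricity",
                "Solidity")),
    run_class(function() shape_index_histogram(grid, mask),
              paste0("ShapeIndex", 1:9)),
    run_class(function() sigmoid_margin_features(grid, mask,
                                                 width = sigmoid_width,
                                                 n_normals = sigmoid_normals),
              c("SigmoidAmplitude", "SigmoidWidth", "SigmoidBaseline")),
    run_class(function() first_order_features(grid, mask),
              paste0("Density", rep(c("Mean", "SD", "Skewness", "Kurtosis"), 2),
                     rep(c("3D", "2D"), each = 4))),
    run_class(function() glcm_features(q), paste0("GLCM_", glcm_feature_names())),
    run_class(function() gtdm_features(q),
              paste0("GTDM_", c("Coarseness", "Contrast", "Busyness",
                                "Complexity", "Strength"))),
    run_class(function() spatial_correlation_features(grid, mask),
              c("AutoCorrX", "AutoCorrY")),
    run_class(function() runlength_features(q),
              paste0("RL_", runlength_feature_names())),
    run_class(function() laws_features(grid, mask),
              paste0("Laws_", c("L5E5", "L5S5", "E5E5", "E5S5", "S5S5"))),
    run_class(function() edge_frequency_features(grid, mask),
              c("EdgeFreq1", "EdgeFreq2", "EdgeFreq3", "EdgeFreqCoarseness")),
    run_class(function() gabor_features(grid, mask),
              c("GaborEnergy0", "GaborEnergy90")),
    run_class(function() wavelet_features(grid, mask),
              paste0("Wavelet_", wavelet_subband_names())),
    run_class(function() log_features(grid, mask),
              paste0("LoG_", c(paste0("Mean_s", 1:4),
                               paste0("Uniformity_s", 1:4)))),
    run_class(function() fractal_dimension(grid, mask), "FractalDimension")
  )
  vals <- unlist(lapply(parts, function(p) { attributes(p) <- list(names = names(p)); p }))
  notes <- unlist(lapply(parts, function(p) {
    rep(attr(p, "note") %||% NA_character_, length(p))
  }))
  stopifnot(setequal(names(vals), registry$feature))
  tibble::tibble(feature = registry$feature,
                 class = registry$class,
                 dim = registry$dim,
                 value = unname(vals[registry$feature]),
                 note = unname(notes[match(registry$feature, names(vals))]))
}

# crop grid+mask to the mask bounding box plus enough margin for the
# boundary-band and filter-support operators
crop_to_mask <- function(grid, mask, sigmoid_width = 4) {
  d <- dim(mask$data)
  zr <- range(which(apply(mask$data, 1L, sum) > 0))
  yr <- range(which(apply(mask$data, 2L, sum) > 0))
  xr <- range(which(apply(mask$data, 3L, sum) > 0))
  mz <- max(2L, ceiling(sigmoid_width / mask$spacing[1]) + 1L)
  my <- max(8L, ceiling(sigmoid_width / mask$spacing[2]) + 2L)
  mx <- max(8L, ceiling(sigmoid_width / mask$spacing[3]) + 2L)
  zi <- max(1L, zr[1] - mz):min(d[1], zr[2] + mz)
  yi <- max(1L, yr[1] - my):min(d[2], yr[2] + my)
  xi <- max(1L, xr[1] - mx):min(d[3], xr[2] + mx)
  or <- grid$origin + (c(zi[1], yi[1], xi[1]) - 1) * grid$spacing
  list(grid = voxel_grid(grid$data[zi, yi, xi, drop = FALSE], grid$spacing, or),
       mask = segmentation_mask(mask$data[zi, yi, xi, drop = FALSE],
                                mask$spacing, or))
}

#' Extract features for every entry of a cohort manifest
#'
#' @param manifest A [load_manifest()] tibble.
#' @param registry Feature registry.
#' @param ... Passed to [compute_features()].
#' @return A long tibble: `subject_id`, `scan`, `setting`, `feature`,
#'   `class`, `value`.
#' @export
extract_cohort_features <- function(manifest, registry = feature_registry(),
                                    ...) {
  out <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    grid <- read_volume(row$volume_path)
    mask <- read_mask(row$mask_path)
    fv <- compute_features(grid, mask, registry, ...)
    out[[i]] <- tibble::tibble(subject_id = row$subject_id, scan = row$scan,
                               setting = row$setting, feature = fv$feature,
                               class = fv$class, value = fv$value)
  }
  dplyr::bind_rows(out)
}
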