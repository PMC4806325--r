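#' The canonical feature registry
#'
#' The engine computes exactly 89 features in 15 classes; the registry fixes
#' their names, class membership, dimensionality tag and order (the order is
#' also the heat-map row order). Class sizes: Size 3, Shape 4, ShapeIndex 9,
#' Sigmoid 3, FirstOrder 8 (4 statistics x 2D/3D), GLCM 17, GTDM 5,
#' SpatialCorrelation 2, RunLength 11, Laws 5, EdgeFrequency 4, Gabor 2,
#' Wavelet 8, LoG 8, Fractal 1. The census (89 / 15 / GLCM = 17) is asserted
#' every time the registry is built.
#'
#' @return A tibble with columns `feature`, `class`, `dim` and `params`.
#' @export
feature_registry <- function() {
  reg <- dplyr::bind_rows(
    reg_rows("Size", c("Uni", "Bi", "Volume"), c("2D", "2D", "3D")),
    reg_rows("Shape",
             c("CompactnessFactor3D", "RoundnessFactor2D", "Eccentricity",
               "Solidity"),
             c("3D", "2D", "2D", "3D")),
    reg_rows("ShapeIndex", paste0("ShapeIndex", 1:9), "3D"),
    reg_rows("Sigmoid",
             c("SigmoidAmplitude", "SigmoidWidth", "SigmoidBaseline"), "3D"),
    reg_rows("FirstOrder",
             c("DensityMean3D", "DensitySD3D", "DensitySkewness3D",
               "DensityKurtosis3D", "DensityMean2D", "DensitySD2D",
               "DensitySkewness2D", "DensityKurtosis2D"),
             rep(c("3D", "2D"), each = 4)),
    reg_rows("GLCM", paste0("GLCM_", glcm_feature_names()), "2D",
             params = "G=64, d=1, 4 dirs"),
    reg_rows("GTDM",
             paste0("GTDM_", c("Coarseness", "Contrast", "Busyness",
                               "Complexity", "Strength")),
             "2D", params = "G=64, r=1"),
    reg_rows("SpatialCorrelation", c("AutoCorrX", "AutoCorrY"), "2D",
             params = "lag=1"),
    reg_rows("RunLength", paste0("RL_", runlength_feature_names()), "2D",
             params = "G=64, 4 dirs"),
    reg_rows("Laws",
             paste0("Laws_", c("L5E5", "L5S5", "E5E5", "E5S5", "S5S5")),
             "2D"),
    reg_rows("EdgeFrequency",
             c("EdgeFreq1", "EdgeFreq2", "EdgeFreq3", "EdgeFreqCoarseness"),
             "2D", params = "d=1..3"),
    reg_rows("Gabor", c("GaborEnergy0", "GaborEnergy90"), "2D",
             params = "lambda=4px, sigma=2px"),
    reg_rows("Wavelet", paste0("Wavelet_", wavelet_subband_names()),
             "2D", params = "Haar, orthonormal, 2 levels"),
    reg_rows("LoG",
             paste0("LoG_", c(paste0("Mean_s", 1:4),
                              paste0("Uniformity_s", 1:4))),
             "2D", params = "sigma=0..2.5px"),
    reg_rows("Fractal", "FractalDimension", "3D", params = "box 1,2,4,8")
  )
  stopifnot(nrow(reg) == 89L,
            dplyr::n_distinct(reg$class) == 15L,
            sum(reg$class == "GLCM") == 17L,
            !anyDuplicated(reg$feature))
  reg
}

reg_rows <- function(class, features, dim, params = "") {
  tibble::tibble(feature = features, class = class, dim = dim,
                 params = params)
}

# 17 GLCM features: the Haralick-style list minus MaxProbability
glcm_feature_names <- function() {
  c("Energy", "Entropy", "Contrast", "Dissimilarity", "Homogeneity",
    "Correlation", "Variance", "SumAverage", "SumVariance", "SumEntropy",
    "DifferenceVariance", "DifferenceEntropy", "IMC1", "IMC2",
    "Autocorrelation", "ClusterShade", "ClusterProminence")
}

# retained subbands of a 2-level pyramidal DWT: details at level 1, all
# four subbands at the deepest level
wavelet_subband_names <- function() {
  c("L1_LH", "L1_HL", "L1_HH", "L2_LL", "L2_LH", "L2_HL", "L2_HH")
}

runlength_feature_names <- function() {
  c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE", "SRLGE", "SRHGE",
    "LRLGE", "LRHGE")
}
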