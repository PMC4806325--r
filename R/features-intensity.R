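# First-order density statistics, lag-1 spatial correlation and the
# sigmoid margin-sharpness fits.

#' First-order density statistics
#'
#' Population moments of the in-mask Hounsfield values: Mean, SD,
#' Skewness (m3 / m2^(3/2)) and excess Kurtosis (m4 / m2^2 - 3), each in
#' 3D (whole ROI) and 2D (largest axial slice). A flat ROI returns
#' (mean, 0, 0, 0) by convention.
#'
#' @inheritParams size_features
#' @return Named numeric vector of 8 values.
#' @export
first_order_features <- function(grid, mask) {
  check_aligned(grid, mask); check_nonempty(mask)
  v3 <- grid$data[mask$data != 0L]
  k <- largest_slice(mask)
  sl <- grid$data[k, , , drop = TRUE]
  v2 <- sl[mask$data[k, , , drop = TRUE] != 0L]
  c(stats::setNames(moment_stats(v3),
                    paste0("Density", c("Mean", "SD", "Skewness", "Kurtosis"),
                           "3D")),
    stats::setNames(moment_stats(v2),
                    paste0("Density", c("Mean", "SD", "Skewness", "Kurtosis"),
                           "2D")))
}

moment_stats <- function(v) {
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  if (m2 <= 0) return(c(mu, 0, 0, 0))
  m3 <- mean((v - mu)^3); m4 <- mean((v - mu)^4)
  c(mu, sqrt(m2), m3 / m2^1.5, m4 / m2^2 - 3)
}

#' Lag-1 spatial correlation
#'
#' Pearson correlation of in-mask intensity pairs one pixel apart along x
#' and along y, pooled over axial slices. A flat ROI is defined as
#' perfectly correlated (1, 1); fewer than `min_pairs` valid pairs per
#' direction yields `NA`.
#'
#' @inheritParams size_features
#' @param min_pairs Minimum lag-1 pair count per direction.
#' @return Named numeric vector: AutoCorrX, AutoCorrY.
#' @export
spatial_correlation_features <- function(grid, mask, min_pairs = 10L) {
  check_aligned(grid, mask); check_nonempty(mask)
  out <- c(AutoCorrX = NA_real_, AutoCorrY = NA_real_)
  offs <- list(AutoCorrX = c(0L, 1L), AutoCorrY = c(1L, 0L))
  for (nmi in names(offs)) {
    a <- numeric(0); b <- numeric(0)
    for (k in seq_len(dim(grid$data)[1])) {
      sp <- slice_pair(grid, mask, k)
      if (!any(sp$msk)) next
      pr <- shifted_pairs(sp$img, sp$msk, offs[[nmi]])
      a <- c(a, pr$a); b <- c(b, pr$b)
    }
    if (length(a) < min_pairs) next
    out[nmi] <- if (stats::sd(a) * stats::sd(b) == 0) 1 else stats::cor(a, b)
  }
  out
}

#' Fit a sigmoid to one boundary-normal intensity profile
#'
#' Least-squares fit of `I(d) = B + A / (1 + exp((d - d0) / w))` where d is
#' the signed distance along the outward surface normal (mm, negative
#' inside). A is the inside-outside amplitude (HU), B the outside baseline
#' (HU), w the width (mm; the midpoint slope magnitude is A / (4 w)).
#'
#' @param d Signed distances along the normal, mm.
#' @param intensity Sampled intensities, HU.
#' @return A list with `A`, `B`, `d0`, `w`, `rel_residual` (RMSE divided by
#'   the sampled intensity range) and `ok`.
#' @export
fit_sigmoid <- function(d, intensity) {
  rng <- max(intensity) - min(intensity)
  inner <- intensity[d <= stats::quantile(d, 0.25)]
  outer_ <- intensity[d >= stats::quantile(d, 0.75)]
  start <- list(B = mean(outer_), A = mean(inner) - mean(outer_),
                d0 = 0, w = max(diff(range(d)) / 8, 0.05))
  fit <- tryCatch(
    minpack.lm::nlsLM(intensity ~ B + A / (1 + exp((d - d0) / w)),
                      start = start,
                      lower = c(B = -Inf, A = -Inf, d0 = min(d), w = 0.01),
                      upper = c(B = Inf, A = Inf, d0 = max(d),
                                w = diff(range(d))),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(ok = FALSE))
  cf <- stats::coef(fit)
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  list(A = unname(cf["A"]), B = unname(cf["B"]), d0 = unname(cf["d0"]),
       w = unname(cf["w"]),
       rel_residual = rmse / max(rng, 1e-12), ok = TRUE)
}

#' Sigmoid margin features
#'
#' Density change across the tumor boundary: along outward surface normals
#' (from the gradient of a smoothed mask), HU is sampled at fixed steps
#' over [-width, +width] mm around the sub-voxel surface crossing and a
#' sigmoid is fitted per normal; the features are the medians of the
#' amplitude A, width w and baseline B over normals. Fits with relative
#' residual above 0.5 are discarded.
#'
#' @inheritParams size_features
#' @param width Band half-width, mm.
#' @param n_normals Number of surface normals sampled (evenly over the
#'   surface voxel set).
#' @param step Sampling step along the normal, mm.
#' @return Named numeric vector: SigmoidAmplitude, SigmoidWidth,
#'   SigmoidBaseline (all `NA` if fewer than 20 usable normals exist or
#'   every fit is discarded).
#' @export
sigmoid_margin_features <- function(grid, mask, width = 4, n_normals = 30L,
                                    step = 0.5) {
  check_aligned(grid, mask); check_nonempty(mask)
  nm <- c("SigmoidAmplitude", "SigmoidWidth", "SigmoidBaseline")
  surf <- surface_voxels(mask)
  if (length(surf) < 20L) return(na_vector(nm))
  take <- surf[unique(round(seq(1, length(surf),
                                length.out = min(n_normals, length(surf)))))]
  F3 <- blur3d(mask$data + 0, rep(1, 3))
  g <- gradient3(F3, mask$spacing)
  d <- dim(mask$data)
  iz <- ((take - 1L) %% d[1]) + 1L
  iy <- (((take - 1L) %/% d[1]) %% d[2]) + 1L
  ix <- ((take - 1L) %/% (d[1] * d[2])) + 1L
  ds <- seq(-width, width, by = step)
  fits <- list()
  for (j in seq_along(take)) {
    nvec <- -c(g[[1]][take[j]], g[[2]][take[j]], g[[3]][take[j]])  # outward
    nn <- sqrt(sum(nvec^2))
    if (nn < 1e-9) next
    nvec <- nvec / nn
    p0 <- c(iz[j], iy[j], ix[j])
    # locate the sub-voxel surface crossing (F = 0.5) along the normal
    tt <- seq(-1.5, 1.5, by = 0.1) * min(mask$spacing)
    fv <- interp3(F3,
                  p0[1] + tt * nvec[1] / mask$spacing[1],
                  p0[2] + tt * nvec[2] / mask$spacing[2],
                  p0[3] + tt * nvec[3] / mask$spacing[3])
    cross <- which(diff(sign(fv - 0.5)) != 0)
    t0 <- if (length(cross)) tt[cross[which.min(abs(tt[cross]))]] else 0
    zi <- p0[1] + (t0 + ds) * nvec[1] / mask$spacing[1]
    yi <- p0[2] + (t0 + ds) * nvec[2] / mask$spacing[2]
    xi <- p0[3] + (t0 + ds) * nvec[3] / mask$spacing[3]
    intens <- interp3(grid$data, zi, yi, xi)
    ft <- fit_sigmoid(ds, intens)
    if (isTRUE(ft$ok) && ft$rel_residual <= 0.5) fits[[length(fits) + 1L]] <- ft
  }
  if (!length(fits)) return(na_vector(nm))
  stats::setNames(c(stats::median(vapply(fits, `[[`, numeric(1), "A")),
                    stats::median(vapply(fits, `[[`, numeric(1), "w")),
                    stats::median(vapply(fits, `[[`, numeric(1), "B"))),
                  nm)
}
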