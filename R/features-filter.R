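# Filter-bank texture classes operating on raw HU slices: Laws energy,
# edge frequency, Gabor energy, Haar wavelet subband energies and
# Laplacian-of-Gaussian statistics. Filters act in-plane with reflected
# boundaries; in-mask responses are pooled over axial slices.

slice_pair <- function(grid, mask, k) {
  d <- dim(grid$data)
  list(img = matrix(grid$data[k, , , drop = FALSE], d[2], d[3]),
       msk = matrix(mask$data[k, , , drop = FALSE] != 0L, d[2], d[3]))
}

mask_bbox_2d <- function(msk) {
  rr <- range(which(rowSums(msk) > 0)); cc <- range(which(colSums(msk) > 0))
  c(rr[1], rr[2], cc[1], cc[2])
}

#' Laws texture energy
#'
#' Five zero-mean 5x5 separable kernels built from the level, edge and
#' spot vectors L5 = (1,4,6,4,1), E5 = (-1,-2,0,2,1), S5 = (-1,0,2,0,-1):
#' the symmetrized pairs L5E5/E5L5, L5S5/S5L5, E5S5/S5E5 (responses
#' averaged) plus E5E5 and S5S5. Feature = mean absolute response over
#' in-mask pixels of every slice whose in-mask bounding box is at least
#' 5x5.
#'
#' @param grid A [voxel_grid()].
#' @param mask Aligned non-empty [segmentation_mask()].
#' @return Named numeric vector of 5 features.
#' @export
laws_features <- function(grid, mask) {
  L5 <- c(1, 4, 6, 4, 1); E5 <- c(-1, -2, 0, 2, 1); S5 <- c(-1, 0, 2, 0, -1)
  pairs <- list(L5E5 = list(list(L5, E5), list(E5, L5)),
                L5S5 = list(list(L5, S5), list(S5, L5)),
                E5E5 = list(list(E5, E5)),
                E5S5 = list(list(E5, S5), list(S5, E5)),
                S5S5 = list(list(S5, S5)))
  nm <- paste0("Laws_", names(pairs))
  sums <- stats::setNames(numeric(5), nm)
  n <- 0
  for (k in seq_len(dim(grid$data)[1])) {
    sp <- slice_pair(grid, mask, k)
    if (!any(sp$msk)) next
    bb <- mask_bbox_2d(sp$msk)
    if (bb[2] - bb[1] < 4L || bb[4] - bb[3] < 4L) next
    n <- n + sum(sp$msk)
    for (fi in seq_along(pairs)) {
      resp <- 0
      for (vk in pairs[[fi]])
        resp <- resp + conv2d_sep(sp$img, vk[[1]], vk[[2]]) / length(pairs[[fi]])
      sums[fi] <- sums[fi] + sum(abs(resp)[sp$msk])
    }
  }
  if (n == 0) return(na_vector(nm))
  sums / n
}

# separable 2D correlation: kr along rows (y), kc along cols (x),
# reflected boundaries
conv2d_sep <- function(img, kr, kc) {
  kernel_operator(nrow(img), kr) %*% img %*% t(kernel_operator(ncol(img), kc))
}

kernel_operator <- function(n, k) {
  r <- (length(k) - 1L) / 2L
  M <- matrix(0, n, n)
  for (off in seq(-r, r)) {
    j <- reflect_index(seq_len(n) + off, n)
    M[cbind(seq_len(n), j)] <- M[cbind(seq_len(n), j)] + k[off + r + 1L]
  }
  M
}

#' Edge frequency features
#'
#' `EF(d)` is the mean absolute intensity difference between in-mask pixel
#' pairs at in-plane offset distance d (d = 1, 2, 3 pixels, four in-plane
#' directions, both endpoints in the mask). The class Coarseness is
#' `1 / (1 + mean(EF))`, scaled so a constant image yields 1.
#'
#' @inheritParams laws_features
#' @return Named numeric vector: EdgeFreq1..3 and EdgeFreqCoarseness.
#' @export
edge_frequency_features <- function(grid, mask) {
  nm <- c("EdgeFreq1", "EdgeFreq2", "EdgeFreq3", "EdgeFreqCoarseness")
  tot <- numeric(3); cnt <- numeric(3)
  for (k in seq_len(dim(grid$data)[1])) {
    sp <- slice_pair(grid, mask, k)
    if (!any(sp$msk)) next
    for (d in 1:3) {
      for (off in list(c(0L, d), c(d, 0L))) {
        pr <- shifted_pairs(sp$img, sp$msk, off)
        tot[d] <- tot[d] + sum(abs(pr$a - pr$b))
        cnt[d] <- cnt[d] + length(pr$a)
      }
    }
  }
  if (all(cnt == 0)) return(na_vector(nm))
  ef <- ifelse(cnt > 0, tot / cnt, NA_real_)
  coarse <- 1 / (1 + sum(ef, na.rm = TRUE) / 3)
  stats::setNames(c(ef, coarse), nm)
}

shifted_pairs <- function(img, msk, off) {
  nr <- nrow(img); nc <- ncol(img)
  dr <- off[1]; dc <- off[2]
  r1 <- seq_len(nr - dr); c1 <- seq_len(nc - dc)
  if (!length(r1) || !length(c1)) return(list(a = numeric(0), b = numeric(0)))
  ok <- msk[r1, c1, drop = FALSE] & msk[r1 + dr, c1 + dc, drop = FALSE]
  list(a = img[r1, c1, drop = FALSE][ok],
       b = img[r1 + dr, c1 + dc, drop = FALSE][ok])
}

#' Gabor energy
#'
#' Complex 2D Gabor filters with carrier wavelength 4 px and Gaussian
#' envelope sigma 2 px at orientations 0 and 90 degrees (0 = carrier along
#' x, responding to intensity variation across columns). The even part is
#' DC-corrected so a constant image yields zero response. Feature = mean
#' squared response magnitude over in-mask pixels of slices whose in-mask
#' bounding box reaches the filter support (13 px).
#'
#' @inheritParams laws_features
#' @param wavelength,sigma Carrier wavelength and envelope SD, pixels.
#' @return Named numeric vector: GaborEnergy0, GaborEnergy90.
#' @export
gabor_features <- function(grid, mask, wavelength = 4, sigma = 2) {
  r <- ceiling(3 * sigma)
  x <- seq(-r, r)
  env <- exp(-x^2 / (2 * sigma^2))
  car_re <- env * cos(2 * pi * x / wavelength)
  car_im <- env * sin(2 * pi * x / wavelength)
  car_re <- car_re - env * sum(car_re) / sum(env)    # zero-DC even part
  support <- 2L * r + 1L
  nm <- c("GaborEnergy0", "GaborEnergy90")
  sums <- stats::setNames(numeric(2), nm)
  n <- 0
  for (k in seq_len(dim(grid$data)[1])) {
    sp <- slice_pair(grid, mask, k)
    if (!any(sp$msk)) next
    bb <- mask_bbox_2d(sp$msk)
    if (bb[2] - bb[1] + 1L < support && bb[4] - bb[3] + 1L < support) next
    n <- n + sum(sp$msk)
    # 0 deg: carrier along columns (x); envelope along rows
    re0 <- conv2d_sep(sp$img, env, car_re)
    im0 <- conv2d_sep(sp$img, env, car_im)
    re90 <- conv2d_sep(sp$img, car_re, env)
    im90 <- conv2d_sep(sp$img, car_im, env)
    sums[1] <- sums[1] + sum((re0^2 + im0^2)[sp$msk])
    sums[2] <- sums[2] + sum((re90^2 + im90^2)[sp$msk])
  }
  if (n == 0) return(na_vector(nm))
  sums / n
}

#' Haar wavelet subband energies
#'
#' Per eligible slice, a 2-level orthonormal 2D Haar transform of the
#' in-mask bounding-box crop (out-of-mask pixels filled with the in-mask
#' mean, crop padded to a multiple of 4 with the same fill). The energy of
#' a subband is the in-mask-weighted mean squared coefficient: each
#' coefficient is weighted by the in-mask fraction of its spatial support
#' and the sum is divided by the in-mask-weighted support, so on a fully
#' masked square input the three level-1 detail energies plus the four
#' level-2 energies sum to the input mean-square energy (Parseval). The
#' retained subbands are those of a standard 2-level pyramid (the
#' low-pass band is kept only at the deepest level). Energies are
#' averaged over slices; level-2 features require an in-mask bounding box
#' of at least 4x4.
#'
#' @inheritParams laws_features
#' @return Named numeric vector of 7 subband energies.
#' @export
wavelet_features <- function(grid, mask) {
  nm <- paste0("Wavelet_", wavelet_subband_names())
  acc <- stats::setNames(numeric(7), nm)
  cnt <- c(L1 = 0, L2 = 0)
  for (k in seq_len(dim(grid$data)[1])) {
    sp <- slice_pair(grid, mask, k)
    if (!any(sp$msk)) next
    bb <- mask_bbox_2d(sp$msk)
    h <- bb[2] - bb[1] + 1L; w <- bb[4] - bb[3] + 1L
    if (h < 2L || w < 2L) next
    img <- sp$img[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
    msk <- sp$msk[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
    fill <- mean(img[msk])
    img[!msk] <- fill
    pad_to <- function(m, mult, value) {
      nr <- ceiling(nrow(m) / mult) * mult; nc <- ceiling(ncol(m) / mult) * mult
      out <- matrix(value, nr, nc); out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
      out
    }
    img4 <- pad_to(img, 4L, fill)
    wgt4 <- pad_to(msk * 1, 4L, 0)
    l1 <- haar_level(img4)
    w1 <- block_sum(wgt4, 2L)
    for (s in 1:3) acc[s] <- acc[s] + subband_energy(l1[[s + 1L]], w1, 4L)
    cnt["L1"] <- cnt["L1"] + 1
    if (h >= 4L && w >= 4L) {
      l2 <- haar_level(l1$LL)
      w2 <- block_sum(wgt4, 4L)
      for (s in 1:4) acc[s + 3L] <- acc[s + 3L] + subband_energy(l2[[s]], w2, 16L)
      cnt["L2"] <- cnt["L2"] + 1
    }
  }
  out <- na_vector(nm)
  if (cnt["L1"] > 0) out[1:3] <- acc[1:3] / cnt["L1"]
  if (cnt["L2"] > 0) out[4:7] <- acc[4:7] / cnt["L2"]
  out
}

# one level of the orthonormal 2D Haar transform (input dims even)
haar_level <- function(m) {
  ro <- seq(1L, nrow(m) - 1L, by = 2L); co <- seq(1L, ncol(m) - 1L, by = 2L)
  s <- (m[ro, , drop = FALSE] + m[ro + 1L, , drop = FALSE]) / sqrt(2)
  d <- (m[ro, , drop = FALSE] - m[ro + 1L, , drop = FALSE]) / sqrt(2)
  list(LL = (s[, co, drop = FALSE] + s[, co + 1L, drop = FALSE]) / sqrt(2),
       LH = (s[, co, drop = FALSE] - s[, co + 1L, drop = FALSE]) / sqrt(2),
       HL = (d[, co, drop = FALSE] + d[, co + 1L, drop = FALSE]) / sqrt(2),
       HH = (d[, co, drop = FALSE] - d[, co + 1L, drop = FALSE]) / sqrt(2))
}

block_sum <- function(m, b) {
  ro <- rep(seq_len(nrow(m) %/% b), each = b)
  co <- rep(seq_len(ncol(m) %/% b), each = b)
  t(rowsum(t(rowsum(m[seq_along(ro), seq_along(co), drop = FALSE], ro)), co))
}

subband_energy <- function(coefs, wsum, block_px) {
  f <- wsum / block_px                     # in-mask fraction per block
  den <- sum(f) * block_px                 # in-mask-weighted support
  if (den == 0) return(0)
  sum(f * coefs^2) / den
}

#' Laplacian-of-Gaussian multiscale statistics
#'
#' Four scales s = 1..4 with Gaussian sigma linear from 0 to 2.5 in-plane
#' pixels (0, 0.8333, 1.6667, 2.5). s = 1 applies no preprocessing and
#' uses the raw in-mask intensities; for s > 1 each slice is Gaussian
#' smoothed and the discrete Laplacian response is pooled over in-mask
#' pixels. Features per scale: the response Mean and a Uniformity index
#' (sum of squared fractions over a 64-bin equal-width histogram of the
#' in-mask response; a flat response gives 1).
#'
#' @inheritParams laws_features
#' @param nbins Histogram bins for Uniformity.
#' @return Named numeric vector of 8 values (Mean and Uniformity at
#'   s = 1..4).
#' @export
log_features <- function(grid, mask, nbins = 64L) {
  sigmas <- 2.5 * (0:3) / 3
  out <- numeric(0)
  for (s in 1:4) {
    vals <- numeric(0)
    for (k in seq_len(dim(grid$data)[1])) {
      sp <- slice_pair(grid, mask, k)
      if (!any(sp$msk)) next
      resp <- if (s == 1L) sp$img else laplacian2d(blur2d(sp$img, sigmas[s]))
      vals <- c(vals, resp[sp$msk])
    }
    out <- c(out, stats::setNames(
      c(mean(vals), uniformity_index(vals, nbins)),
      paste0("LoG_", c("Mean_s", "Uniformity_s"), s)))
  }
  out[paste0("LoG_", c(paste0("Mean_s", 1:4), paste0("Uniformity_s", 1:4)))]
}

uniformity_index <- function(vals, nbins) {
  rg <- range(vals)
  # a numerically flat response occupies a single bin
  if (diff(rg) <= 1e-9 * max(abs(rg), 1)) return(1)
  b <- pmin(floor((vals - rg[1]) / diff(rg) * nbins) + 1L, nbins)
  p <- tabulate(b, nbins) / length(vals)
  sum(p^2)
}
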