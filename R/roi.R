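#' Two-of-three consensus mask
#'
#' Reproduces the study's reader-consensus rule: a voxel belongs to the
#' tumor iff at least 2 of the 3 independent segmentations mark it. The
#' result is restricted to its largest 6-connected component so stray
#' agreed voxels cannot fragment the ROI.
#'
#' @param m1,m2,m3 Three [segmentation_mask()]s sharing shape and spacing.
#' @return A [segmentation_mask()].
#' @export
consensus_mask <- function(m1, m2, m3) {
  check_aligned(m1, m2); check_aligned(m1, m3)
  votes <- m1$data + m2$data + m3$data
  cons <- array(as.integer(votes >= 2L), dim = dim(votes))
  if (sum(cons) == 0L) stop("empty consensus: no voxel agreed by 2 of 3",
                            call. = FALSE)
  cons <- largest_component(cons)
  segmentation_mask(cons, m1$spacing, m1$origin)
}

# largest 6-connected foreground component of a 0/1 array
largest_component <- function(m) {
  d <- dim(m)
  nzy <- d[1] * d[2]
  labels <- array(0L, dim = d)
  fg <- which(m != 0L)
  lab <- 0L
  best <- integer(0)
  coords_z <- ((fg - 1L) %% d[1]) + 1L
  names(coords_z) <- NULL
  unvisited <- array(m != 0L, dim = d)
  for (s in fg) {
    if (!unvisited[s]) next
    lab <- lab + 1L
    comp <- integer(0)
    frontier <- s
    unvisited[s] <- FALSE
    while (length(frontier)) {
      comp <- c(comp, frontier)
      iz <- ((frontier - 1L) %% d[1]) + 1L
      iy <- (((frontier - 1L) %/% d[1]) %% d[2]) + 1L
      ix <- ((frontier - 1L) %/% nzy) + 1L
      nb <- c(frontier[iz > 1L] - 1L, frontier[iz < d[1]] + 1L,
              frontier[iy > 1L] - d[1], frontier[iy < d[2]] + d[1],
              frontier[ix > 1L] - nzy, frontier[ix < d[3]] + nzy)
      nb <- unique(nb[unvisited[nb]])
      unvisited[nb] <- FALSE
      frontier <- nb
    }
    if (length(comp) > length(best)) best <- comp
  }
  out <- array(0L, dim = d)
  out[best] <- 1L
  out
}

#' Index of the largest axial slice
#'
#' The 2D feature variants (Roundness Factor, 2D density statistics) are
#' computed on the axial slice with the most in-mask pixels; ties break to
#' the smallest slice index.
#'
#' @param mask A non-empty [segmentation_mask()].
#' @return Integer z index.
#' @export
largest_slice <- function(mask) {
  check_nonempty(mask)
  areas <- apply(mask$data, 1L, sum)
  which.max(areas)   # which.max takes the first maximum: stated tie-break
}

# Felzenszwalb-Huttenlocher 1D squared-distance transform at sample
# positions i * step (mm); f is the input squared-distance function.
dt1d <- function(f, step) {
  n <- length(f)
  if (n == 1L) return(f)
  x <- seq_len(n) * step
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2L:n) {
    if (is.infinite(f[q])) next
    repeat {
      p <- v[k]
      if (is.infinite(f[p])) { s <- -Inf } else {
        s <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * x[q] - 2 * x[p])
      }
      if (s <= z[k] && k > 1L) { k <- k - 1L } else break
    }
    if (is.infinite(f[v[k]])) {    # no finite parabola yet
      v[k] <- q; z[k + 1L] <- Inf
    } else {
      k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
    }
  }
  d <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < x[q]) k <- k + 1L
    d[q] <- (x[q] - x[v[k]])^2 + f[v[k]]
  }
  d
}

# Exact anisotropic squared EDT to the set where seed != 0 (mm^2)
edt_squared <- function(seedmask, spacing) {
  d <- dim(seedmask)
  f <- array(ifelse(seedmask != 0L, 0, Inf), dim = d)
  for (ax in 1:3) {
    perm <- switch(ax, c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 2L, 1L))
    a <- if (ax == 1L) f else aperm(f, perm)
    da <- dim(a)
    m <- matrix(a, da[1], da[2] * da[3])
    for (j in seq_len(ncol(m))) m[, j] <- dt1d(m[, j], spacing[ax])
    a <- array(m, da)
    f <- if (ax == 1L) a else aperm(a, perm)
  }
  f
}

#' Boundary band with signed distances
#'
#' Voxels within `width` mm of the mask surface, each carrying a signed
#' Euclidean distance to the surface (negative inside). Distances use the
#' physical spacing (exact separable EDT); the voxel-center-to-surface
#' offset is taken as half the smallest voxel dimension, so on an isotropic
#' grid the first shells inside and outside the surface sit at -/+ half a
#' voxel.
#'
#' @param mask A non-empty [segmentation_mask()].
#' @param width Half-width of the band in mm (> 0).
#' @return A list: `band` (a [segmentation_mask()]) and `distance`
#'   (3D array of signed distances, mm, for every voxel).
#' @export
boundary_band <- function(mask, width) {
  check_nonempty(mask)
  stopifnot(width > 0)
  sp <- mask$spacing
  d_fg <- sqrt(edt_squared(mask$data, sp))          # 0 inside the mask
  d_bg <- sqrt(edt_squared(1L - mask$data, sp))     # 0 outside
  delta <- 0.5 * min(sp)
  signed <- ifelse(mask$data != 0L, -(d_bg - delta), d_fg - delta)
  band <- array(as.integer(abs(signed) <= width), dim = dim(signed))
  list(band = segmentation_mask(band, sp, mask$origin), distance = signed)
}

#' Quantize the ROI to G gray levels
#'
#' Equal-width binning of the in-mask Hounsfield values into `G` levels
#' over the in-mask min-max; the maximum maps to level `G`. A flat ROI
#' (zero intensity range) maps entirely to level 1. Levels are invariant
#' under positive affine rescaling of the intensities, which makes every
#' matrix-based texture feature scale-free.
#'
#' @param grid A [voxel_grid()].
#' @param mask An aligned non-empty [segmentation_mask()].
#' @param G Number of gray levels (>= 2); 64 is the package default used
#'   by [compute_features()].
#' @return A `quantized_roi`: `levels` (3D integer array, 1..G in mask,
#'   0 outside), `G`, `edges` (bin edges, HU) and the mask.
#' @export
quantize_roi <- function(grid, mask, G = 64L) {
  stopifnot(G >= 2L)
  check_aligned(grid, mask)
  check_nonempty(mask)
  inmask <- mask$data != 0L
  v <- grid$data[inmask]
  lo <- min(v); hi <- max(v)
  lev <- array(0L, dim = dim(grid$data))
  if (hi - lo <= 0) {
    lev[inmask] <- 1L
    edges <- c(lo, lo)
  } else {
    q <- floor((v - lo) / (hi - lo) * G) + 1L
    q[q > G] <- G
    lev[inmask] <- as.integer(q)
    edges <- seq(lo, hi, length.out = G + 1L)
  }
  structure(list(levels = lev, G = as.integer(G), edges = edges,
                 mask = mask$data, spacing = grid$spacing),
            class = "quantized_roi")
}
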