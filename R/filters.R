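# Internal image operators. All separable smoothing uses truncated Gaussian
# kernels with reflected boundary handling, applied as small dense operator
# matrices (grids are <= 64 voxels per axis, so this is both exact and fast).

gaussian_kernel <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

reflect_index <- function(j, n) {
  # reflect about the edge samples: ..., 3, 2, 1, 2, 3, ...
  j <- ifelse(j < 1L, 2L - j, j)
  j <- ifelse(j > n, 2L * n - j, j)
  pmin(pmax(j, 1L), n)
}

# n x n smoothing operator with reflected boundaries; rows sum to 1 exactly
blur_operator <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  M <- matrix(0, n, n)
  for (off in seq(-r, r)) {
    j <- reflect_index(seq_len(n) + off, n)
    M[cbind(seq_len(n), j)] <- M[cbind(seq_len(n), j)] + k[off + r + 1L]
  }
  M
}

apply_axis <- function(arr, M, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                 `3` = c(3L, 2L, 1L))
  a <- if (axis == 1L) arr else aperm(arr, perm)
  da <- dim(a)
  a <- array(M %*% matrix(a, da[1], da[2] * da[3]), da)
  if (axis == 1L) a else aperm(a, perm)
}

# sigma per axis in voxel units, order (z, y, x)
blur3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0)
      arr <- apply_axis(arr, blur_operator(d[ax], sigma_vox[ax]), ax)
  }
  arr
}

# 2D slice blur, sigma in pixels, order (row, col) = (y, x)
blur2d <- function(img, sigma_row, sigma_col = sigma_row) {
  if (sigma_row > 0) img <- blur_operator(nrow(img), sigma_row) %*% img
  if (sigma_col > 0) img <- img %*% t(blur_operator(ncol(img), sigma_col))
  img
}

# 2D correlation with an arbitrary kernel, reflected boundaries
conv2d_reflect <- function(img, K) {
  nr <- nrow(img); nc <- ncol(img)
  rr <- (nrow(K) - 1L) / 2L; rc <- (ncol(K) - 1L) / 2L
  ridx <- reflect_index(seq(1L - rr, nr + rr), nr)
  cidx <- reflect_index(seq(1L - rc, nc + rc), nc)
  pad <- img[ridx, cidx, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (a in seq_len(nrow(K))) for (b in seq_len(ncol(K))) {
    if (K[a, b] == 0) next
    out <- out + K[a, b] * pad[(a - 1L) + seq_len(nr), (b - 1L) + seq_len(nc)]
  }
  out
}

# 5-point discrete Laplacian (unit pixel spacing), reflected boundaries
laplacian2d <- function(img) {
  conv2d_reflect(img, matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3))
}

# Trilinear interpolation of arr (z,y,x) at fractional voxel indices
# (1-based); coordinates clamped to the grid.
interp3 <- function(arr, zi, yi, xi) {
  d <- dim(arr)
  zi <- pmin(pmax(zi, 1), d[1]); yi <- pmin(pmax(yi, 1), d[2])
  xi <- pmin(pmax(xi, 1), d[3])
  z0 <- pmin(floor(zi), d[1] - 1L); y0 <- pmin(floor(yi), d[2] - 1L)
  x0 <- pmin(floor(xi), d[3] - 1L)
  if (d[1] == 1L) z0 <- rep(1, length(zi))
  if (d[2] == 1L) y0 <- rep(1, length(yi))
  if (d[3] == 1L) x0 <- rep(1, length(xi))
  fz <- zi - z0; fy <- yi - y0; fx <- xi - x0
  z1 <- pmin(z0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2]); x1 <- pmin(x0 + 1L, d[3])
  at <- function(z, y, x) arr[cbind(z, y, x)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * at(z0, y0, x0) + fx * at(z0, y0, x1)) +
                fy * ((1 - fx) * at(z0, y1, x0) + fx * at(z0, y1, x1))) +
    fz * ((1 - fy) * ((1 - fx) * at(z1, y0, x0) + fx * at(z1, y0, x1)) +
            fy * ((1 - fx) * at(z1, y1, x0) + fx * at(z1, y1, x1)))
}

# Translate content by `shift_vox` (z,y,x, fractional voxels): out(p) = in(p - t)
translate3 <- function(arr, shift_vox) {
  d <- dim(arr)
  idx <- expand_grid_indices(d)
  vals <- interp3(arr, idx[, 1] - shift_vox[1], idx[, 2] - shift_vox[2],
                  idx[, 3] - shift_vox[3])
  array(vals, d)
}

expand_grid_indices <- function(d) {
  cbind(rep(seq_len(d[1]), times = d[2] * d[3]),
        rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
        rep(seq_len(d[3]), each = d[1] * d[2]))
}

# Central-difference gradient in physical units; one-sided at edges.
gradient3 <- function(arr, spacing) {
  d <- dim(arr)
  g <- list()
  for (ax in 1:3) {
    n <- d[ax]
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    denom <- (ip - im) * spacing[ax]
    if (ax == 1L) {
      diffd <- arr[ip, , , drop = FALSE] - arr[im, , , drop = FALSE]
      g[[ax]] <- sweep(diffd, 1L, denom, "/")
    } else if (ax == 2L) {
      diffd <- arr[, ip, , drop = FALSE] - arr[, im, , drop = FALSE]
      g[[ax]] <- sweep(diffd, 2L, denom, "/")
    } else {
      diffd <- arr[, , ip, drop = FALSE] - arr[, , im, drop = FALSE]
      g[[ax]] <- sweep(diffd, 3L, denom, "/")
    }
  }
  g
}

# Evaluate expr with a temporary RNG state seeded by `seed`
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}
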