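# Size, shape and surface-shape feature classes. Surface area and slice
# perimeter are estimated by the coarea integral of a Gaussian-smoothed
# indicator (sigma = 1 voxel): exposed-face/boundary-pixel counting
# overestimates curved interfaces by up to 50% and would badly bias the
# sphericity measures, while the coarea estimator converges to the true
# measure for smooth shapes.

#' Tumor size features
#'
#' Uni = maximal in-plane diameter over axial slices (mm, boundary-point
#' pair search over each slice's convex hull, RECIST-style); Bi = on Uni's
#' slice, Uni times the maximal extent perpendicular to it (mm^2);
#' Volume = voxel count times voxel volume (mm^3).
#'
#' @param grid A [voxel_grid()].
#' @param mask Aligned non-empty [segmentation_mask()].
#' @return Named numeric vector: Uni, Bi, Volume.
#' @export
size_features <- function(grid, mask) {
  check_aligned(grid, mask); check_nonempty(mask)
  vol <- sum(mask$data) * voxel_volume(mask)
  best <- list(diam = 0, pair = NULL, pts = NULL)
  for (k in seq_len(dim(mask$data)[1])) {
    d <- dim(mask$data)
    msk <- matrix(mask$data[k, , , drop = FALSE] != 0L, d[2], d[3])
    if (!any(msk)) next
    pts <- which(msk, arr.ind = TRUE)  # (row=y, col=x)
    pts <- cbind(pts[, 1] * mask$spacing[2], pts[, 2] * mask$spacing[3])
    hull <- if (nrow(pts) >= 3L) pts[grDevices::chull(pts), , drop = FALSE] else pts
    if (nrow(hull) < 2L) next
    dd <- as.matrix(stats::dist(hull))
    ij <- which(dd == max(dd), arr.ind = TRUE)[1, ]
    if (max(dd) > best$diam)
      best <- list(diam = max(dd), pair = hull[ij, , drop = FALSE], pts = hull)
  }
  uni <- best$diam
  bi <- 0
  if (uni > 0) {
    u <- (best$pair[2, ] - best$pair[1, ]) / uni
    perp <- c(-u[2], u[1])
    proj <- best$pts %*% perp
    bi <- uni * (max(proj) - min(proj))
  }
  c(Uni = uni, Bi = bi, Volume = vol)
}

#' Shape features
#'
#' CompactnessFactor3D = 6 sqrt(pi) V / S^(3/2) (1 for a perfect ball);
#' RoundnessFactor2D = 4 pi A / P^2 on the largest axial slice (1 for a
#' disk); Eccentricity = sqrt(1 - lambda2/lambda1) from the largest
#' slice's second moments; Solidity = V / V(convex image) in 3D (the
#' convex hull of the voxel centers rasterized back onto the grid).
#'
#' @inheritParams size_features
#' @return Named numeric vector of 4 features; degenerate inputs
#'   (single-pixel slice, single-slice mask) yield `NA` for the affected
#'   feature.
#' @export
shape_features <- function(grid, mask) {
  check_aligned(grid, mask); check_nonempty(mask)
  sp <- mask$spacing
  V <- sum(mask$data) * voxel_volume(mask)
  S <- surface_area_coarea(mask)
  compact <- 6 * sqrt(pi) * V / S^1.5

  k <- largest_slice(mask)
  msk <- matrix(mask$data[k, , , drop = FALSE] != 0L,
                dim(mask$data)[2], dim(mask$data)[3])
  npix <- sum(msk)
  A <- npix * sp[2] * sp[3]
  if (npix >= 2L) {
    P <- perimeter_coarea(msk, sp[2:3])
    round2d <- 4 * pi * A / P^2
  } else {
    round2d <- NA_real_
  }
  if (npix >= 3L) {
    pts <- which(msk, arr.ind = TRUE)
    pts <- cbind(pts[, 1] * sp[2], pts[, 2] * sp[3])
    ev <- eigen(stats::cov(pts), symmetric = TRUE, only.values = TRUE)$values
    ecc <- if (ev[1] > 1e-12) sqrt(max(1 - ev[2] / ev[1], 0)) else NA_real_
  } else {
    ecc <- NA_real_
  }
  vh <- convex_image_volume(mask)
  solidity <- if (is.na(vh) || vh <= 0) NA_real_ else V / vh
  c(CompactnessFactor3D = compact, RoundnessFactor2D = round2d,
    Eccentricity = ecc, Solidity = solidity)
}

surface_area_coarea <- function(mask, sigma_vox = 1) {
  F3 <- blur3d(mask$data + 0, rep(sigma_vox, 3))
  g <- gradient3(F3, mask$spacing)
  sum(sqrt(g[[1]]^2 + g[[2]]^2 + g[[3]]^2)) * voxel_volume(mask)
}

perimeter_coarea <- function(msk, sp2, sigma_px = 1) {
  F2 <- blur2d(msk + 0, sigma_px)
  nr <- nrow(F2); nc <- ncol(F2)
  ipr <- pmin(seq_len(nr) + 1L, nr); imr <- pmax(seq_len(nr) - 1L, 1L)
  ipc <- pmin(seq_len(nc) + 1L, nc); imc <- pmax(seq_len(nc) - 1L, 1L)
  gr <- (F2[ipr, ] - F2[imr, ]) / ((ipr - imr) * sp2[1])
  gc <- (F2[, ipc] - F2[, imc]) / sweep(matrix(1, nr, nc), 2L, (ipc - imc) * sp2[2], "*")
  sum(sqrt(gr^2 + gc^2)) * sp2[1] * sp2[2]
}

# Solidity denominator as in regionprops: the convex image. The 3D hull of
# the voxel centers (per-slice 2D hull vertices suffice as candidates) is
# rasterized back onto the grid; the convex volume is the count of voxel
# centers inside the hull. For a convex digital shape this is within a
# fraction of a percent of the mask volume itself.
convex_image_volume <- function(mask) {
  sp <- mask$spacing
  zvals <- which(apply(mask$data, 1L, sum) > 0)
  if (length(zvals) < 2L) return(NA_real_)
  zs <- range(zvals)
  pts <- list()
  for (k in zvals) {
    msk <- matrix(mask$data[k, , , drop = FALSE] != 0L,
                  dim(mask$data)[2], dim(mask$data)[3])
    pc <- which(msk, arr.ind = TRUE)
    if (nrow(pc) >= 3L) pc <- pc[grDevices::chull(pc), , drop = FALSE]
    pts[[length(pts) + 1L]] <- cbind(k * sp[1], pc[, 1] * sp[2], pc[, 2] * sp[3])
  }
  hull <- quickhull(do.call(rbind, pts))
  if (is.null(hull)) return(NA_real_)
  yr <- range(which(apply(mask$data, 2L, sum) > 0))
  xr <- range(which(apply(mask$data, 3L, sum) > 0))
  bbox <- expand.grid(z = zs[1]:zs[2], y = yr[1]:yr[2], x = xr[1]:xr[2])
  # mask voxel centers are hull vertices or interior by construction; only
  # background centers inside the bounding box need the point-in-hull test
  outside_mask <- mask$data[cbind(bbox$z, bbox$y, bbox$x)] == 0L
  cand <- cbind(bbox$z[outside_mask] * sp[1], bbox$y[outside_mask] * sp[2],
                bbox$x[outside_mask] * sp[3])
  # tolerance far above the hull's internal jitter so centers lying exactly
  # on a face count as inside; progressive filtering keeps this cheap
  eps <- 1e-3 * min(sp)
  idx <- seq_len(nrow(cand))
  for (f in seq_along(hull$offsets)) {
    if (!length(idx)) break
    proj <- cand[idx, , drop = FALSE] %*% hull$normals[f, ]
    idx <- idx[proj <= hull$offsets[f] + eps]
  }
  (sum(mask$data) + length(idx)) * prod(sp)
}

# Volume of the 3D convex hull of a point set; NA when degenerate.
quickhull_volume <- function(pts) {
  h <- quickhull(pts)
  if (is.null(h)) NA_real_ else h$volume
}

# 3D convex hull of a point set (quickhull): returns the outward face list
# (unit normal n, offset d with n . p <= d inside) and the volume, or NULL
# when the points are degenerate (rank < 3).
quickhull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 4L) return(NULL)
  scale <- max(apply(pts, 2, function(v) diff(range(v))))
  eps <- 1e-9 * max(scale, 1)

  # initial tetrahedron from extreme points
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (i1 == i2) { i1 <- which.min(pts[, 2]); i2 <- which.max(pts[, 2]) }
  d12 <- pts[i2, ] - pts[i1, ]
  if (sqrt(sum(d12^2)) < eps) return(NULL)
  # farthest from the line (i1, i2)
  rel <- sweep(pts, 2, pts[i1, ])
  t <- rel %*% d12 / sum(d12^2)
  perp <- rel - t %*% t(d12)
  i3 <- which.max(rowSums(perp^2))
  if (sqrt(sum(perp[i3, ]^2)) < eps) return(NULL)
  nrm <- cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  dist4 <- abs(rel %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(dist4)
  if (dist4[i4] < 1e-6 * max(scale, 1)) return(NULL)   # coplanar set

  # deterministic sub-epsilon jitter removes collinear/coplanar ties during
  # the incremental construction, with a relative volume perturbation below
  # 1e-6; applied only after the global degeneracy checks above
  pts <- pts + with_local_seed(42L, {
    matrix(stats::runif(3L * n, -1, 1), n, 3) * 1e-7 * max(scale, 1)
  })
  c0 <- colMeans(pts[c(i1, i2, i3, i4), ])
  # face store: vertex index matrix V, outward unit normals N, offsets D,
  # per-face outside point sets OUT; rows are append-only with an alive flag
  V <- matrix(0L, 0, 3); N <- matrix(0, 0, 3); D <- numeric(0)
  OUT <- list(); alive <- logical(0)
  add_face <- function(a, b, cc) {
    nf <- cross3(pts[b, ] - pts[a, ], pts[cc, ] - pts[a, ])
    nf <- nf / sqrt(sum(nf^2))
    d <- sum(nf * pts[a, ])
    if (sum(nf * c0) > d) { nf <- -nf; d <- -d }
    V <<- rbind(V, c(a, b, cc)); N <<- rbind(N, nf)
    D <<- c(D, d); OUT[[nrow(V)]] <<- integer(0); alive <<- c(alive, TRUE)
  }
  tri <- utils::combn(c(i1, i2, i3, i4), 3)
  for (cix in seq_len(ncol(tri))) add_face(tri[1, cix], tri[2, cix], tri[3, cix])

  assign_pts <- function(cand) {
    if (!length(cand)) return(invisible())
    rows <- which(alive)
    dmat <- pts[cand, , drop = FALSE] %*% t(N[rows, , drop = FALSE]) -
      rep(D[rows], each = length(cand))
    bestf <- max.col(dmat, ties.method = "first")
    bestd <- dmat[cbind(seq_along(cand), bestf)]
    keep <- bestd > eps
    for (fi in unique(bestf[keep])) {
      r <- rows[fi]
      OUT[[r]] <<- c(OUT[[r]], cand[keep & bestf == fi])
    }
    invisible()
  }
  assign_pts(setdiff(seq_len(n), c(i1, i2, i3, i4)))

  has_out <- function() {
    w <- which(alive)
    w[lengths(OUT[w]) > 0L]
  }
  repeat {
    cand_faces <- has_out()
    if (!length(cand_faces)) break
    fi <- cand_faces[1]
    outs <- OUT[[fi]]
    dd <- pts[outs, , drop = FALSE] %*% N[fi, ] - D[fi]
    p <- outs[which.max(dd)]
    rows <- which(alive)
    visd <- N[rows, , drop = FALSE] %*% pts[p, ] - D[rows]
    vis <- rows[visd > eps]
    ev <- V[vis, , drop = FALSE]
    e1 <- cbind(pmin(ev[, 1], ev[, 2]), pmax(ev[, 1], ev[, 2]))
    e2 <- cbind(pmin(ev[, 2], ev[, 3]), pmax(ev[, 2], ev[, 3]))
    e3 <- cbind(pmin(ev[, 1], ev[, 3]), pmax(ev[, 1], ev[, 3]))
    edges <- rbind(e1, e2, e3)
    key <- edges[, 1] * (n + 1) + edges[, 2]
    horizon <- edges[key %in% as.numeric(names(which(table(key) == 1L))), ,
                     drop = FALSE]
    orphans <- setdiff(unique(unlist(OUT[vis])), p)
    alive[vis] <- FALSE
    for (e in seq_len(nrow(horizon))) add_face(horizon[e, 1], horizon[e, 2], p)
    assign_pts(orphans)
  }
  rows <- which(alive)
  a <- pts[V[rows, 1], , drop = FALSE] - rep(c0, each = length(rows))
  b <- pts[V[rows, 2], , drop = FALSE] - rep(c0, each = length(rows))
  cc <- pts[V[rows, 3], , drop = FALSE] - rep(c0, each = length(rows))
  cx <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
              b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
              b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  vol <- sum(abs(rowSums(a * cx))) / 6
  list(normals = N[rows, , drop = FALSE], offsets = D[rows], volume = vol)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# foreground voxels with at least one background voxel in their
# 26-neighborhood (edge-of-grid treated as replicated, so the FOV border
# itself is not a surface)
surface_voxels <- function(mask) {
  m <- mask$data
  d <- dim(m)
  pad <- function(ix, n) pmin(pmax(ix, 1L), n)
  all_in <- array(TRUE, dim = d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0L && dy == 0L && dx == 0L) next
    all_in <- all_in & (m[pad(seq_len(d[1]) + dz, d[1]),
                          pad(seq_len(d[2]) + dy, d[2]),
                          pad(seq_len(d[3]) + dx, d[3]), drop = FALSE] != 0L)
  }
  which(m != 0L & !all_in)
}

#' Shape-index histogram
#'
#' Koenderink's shape index SI = (2/pi) atan((k1 + k2) / (k1 - k2)) from
#' the principal curvatures of a smoothed level set of the mask
#' (Gaussian, sigma = 1.5 voxels: enough smoothing that voxelization noise
#' does not split a sphere's caps across bins), evaluated at surface
#' voxels and histogrammed
#' over 9 equal bins of [-1, 1] (fractions summing to 1). Umbilic points
#' (k1 = k2) are assigned SI = sign(k1). A ball concentrates in bin 9
#' (spherical cap, SI = +1).
#'
#' @inheritParams size_features
#' @param min_surface Minimum surface voxel count; below it all bins are
#'   `NA`.
#' @return Named numeric vector ShapeIndex1..ShapeIndex9.
#' @export
shape_index_histogram <- function(grid, mask, min_surface = 50L,
                                  sigma_vox = 1.5) {
  check_nonempty(mask)
  nm <- paste0("ShapeIndex", 1:9)
  surf <- surface_voxels(mask)
  if (length(surf) < min_surface) return(na_vector(nm))
  sp <- mask$spacing
  F3 <- blur3d(mask$data + 0, rep(sigma_vox, 3))
  g <- gradient3(F3, sp)
  Hz <- gradient3(g[[1]], sp); Hy <- gradient3(g[[2]], sp)
  Hx <- gradient3(g[[3]], sp)
  gz <- g[[1]][surf]; gy <- g[[2]][surf]; gx <- g[[3]][surf]
  a <- Hz[[1]][surf]                         # F_zz
  b <- (Hz[[2]][surf] + Hy[[1]][surf]) / 2   # F_zy
  cc <- (Hz[[3]][surf] + Hx[[1]][surf]) / 2  # F_zx
  dd <- Hy[[2]][surf]                        # F_yy
  e <- (Hy[[3]][surf] + Hx[[2]][surf]) / 2   # F_yx
  f <- Hx[[3]][surf]                         # F_xx
  g2 <- gz^2 + gy^2 + gx^2
  ok <- g2 > 1e-12
  gHg <- gz^2 * a + gy^2 * dd + gx^2 * f +
    2 * (gz * gy * b + gz * gx * cc + gy * gx * e)
  trH <- a + dd + f
  Hmean <- (gHg - g2 * trH) / (2 * g2^1.5)
  A11 <- dd * f - e^2; A22 <- a * f - cc^2; A33 <- a * dd - b^2
  A12 <- cc * e - b * f; A13 <- b * e - cc * dd; A23 <- b * cc - a * e
  gAg <- gz^2 * A11 + gy^2 * A22 + gx^2 * A33 +
    2 * (gz * gy * A12 + gz * gx * A13 + gy * gx * A23)
  K <- gAg / g2^2
  disc <- sqrt(pmax(Hmean^2 - K, 0))
  k1 <- Hmean + disc; k2 <- Hmean - disc
  si <- numeric(length(k1))
  umb <- (k1 - k2) <= 1e-9 * (abs(k1) + abs(k2) + 1e-12)
  si[umb] <- sign(k1[umb])
  si[!umb] <- (2 / pi) * atan((k1[!umb] + k2[!umb]) / (k1[!umb] - k2[!umb]))
  si <- si[ok]
  if (!length(si)) return(na_vector(nm))
  bins <- pmin(floor((si + 1) / 2 * 9) + 1L, 9L)
  stats::setNames(tabulate(bins, 9L) / length(si), nm)
}

#' Box-counting fractal dimension of the mask surface
#'
#' Counts occupied boxes of edge 1, 2, 4, 8 voxels over the surface voxel
#' set; FD is minus the least-squares slope of log2 N versus log2 eps.
#' A smooth surface gives FD near 2.
#'
#' @inheritParams size_features
#' @param min_surface Minimum surface voxel count; below it `NA`.
#' @return Scalar FD (named `FractalDimension`).
#' @export
fractal_dimension <- function(grid, mask, min_surface = 100L) {
  check_nonempty(mask)
  surf <- surface_voxels(mask)
  if (length(surf) < min_surface)
    return(c(FractalDimension = NA_real_))
  d <- dim(mask$data)
  iz <- ((surf - 1L) %% d[1])
  iy <- (((surf - 1L) %/% d[1]) %% d[2])
  ix <- ((surf - 1L) %/% (d[1] * d[2]))
  eps <- c(1L, 2L, 4L, 8L)
  counts <- vapply(eps, function(e) {
    nrow(unique(cbind(iz %/% e, iy %/% e, ix %/% e)))
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, log2(eps)), log2(counts))
  c(FractalDimension = -unname(fit$coefficients[2]))
}
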