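# Independent brute-force oracles: plain double-loop enumerations of voxel
# pairs, neighborhoods, runs and convolutions, kept deliberately naive and
# separate from the package's vectorized implementations.

# --- GLCM: enumerate symmetric co-occurrence pairs per slice -----------------
oracle_glcm <- function(slices, G, min_pixels = 16L) {
  P <- matrix(0, G, G)
  for (sl in slices) {
    if (sum(sl > 0) < min_pixels) next
    nr <- nrow(sl); nc <- ncol(sl)
    for (off in list(c(0, 1), c(-1, 1), c(1, 0), c(1, 1))) {
      for (r in seq_len(nr)) for (c in seq_len(nc)) {
        r2 <- r + off[1]; c2 <- c + off[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        a <- sl[r, c]; b <- sl[r2, c2]
        if (a > 0 && b > 0) {
          P[a, b] <- P[a, b] + 1
          P[b, a] <- P[b, a] + 1
        }
      }
    }
  }
  if (sum(P) == 0) return(NULL)
  P <- P / sum(P)
  lg <- function(x) ifelse(x > 0, log2(x), 0)
  px <- rowSums(P); py <- colSums(P)
  mx <- sum((1:G) * px); my <- sum((1:G) * py)
  sx <- sqrt(sum(((1:G) - mx)^2 * px)); sy <- sqrt(sum(((1:G) - my)^2 * py))
  out <- c(Energy = 0, Entropy = 0, Contrast = 0, Dissimilarity = 0,
           Homogeneity = 0, Correlation = 0, Variance = 0)
  for (i in 1:G) for (j in 1:G) {
    p <- P[i, j]
    out["Energy"] <- out["Energy"] + p^2
    out["Entropy"] <- out["Entropy"] - p * lg(p)
    out["Contrast"] <- out["Contrast"] + (i - j)^2 * p
    out["Dissimilarity"] <- out["Dissimilarity"] + abs(i - j) * p
    out["Homogeneity"] <- out["Homogeneity"] + p / (1 + (i - j)^2)
    out["Variance"] <- out["Variance"] + (i - mx)^2 * p
  }
  out["Correlation"] <- if (sx * sy > 0) {
    acc <- 0
    for (i in 1:G) for (j in 1:G) acc <- acc + i * j * P[i, j]
    (acc - mx * my) / (sx * sy)
  } else 0
  psum <- rep(0, 2 * G); pdif <- rep(0, G)
  for (i in 1:G) for (j in 1:G) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + P[i, j]
  }
  sa <- sum((2:(2 * G)) * psum[2:(2 * G)])
  sv <- sum(((2:(2 * G)) - sa)^2 * psum[2:(2 * G)])
  se <- -sum(psum * lg(psum))
  md <- sum((0:(G - 1)) * pdif)
  dv <- sum(((0:(G - 1)) - md)^2 * pdif)
  de <- -sum(pdif * lg(pdif))
  hx <- -sum(px * lg(px)); hy <- -sum(py * lg(py))
  hxy1 <- 0; hxy2 <- 0; ac <- 0; cs <- 0; cp <- 0
  for (i in 1:G) for (j in 1:G) {
    q <- px[i] * py[j]
    hxy1 <- hxy1 - P[i, j] * lg(q)
    hxy2 <- hxy2 - q * lg(q)
    ac <- ac + i * j * P[i, j]
    cs <- cs + (i + j - mx - my)^3 * P[i, j]
    cp <- cp + (i + j - mx - my)^4 * P[i, j]
  }
  imc1 <- if (max(hx, hy) > 0) (out["Entropy"] - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(1 - exp(-2 * (hxy2 - out["Entropy"])), 0))
  unname(c(out["Energy"], out["Entropy"], out["Contrast"],
           out["Dissimilarity"], out["Homogeneity"], out["Correlation"],
           out["Variance"], sa, sv, se, dv, de, imc1, imc2, ac, cs, cp))
}

# --- GTDM: Amadasun-King by explicit neighborhood enumeration ---------------
oracle_gtdm <- function(slices, G, eps = 1e-12) {
  s <- rep(0, G); n <- rep(0, G)
  for (sl in slices) {
    nr <- nrow(sl); nc <- ncol(sl)
    if (nr < 3 || nc < 3) next
    for (r in 2:(nr - 1)) for (c in 2:(nc - 1)) {
      if (sl[r, c] == 0) next
      nbr <- c()
      ok <- TRUE
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        v <- sl[r + dr, c + dc]
        if (v == 0) ok <- FALSE
        nbr <- c(nbr, v)
      }
      if (!ok) next
      lev <- sl[r, c]
      s[lev] <- s[lev] + abs(lev - mean(nbr))
      n[lev] <- n[lev] + 1
    }
  }
  N <- sum(n)
  if (N == 0) return(NULL)
  p <- n / N
  pres <- which(p > 0)
  Ng <- length(pres)
  coarse <- 1 / (eps + sum(p * s))
  contrast <- 0; busy_den <- 0; cplx <- 0; strength <- 0
  if (Ng > 1) {
    for (i in pres) for (j in pres) {
      contrast <- contrast + p[i] * p[j] * (i - j)^2
      busy_den <- busy_den + abs(i * p[i] - j * p[j])
      cplx <- cplx + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) /
        (N * (p[i] + p[j]))
      strength <- strength + (p[i] + p[j]) * (i - j)^2
    }
    contrast <- contrast / (Ng * (Ng - 1)) * sum(s) / N
    busy <- sum(p * s) / (eps + busy_den)
    strength <- strength / (eps + sum(s))
  } else {
    busy <- 0
  }
  c(coarse, contrast, busy, cplx, strength)
}

# --- run length: walk every line of every direction -------------------------
oracle_runlength <- function(slices, G, directions = 1:4) {
  maxlen <- max(vapply(slices, function(s) max(dim(s)), numeric(1)))
  R <- matrix(0, G, maxlen)
  Np <- 0
  step <- list(c(0, 1), c(1, 0), c(1, 1), c(-1, 1))
  for (sl in slices) {
    nr <- nrow(sl); nc <- ncol(sl)
    npx <- sum(sl > 0)
    if (npx == 0) next
    Np <- Np + npx * length(directions)
    for (d in directions) {
      dr <- step[[d]][1]; dc <- step[[d]][2]
      starts <- list()
      for (r in seq_len(nr)) for (c in seq_len(nc)) {
        pr <- r - dr; pc <- c - dc
        if (pr < 1 || pr > nr || pc < 1 || pc > nc)
          starts[[length(starts) + 1]] <- c(r, c)
      }
      for (st in starts) {
        r <- st[1]; c <- st[2]
        run_val <- 0; run_len <- 0
        while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
          v <- sl[r, c]
          if (v == run_val && v > 0) {
            run_len <- run_len + 1
          } else {
            if (run_val > 0) R[run_val, run_len] <- R[run_val, run_len] + 1
            run_val <- v; run_len <- 1
          }
          r <- r + dr; c <- c + dc
        }
        if (run_val > 0) R[run_val, run_len] <- R[run_val, run_len] + 1
      }
    }
  }
  Nr <- sum(R)
  if (Nr == 0) return(NULL)
  sre <- lre <- lgre <- hgre <- srlge <- srhge <- lrlge <- lrhge <- 0
  for (i in 1:G) for (j in 1:maxlen) {
    r <- R[i, j]
    if (r == 0) next
    sre <- sre + r / j^2; lre <- lre + r * j^2
    lgre <- lgre + r / i^2; hgre <- hgre + r * i^2
    srlge <- srlge + r / (i^2 * j^2); srhge <- srhge + r * i^2 / j^2
    lrlge <- lrlge + r * j^2 / i^2; lrhge <- lrhge + r * i^2 * j^2
  }
  c(sre / Nr, lre / Nr, sum(rowSums(R)^2) / Nr, sum(colSums(R)^2) / Nr,
    Nr / Np, lgre / Nr, hgre / Nr, srlge / Nr, srhge / Nr, lrlge / Nr,
    lrhge / Nr)
}

# --- direct 2D correlation with reflected boundaries ------------------------
oracle_conv2d <- function(img, K) {
  nr <- nrow(img); nc <- ncol(img)
  rr <- (nrow(K) - 1) / 2; rc <- (ncol(K) - 1) / 2
  refl <- function(i, n) {
    if (i < 1) i <- 2 - i
    if (i > n) i <- 2 * n - i
    min(max(i, 1), n)
  }
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    acc <- 0
    for (a in seq_len(nrow(K))) for (b in seq_len(ncol(K))) {
      acc <- acc + K[a, b] * img[refl(r + a - 1 - rr, nr),
                                 refl(c + b - 1 - rc, nc)]
    }
    out[r, c] <- acc
  }
  out
}

oracle_laws <- function(img, msk) {
  L5 <- c(1, 4, 6, 4, 1); E5 <- c(-1, -2, 0, 2, 1); S5 <- c(-1, 0, 2, 0, -1)
  two <- function(a, b) (oracle_conv2d(img, outer(a, b)) +
                           oracle_conv2d(img, outer(b, a))) / 2
  one <- function(a, b) oracle_conv2d(img, outer(a, b))
  resp <- list(two(L5, E5), two(L5, S5), one(E5, E5), two(E5, S5),
               one(S5, S5))
  vapply(resp, function(m) mean(abs(m)[msk]), numeric(1))
}

# --- edge frequency by explicit pair walks ----------------------------------
oracle_edge_freq <- function(slices_img, slices_msk) {
  tot <- rep(0, 3); cnt <- rep(0, 3)
  for (k in seq_along(slices_img)) {
    img <- slices_img[[k]]; msk <- slices_msk[[k]]
    nr <- nrow(img); nc <- ncol(img)
    for (d in 1:3) for (off in list(c(0, d), c(d, 0))) {
      for (r in seq_len(nr)) for (c in seq_len(nc)) {
        r2 <- r + off[1]; c2 <- c + off[2]
        if (r2 > nr || c2 > nc) next
        if (msk[r, c] && msk[r2, c2]) {
          tot[d] <- tot[d] + abs(img[r, c] - img[r2, c2])
          cnt[d] <- cnt[d] + 1
        }
      }
    }
  }
  ef <- tot / cnt
  c(ef, 1 / (1 + mean(ef)))
}

# --- lag-1 spatial correlation by explicit pair collection ------------------
oracle_spatial_corr <- function(slices_img, slices_msk) {
  out <- c(NA_real_, NA_real_)
  offs <- list(c(0, 1), c(1, 0))
  for (oi in 1:2) {
    a <- c(); b <- c()
    for (k in seq_along(slices_img)) {
      img <- slices_img[[k]]; msk <- slices_msk[[k]]
      nr <- nrow(img); nc <- ncol(img)
      for (r in seq_len(nr)) for (c in seq_len(nc)) {
        r2 <- r + offs[[oi]][1]; c2 <- c + offs[[oi]][2]
        if (r2 > nr || c2 > nc) next
        if (msk[r, c] && msk[r2, c2]) { a <- c(a, img[r, c]); b <- c(b, img[r2, c2]) }
      }
    }
    out[oi] <- if (stats::sd(a) * stats::sd(b) == 0) 1 else stats::cor(a, b)
  }
  out
}

# --- fixture builders --------------------------------------------------------
# wrap a single 2D slice (rows = y, cols = x) as grid + mask
slice_fixture <- function(img, msk = NULL, spacing = c(1, 1, 1)) {
  if (is.null(msk)) msk <- matrix(TRUE, nrow(img), ncol(img))
  g <- voxel_grid(array(img, c(1, nrow(img), ncol(img))), spacing)
  m <- segmentation_mask(array(msk * 1L, c(1, nrow(img), ncol(img))), spacing)
  list(grid = g, mask = m)
}

# a seeded random multi-slice quantized fixture plus its level slices
random_quantized_fixture <- function(nz = 2, ny = 8, nx = 8, G = 6,
                                     seed = 42) {
  set.seed(seed)
  vals <- array(stats::rnorm(nz * ny * nx), c(nz, ny, nx))
  msk <- array(stats::runif(nz * ny * nx) > 0.2, c(nz, ny, nx))
  if (sum(msk) < 5) msk[] <- TRUE
  g <- voxel_grid(vals, c(1, 1, 1))
  m <- segmentation_mask(msk * 1L, c(1, 1, 1))
  q <- quantize_roi(g, m, G)
  slices <- lapply(seq_len(nz), function(k) q$levels[k, , ])
  list(grid = g, mask = m, q = q, slices = slices)
}
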