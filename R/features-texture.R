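# Matrix-based texture classes: GLCM, GTDM (Amadasun-King NGTDM) and
# gray-level run length. All three operate on the quantized ROI with
# in-plane offsets accumulated over axial slices (voxels are strongly
# anisotropic at 2.5 / 5 mm, so 3D offsets would mix unlike scales).
# Logarithms are base 2 and 0 * log 0 = 0 throughout.

# in-plane slice of the quantized ROI, rows = y, cols = x
roi_slices <- function(q) {
  d <- dim(q$levels)
  lapply(seq_len(d[1]), function(k)
    matrix(q$levels[k, , , drop = FALSE], d[2], d[3]))
}

#' Gray-level co-occurrence features
#'
#' Per axial slice, symmetric co-occurrence counts at distance 1 for the
#' four in-plane directions (0, 45, 90, 135 degrees); counts from all
#' slices with at least `min_pixels` in-mask pixels are summed into one
#' matrix, normalized once, and the 17 registry features are computed from
#' it (matrix summation before feature computation, not feature averaging).
#'
#' @param q A [quantize_roi()] result.
#' @param min_pixels Minimum in-mask pixels for a slice to contribute.
#' @return Named numeric vector of 17 features (all `NA` if no slice is
#'   eligible).
#' @export
glcm_features <- function(q, min_pixels = 16L) {
  G <- q$G
  counts <- numeric(G * G)
  offsets <- list(c(0L, 1L), c(-1L, 1L), c(1L, 0L), c(1L, 1L))
  for (sl in roi_slices(q)) {
    if (sum(sl > 0L) < min_pixels) next
    counts <- counts + glcm_counts_slice(sl, G, offsets)
  }
  nm <- paste0("GLCM_", glcm_feature_names())
  if (sum(counts) == 0) return(na_vector(nm))
  P <- matrix(counts / sum(counts), G, G)
  glcm_from_matrix(P, nm)
}

glcm_counts_slice <- function(sl, G, offsets) {
  nr <- nrow(sl); nc <- ncol(sl)
  counts <- numeric(G * G)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    if (!length(r1) || !length(c1)) next
    a <- sl[r1, c1, drop = FALSE]
    b <- sl[r1 + dr, c1 + dc, drop = FALSE]
    ok <- a > 0L & b > 0L
    if (!any(ok)) next
    ia <- a[ok]; ib <- b[ok]
    tab <- tabulate((ia - 1L) * G + ib, nbins = G * G) +
      tabulate((ib - 1L) * G + ia, nbins = G * G)
    counts <- counts + tab
  }
  counts
}

log2z <- function(x) ifelse(x > 0, log2(x), 0)

glcm_from_matrix <- function(P, nm = paste0("GLCM_", glcm_feature_names())) {
  G <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(G) * px); muy <- sum(seq_len(G) * py)
  sx <- sqrt(sum((seq_len(G) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(G) - muy)^2 * py))

  energy <- sum(P^2)
  entropy <- -sum(P * log2z(P))
  contrast <- sum((i - j)^2 * P)
  dissim <- sum(abs(i - j) * P)
  homog <- sum(P / (1 + (i - j)^2))
  corr <- if (sx * sy > 0) (sum(i * j * P) - mux * muy) / (sx * sy) else 0
  variance <- sum((i - mux)^2 * P)

  k_sum <- 2:(2 * G)
  pxy_sum <- vapply(k_sum, function(k) sum(P[i + j == k]), numeric(1))
  sum_avg <- sum(k_sum * pxy_sum)
  sum_var <- sum((k_sum - sum_avg)^2 * pxy_sum)
  sum_ent <- -sum(pxy_sum * log2z(pxy_sum))

  k_diff <- 0:(G - 1)
  pxy_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  mu_diff <- sum(k_diff * pxy_diff)
  diff_var <- sum((k_diff - mu_diff)^2 * pxy_diff)
  diff_ent <- -sum(pxy_diff * log2z(pxy_diff))

  hx <- -sum(px * log2z(px)); hy <- -sum(py * log2z(py))
  pxpy <- outer(px, py)
  hxy1 <- -sum(P * log2z(pxpy))
  hxy2 <- -sum(pxpy * log2z(pxpy))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - entropy)), 0))

  autocorr <- sum(i * j * P)
  cs <- sum((i + j - mux - muy)^3 * P)
  cp <- sum((i + j - mux - muy)^4 * P)

  stats::setNames(
    c(energy, entropy, contrast, dissim, homog, corr, variance, sum_avg,
      sum_var, sum_ent, diff_var, diff_ent, imc1, imc2, autocorr, cs, cp),
    nm)
}

na_vector <- function(nm) stats::setNames(rep(NA_real_, length(nm)), nm)

#' Gray-tone difference features (NGTDM)
#'
#' Amadasun-King neighborhood gray-tone difference formulation with an
#' in-plane radius-1 (3x3) neighborhood; only pixels whose neighborhood
#' lies fully inside the mask contribute, and slices are accumulated.
#' Denominators are guarded with `eps = 1e-12` (a constant ROI therefore
#' returns the 1/eps-capped Coarseness maximum).
#'
#' @inheritParams glcm_features
#' @param eps Denominator guard.
#' @return Named numeric vector: Coarseness, Contrast, Busyness,
#'   Complexity, Strength (all `NA` when no interior pixel exists).
#' @export
gtdm_features <- function(q, eps = 1e-12) {
  G <- q$G
  s_i <- numeric(G); n_i <- numeric(G)
  for (sl in roi_slices(q)) {
    acc <- gtdm_slice(sl, G)
    s_i <- s_i + acc$s; n_i <- n_i + acc$n
  }
  nm <- paste0("GTDM_", c("Coarseness", "Contrast", "Busyness",
                          "Complexity", "Strength"))
  N <- sum(n_i)
  if (N == 0) return(na_vector(nm))
  p_i <- n_i / N
  pres <- which(p_i > 0)
  Ng <- length(pres)
  lv <- seq_len(G)

  coarse <- 1 / (eps + sum(p_i * s_i))
  if (Ng > 1) {
    pp <- outer(p_i[pres], p_i[pres])
    dd <- outer(lv[pres], lv[pres], "-")
    contrast <- (sum(pp * dd^2) / (Ng * (Ng - 1))) * (sum(s_i) / N)
    busy_den <- sum(abs(outer(lv[pres] * p_i[pres], lv[pres] * p_i[pres], "-")))
    busy <- sum(p_i * s_i) / (eps + busy_den)
    psi <- p_i[pres] * s_i[pres]
    cplx <- sum(abs(dd) * (outer(psi, psi, "+")) /
                  (N * outer(p_i[pres], p_i[pres], "+")))
    strength <- sum((outer(p_i[pres], p_i[pres], "+")) * dd^2) /
      (eps + sum(s_i))
  } else {
    contrast <- 0; busy <- 0; cplx <- 0; strength <- 0
  }
  stats::setNames(c(coarse, contrast, busy, cplx, strength), nm)
}

gtdm_slice <- function(sl, G) {
  nr <- nrow(sl); nc <- ncol(sl)
  s <- numeric(G); n <- numeric(G)
  if (nr < 3L || nc < 3L) return(list(s = s, n = n))
  inm <- sl > 0L
  ctr_r <- 2:(nr - 1L); ctr_c <- 2:(nc - 1L)
  nbr_sum <- matrix(0, length(ctr_r), length(ctr_c))
  nbr_all <- matrix(TRUE, length(ctr_r), length(ctr_c))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nbr_sum <- nbr_sum + sl[ctr_r + dr, ctr_c + dc, drop = FALSE]
    nbr_all <- nbr_all & inm[ctr_r + dr, ctr_c + dc, drop = FALSE]
  }
  interior <- inm[ctr_r, ctr_c, drop = FALSE] & nbr_all
  if (!any(interior)) return(list(s = s, n = n))
  lev <- sl[ctr_r, ctr_c, drop = FALSE][interior]
  diff <- abs(lev - nbr_sum[interior] / 8)
  s_acc <- rowsum(diff, lev)
  s[as.integer(rownames(s_acc))] <- s_acc[, 1]
  n <- tabulate(lev, nbins = G)
  list(s = s, n = n)
}

#' Gray-level run-length features
#'
#' Run-length matrices per axial slice over the four in-plane directions
#' (runs of consecutive equal levels; out-of-mask pixels break runs),
#' summed over directions and slices; 11 standard features.
#'
#' @inheritParams glcm_features
#' @param directions Integer subset of 1:4 (1 = horizontal, 2 = vertical,
#'   3 = diagonal, 4 = anti-diagonal); all four by default.
#' @return Named numeric vector of 11 features.
#' @export
runlength_features <- function(q, directions = 1:4) {
  G <- q$G
  maxlen <- max(dim(q$levels))
  R <- matrix(0, G, maxlen)
  Np <- 0
  for (sl in roi_slices(q)) {
    npix <- sum(sl > 0L)
    if (npix == 0L) next
    Np <- Np + npix * length(directions)
    for (dir in directions) R <- R + rl_matrix_slice(sl, G, maxlen, dir)
  }
  nm <- paste0("RL_", runlength_feature_names())
  Nr <- sum(R)
  if (Nr == 0) return(na_vector(nm))
  iL <- matrix(seq_len(G), G, maxlen)
  jL <- matrix(seq_len(maxlen), G, maxlen, byrow = TRUE)
  stats::setNames(c(
    sum(R / jL^2) / Nr,             # SRE
    sum(R * jL^2) / Nr,             # LRE
    sum(rowSums(R)^2) / Nr,         # GLN
    sum(colSums(R)^2) / Nr,         # RLN
    Nr / Np,                        # RP
    sum(R / iL^2) / Nr,             # LGRE
    sum(R * iL^2) / Nr,             # HGRE
    sum(R / (iL^2 * jL^2)) / Nr,    # SRLGE
    sum(R * iL^2 / jL^2) / Nr,      # SRHGE
    sum(R * jL^2 / iL^2) / Nr,      # LRLGE
    sum(R * iL^2 * jL^2) / Nr       # LRHGE
  ), nm)
}

rl_matrix_slice <- function(sl, G, maxlen, dir) {
  lines <- switch(dir,
                  split(sl, row(sl)),                 # horizontal runs
                  split(sl, col(sl)),                 # vertical runs
                  split(sl, col(sl) - row(sl)),       # diagonal
                  split(sl, col(sl) + row(sl)))       # anti-diagonal
  R <- matrix(0, G, maxlen)
  for (ln in lines) {
    r <- rle(as.integer(ln))
    keep <- r$values > 0L
    if (!any(keep)) next
    idx <- cbind(r$values[keep], r$lengths[keep])
    for (k in seq_len(nrow(idx)))
      R[idx[k, 1], idx[k, 2]] <- R[idx[k, 1], idx[k, 2]] + 1
  }
  R
}
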