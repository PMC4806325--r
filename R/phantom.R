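#' Specify a synthetic CT tumor phantom
#'
#' The phantom emulates a lung tumor on unenhanced CT: a lung-like
#' low-density background, a roughly ellipsoidal soft-tissue tumor whose
#' interior is a correlated Gaussian random field (tumor heterogeneity),
#' optional margin spiculation (a low-order spherical-harmonic radial
#' perturbation) and an optional adjacent vessel. The high-resolution
#' master grid is isotropic at 0.625 mm so that the study slice
#' thicknesses 1.25 / 2.5 / 5 mm are exact slabs of 2 / 4 / 8 voxels.
#'
#' @param tumor_radius Tumor radius in mm (2-30); must fit in the field of
#'   view with a 2 mm margin.
#' @param texture_sd Amplitude (HU) of the internal texture field.
#' @param texture_corr_len Gaussian correlation length (mm) of the texture;
#'   at least one high-resolution voxel (0.625 mm).
#' @param spiculation_amp Radial boundary perturbation as a fraction of the
#'   radius, 0-0.5.
#' @param vessel Logical; add a vessel tangent to the tumor.
#' @param vessel_radius Vessel radius in mm.
#' @param background_hu Mean background density (lung parenchyma), HU.
#' @param background_texture_sd Texture amplitude of the background, HU.
#' @param tumor_hu Mean tumor density, HU.
#' @param noise_sd Acquisition noise (HU), consumed by [acquire()].
#' @param fov_mm Cubic field-of-view edge length, mm.
#' @param seed Integer seed; the phantom is deterministic given the seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(tumor_radius = 10, texture_sd = 80,
                         texture_corr_len = 2, spiculation_amp = 0,
                         vessel = FALSE, vessel_radius = 1.5,
                         background_hu = -850, background_texture_sd = 40,
                         tumor_hu = 0, noise_sd = 20, fov_mm = 40,
                         seed = 1L) {
  stopifnot(tumor_radius >= 2, tumor_radius <= 30,
            texture_sd >= 0, spiculation_amp >= 0, spiculation_amp <= 0.5,
            noise_sd >= 0, fov_mm > 0)
  hires <- 0.625
  if (texture_corr_len < hires)
    stop("texture_corr_len must be >= the high-resolution voxel size (",
         hires, " mm)", call. = FALSE)
  max_r <- tumor_radius * (1 + spiculation_amp)
  if (max_r + 2 > fov_mm / 2)
    stop("tumor exceeds field of view: needs a 2 mm margin inside ",
         fov_mm, " mm FOV", call. = FALSE)
  structure(list(tumor_radius = tumor_radius, texture_sd = texture_sd,
                 texture_corr_len = texture_corr_len,
                 spiculation_amp = spiculation_amp, vessel = vessel,
                 vessel_radius = vessel_radius, background_hu = background_hu,
                 background_texture_sd = background_texture_sd,
                 tumor_hu = tumor_hu, noise_sd = noise_sd, fov_mm = fov_mm,
                 hires_mm = hires, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Legendre polynomials used for the radial spiculation basis
legendre_p <- function(l, x) {
  switch(as.character(l),
         "2" = (3 * x^2 - 1) / 2,
         "3" = (5 * x^3 - 3 * x) / 2,
         "4" = (35 * x^4 - 30 * x^2 + 3) / 8,
         stop("unsupported Legendre order"))
}

#' Generate the high-resolution phantom volume and ground-truth mask
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` (a [voxel_grid()]) and `mask`
#'   (a [segmentation_mask()]), both at 0.625 mm isotropic resolution.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_local_seed(spec$seed, {
    h <- spec$hires_mm
    n <- round(spec$fov_mm / h)
    sp <- c(h, h, h)
    ctr <- (n + 1) / 2                       # voxel index of the FOV centre

    idx <- expand_grid_indices(c(n, n, n))
    dz <- (idx[, 1] - ctr) * h
    dy <- (idx[, 2] - ctr) * h
    dx <- (idx[, 3] - ctr) * h
    r <- sqrt(dz^2 + dy^2 + dx^2)

    # spiculation: radius modulated by a low-order spherical-harmonic field
    if (spec$spiculation_amp > 0) {
      nb <- 4L
      u <- matrix(stats::rnorm(3 * nb), nb, 3)
      u <- u / sqrt(rowSums(u^2))
      a <- stats::rnorm(nb)
      l <- sample(2:4, nb, replace = TRUE)
      dir <- cbind(dz, dy, dx) / pmax(r, 1e-9)
      g <- numeric(length(r))
      for (j in seq_len(nb)) g <- g + a[j] * legendre_p(l[j], dir %*% u[j, ])
      g <- g / max(abs(g))
      radius <- spec$tumor_radius * (1 + spec$spiculation_amp * g)
    } else {
      radius <- spec$tumor_radius
    }
    inside <- r <= radius
    mask <- array(as.integer(inside), dim = c(n, n, n))

    # correlated Gaussian random field, unit variance after smoothing
    field <- array(stats::rnorm(n^3), dim = c(n, n, n))
    sig_vox <- spec$texture_corr_len / h
    field <- blur3d(field, rep(sig_vox, 3))
    field <- field / stats::sd(field)

    vol <- array(spec$background_hu + spec$background_texture_sd * field,
                 dim = c(n, n, n))
    vol[inside] <- spec$tumor_hu + spec$texture_sd * field[inside]

    if (isTRUE(spec$vessel)) {
      # vessel: a z-axis cylinder tangent to the tumor on the +x side
      vx <- spec$tumor_radius + spec$vessel_radius
      in_vessel <- (dy^2 + (dx - vx)^2) <= spec$vessel_radius^2 & !inside
      vol[in_vessel] <- 50
    }

    list(volume = voxel_grid(vol, sp),
         mask = segmentation_mask(mask, sp))
  })
}

#' Acquisition parameters for repeat-scan emulation
#'
#' Repeat scans of the same patient differ by a small rigid repositioning
#' and an independent noise realization; anatomy is fixed (the study's
#' repeat scans were 15 minutes apart).
#'
#' @param shift_sd SD (mm, per axis) of the rigid translation drawn per scan.
#' @param noise_sd SD (HU) of additive Gaussian acquisition noise.
#' @param seed Integer seed; scans 1 and 2 derive distinct substreams.
#' @return An `acquisition_params` list.
#' @export
acquisition_params <- function(shift_sd = 1.0, noise_sd = 20, seed = 1L) {
  stopifnot(shift_sd >= 0, noise_sd >= 0)
  structure(list(shift_sd = shift_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "acquisition_params")
}

#' Emulate one repeat-scan acquisition
#'
#' Applies a rigid translation (per-axis normal, sd `shift_sd`) followed by
#' additive white Gaussian noise (sd `noise_sd`) to the high-resolution
#' phantom; the truth mask is translated identically. Scans 1 and 2 of the
#' same phantom differ only in shift and noise realization.
#'
#' @param volume High-resolution [voxel_grid()] from [generate_phantom()].
#' @param mask Matching [segmentation_mask()].
#' @param params An [acquisition_params()].
#' @param scan_index 1 or 2.
#' @return A list with translated, noise-corrupted `volume` and translated
#'   `mask`.
#' @export
acquire <- function(volume, mask, params, scan_index) {
  stopifnot(inherits(params, "acquisition_params"),
            scan_index %in% c(1L, 2L))
  check_aligned(volume, mask)
  with_local_seed(params$seed + 7919L * as.integer(scan_index), {
    shift_mm <- stats::rnorm(3, sd = params$shift_sd)
    shift_vox <- shift_mm / volume$spacing
    vol <- volume$data
    msk <- mask$data
    if (params$shift_sd > 0 && any(shift_vox != 0)) {
      vol <- translate3(vol, shift_vox)
      msk <- array(as.integer(translate3(msk + 0, shift_vox) >= 0.5),
                   dim = dim(msk))
    }
    if (params$noise_sd > 0)
      vol <- vol + array(stats::rnorm(length(vol), sd = params$noise_sd),
                         dim = dim(vol))
    list(volume = voxel_grid(vol, volume$spacing, volume$origin),
         mask = segmentation_mask(msk, mask$spacing, mask$origin))
  })
}

#' Reconstruct an acquired scan at an imaging setting
#'
#' Through-plane: slices are slab-averaged to the target thickness (exact
#' integer slabs of the 0.625 mm master grid). In-plane, the reconstruction
#' kernel is modeled in image space: the smooth ("standard") kernel is a
#' Gaussian low-pass (sigma 1 mm), the sharp ("lung") kernel an unsharp
#' enhancement `I + alpha * (I - blur(I))` with `alpha = 1`, which amplifies
#' both detail and noise — the contrast between the two kernels the
#' reproducibility analysis studies. The mask is slab-resampled by majority.
#'
#' @param volume Acquired [voxel_grid()].
#' @param mask Matching [segmentation_mask()].
#' @param setting An [imaging_setting()].
#' @param sigma_mm In-plane kernel scale (mm) for both blur and unsharp.
#' @param alpha Unsharp gain of the sharp kernel.
#' @return A list with reconstructed `volume` and `mask`; z spacing equals
#'   the setting's slice thickness.
#' @export
reconstruct <- function(volume, mask, setting, sigma_mm = 1.0, alpha = 1.0) {
  stopifnot(inherits(setting, "imaging_setting"))
  check_aligned(volume, mask)
  dz <- volume$spacing[1]
  f <- setting$thickness / dz
  if (abs(f - round(f)) > 1e-9)
    stop("slice thickness ", setting$thickness,
         " mm is not an integer multiple of source z spacing ", dz, " mm",
         call. = FALSE)
  f <- as.integer(round(f))
  d <- dim(volume$data)
  nz_out <- d[1] %/% f
  keep <- seq_len(nz_out * f)
  slab <- rep(seq_len(nz_out), each = f)

  vmat <- matrix(volume$data[keep, , , drop = FALSE], nz_out * f, d[2] * d[3])
  vslab <- rowsum(vmat, slab) / f
  mmat <- matrix(mask$data[keep, , , drop = FALSE], nz_out * f, d[2] * d[3])
  mslab <- rowsum(mmat, slab) >= f / 2

  vol <- array(vslab, dim = c(nz_out, d[2], d[3]))
  msk <- array(as.integer(mslab), dim = c(nz_out, d[2], d[3]))

  sig_px_row <- sigma_mm / volume$spacing[2]
  sig_px_col <- sigma_mm / volume$spacing[3]
  Mr <- blur_operator(d[2], sig_px_row)
  Mc <- t(blur_operator(d[3], sig_px_col))
  for (k in seq_len(nz_out)) {
    sl <- vol[k, , ]
    bl <- Mr %*% sl %*% Mc
    vol[k, , ] <- if (setting$kernel == "smooth") bl else sl + alpha * (sl - bl)
  }

  sp <- c(setting$thickness, volume$spacing[2], volume$spacing[3])
  or <- volume$origin + c((f - 1) / 2 * dz, 0, 0)
  list(volume = voxel_grid(vol, sp, or),
       mask = segmentation_mask(msk, sp, or))
}

#' Generate a synthetic repeat-scan cohort on disk
#'
#' Writes `n` subjects x 2 repeat scans x 6 imaging settings of volumes and
#' masks (NRRD) plus a `manifest.tsv` and a JSON sidecar echoing the
#' per-subject phantom parameters. Per-subject phantom parameters are drawn
#' uniformly within `spec_ranges`; everything is deterministic given `seed`.
#'
#' @param n Number of subjects (>= 2).
#' @param root Output directory (created if needed).
#' @param seed Integer master seed.
#' @param spec_ranges Named list of `c(min, max)` ranges for
#'   `tumor_radius`, `texture_sd`, `texture_corr_len`, `spiculation_amp`,
#'   `vessel_radius`, plus scalars `vessel_prob`, `noise_sd`, `shift_sd`.
#' @return The validated [load_manifest()] tibble for `root`.
#' @export
generate_cohort <- function(n, root, seed = 1L,
                            spec_ranges = cohort_defaults()) {
  stopifnot(n >= 2)
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  sr <- utils::modifyList(cohort_defaults(), spec_ranges)
  settings <- all_settings()
  rows <- list()
  sidecar <- list()
  for (i in seq_len(n)) {
    subj <- sprintf("S%02d", i)
    subj_seed <- as.integer(seed) + 101L * i
    draw <- with_local_seed(subj_seed, list(
      tumor_radius = stats::runif(1, sr$tumor_radius[1], sr$tumor_radius[2]),
      texture_sd = stats::runif(1, sr$texture_sd[1], sr$texture_sd[2]),
      texture_corr_len = stats::runif(1, sr$texture_corr_len[1],
                                      sr$texture_corr_len[2]),
      spiculation_amp = stats::runif(1, sr$spiculation_amp[1],
                                     sr$spiculation_amp[2]),
      vessel = stats::runif(1) < sr$vessel_prob,
      vessel_radius = stats::runif(1, sr$vessel_radius[1], sr$vessel_radius[2])
    ))
    spec <- phantom_spec(tumor_radius = draw$tumor_radius,
                         texture_sd = draw$texture_sd,
                         texture_corr_len = draw$texture_corr_len,
                         spiculation_amp = draw$spiculation_amp,
                         vessel = draw$vessel,
                         vessel_radius = draw$vessel_radius,
                         noise_sd = sr$noise_sd,
                         seed = subj_seed)
    ph <- generate_phantom(spec)
    sidecar[[subj]] <- c(draw, list(noise_sd = sr$noise_sd,
                                    shift_sd = sr$shift_sd, seed = subj_seed))
    for (scan in 1:2) {
      acq <- acquire(ph$volume, ph$mask,
                     acquisition_params(shift_sd = sr$shift_sd,
                                        noise_sd = sr$noise_sd,
                                        seed = subj_seed + 17L * scan),
                     scan_index = scan)
      for (st in settings) {
        rec <- reconstruct(acq$volume, acq$mask, st)
        vfile <- sprintf("%s_scan%d_%s_vol.nrrd", subj, scan, st$label)
        mfile <- sprintf("%s_scan%d_%s_mask.nrrd", subj, scan, st$label)
        write_volume(rec$volume, file.path(root, vfile))
        write_volume(rec$mask, file.path(root, mfile))
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = subj, scan = scan, setting = st$label,
          volume_path = vfile, mask_path = mfile,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(root, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = as.integer(seed), n = as.integer(n),
                            ranges = sr, subjects = sidecar),
                       file.path(root, "phantom_params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  load_manifest(root)
}

#' @rdname generate_cohort
#' @export
cohort_defaults <- function() {
  list(tumor_radius = c(6, 14), texture_sd = c(60, 120),
       texture_corr_len = c(1.5, 3), spiculation_amp = c(0, 0.25),
       vessel_prob = 0.5, vessel_radius = c(1, 2),
       noise_sd = 20, shift_sd = 1.0)
}
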