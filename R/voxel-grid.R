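#' Construct a voxel grid
#'
#' A `voxel_grid` is the carrier of all intensity computation: a 3D scalar
#' array of CT numbers (Hounsfield units) together with physical voxel
#' spacing. The axis convention is fixed throughout the package:
#' `data[z, y, x]` (slice, row, column), spacing `c(dz, dy, dx)` in mm.
#'
#' @param data 3D numeric array ordered (z, y, x).
#' @param spacing Numeric length-3, voxel size in mm per axis `(dz, dy, dx)`;
#'   all strictly positive.
#' @param origin Numeric length-3, physical position (mm) of voxel
#'   `[1, 1, 1]`, ordered `(z, y, x)`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x); got a non-3D payload", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (dz, dy, dx) in mm",
         call. = FALSE)
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' Construct a segmentation mask
#'
#' Binary region-of-interest aligned voxel-for-voxel with a [voxel_grid()].
#' Any nonzero input value is coerced to 1 (with a warning when values other
#' than 0/1 are present), so mask dialects that encode labels survive reading.
#'
#' @param data 3D array coercible to 0/1, ordered (z, y, x).
#' @inheritParams voxel_grid
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask `data` must be a 3D array (z, y, x)", call. = FALSE)
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1))) {
    warning("mask contains values other than 0/1; coercing nonzero to 1",
            call. = FALSE)
  }
  m <- array(as.integer(data != 0), dim = dim(data))
  g <- voxel_grid(m, spacing, origin)
  class(g) <- c("segmentation_mask", "voxel_grid")
  g
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d (z,y,x), spacing %.4g x %.4g x %.4g mm\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  if (inherits(x, "segmentation_mask")) {
    cat(sprintf("  foreground voxels: %d\n", sum(x$data)))
  } else {
    cat(sprintf("  intensity range: [%.4g, %.4g] HU\n",
                min(x$data), max(x$data)))
  }
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

# voxel volume in mm^3
voxel_volume <- function(grid) prod(grid$spacing)

check_aligned <- function(grid, mask) {
  if (!identical(dim(grid$data), dim(mask$data)))
    stop("grid and mask shapes differ", call. = FALSE)
  if (max(abs(grid$spacing - mask$spacing)) > 1e-9)
    stop("grid and mask spacing differ", call. = FALSE)
  invisible(TRUE)
}

check_nonempty <- function(mask) {
  if (sum(mask$data) == 0L) stop("mask is empty", call. = FALSE)
  invisible(TRUE)
}

#' Imaging settings (slice thickness x reconstruction kernel)
#'
#' The study grid crosses three reconstructed slice thicknesses
#' (1.25, 2.5, 5 mm) with two reconstruction kernels: a sharp
#' (edge-enhancing, noisier, "lung", L) and a smooth (low-pass, "standard",
#' S) kernel. A setting serializes as `"<thickness><L|S>"`, e.g. `"1.25L"`.
#'
#' @param thickness Slice thickness in mm; one of 1.25, 2.5, 5.
#' @param kernel `"sharp"` or `"smooth"`.
#' @return An `imaging_setting` object with fields `thickness`, `kernel`
#'   and `label`.
#' @export
#' @examples
#' imaging_setting(1.25, "sharp")$label # "1.25L"
imaging_setting <- function(thickness, kernel = c("sharp", "smooth")) {
  thickness <- as.numeric(thickness)
  if (!thickness %in% c(1.25, 2.5, 5))
    stop("thickness must be one of 1.25, 2.5, 5 (mm)", call. = FALSE)
  kernel <- match.arg(kernel)
  label <- paste0(format(thickness, drop0trailing = TRUE),
                  if (kernel == "sharp") "L" else "S")
  structure(list(thickness = thickness, kernel = kernel, label = label),
            class = "imaging_setting")
}

#' @rdname imaging_setting
#' @param label A setting label such as `"2.5S"`.
#' @export
parse_setting <- function(label) {
  m <- regmatches(label, regexec("^([0-9.]+)\\s*([LS])$", label))[[1]]
  if (length(m) != 3L)
    stop("unrecognized setting label: ", label, call. = FALSE)
  imaging_setting(as.numeric(m[2]), if (m[3] == "L") "sharp" else "smooth")
}

#' @rdname imaging_setting
#' @export
all_settings <- function() {
  out <- list()
  for (th in c(1.25, 2.5, 5)) for (k in c("sharp", "smooth"))
    out[[length(out) + 1L]] <- imaging_setting(th, k)
  out
}

#' Enumerate the test-retest comparison pairs
#'
#' The reproducibility analysis compares scan 1 with scan 2 of each subject
#' under two schemes: six identical-setting pairs (both scans reconstructed
#' at the same setting) and three cross-kernel pairs (equal slice thickness,
#' sharp vs smooth kernel).
#'
#' @param which `"identical"`, `"cross"` or `"all"`.
#' @return A tibble with columns `pair` (label such as `"1.25L vs 1.25L"`),
#'   `setting1`, `setting2` and `type`.
#' @export
setting_pairs <- function(which = c("all", "identical", "cross")) {
  which <- match.arg(which)
  ident <- purrr::map_dfr(all_settings(), function(s) {
    tibble::tibble(pair = paste(s$label, "vs", s$label),
                   setting1 = s$label, setting2 = s$label,
                   type = "identical")
  })
  cross <- purrr::map_dfr(c(1.25, 2.5, 5), function(th) {
    l <- imaging_setting(th, "sharp")$label
    s <- imaging_setting(th, "smooth")$label
    tibble::tibble(pair = paste(l, "vs", s),
                   setting1 = l, setting2 = s, type = "cross")
  })
  switch(which, identical = ident, cross = cross,
         all = dplyr::bind_rows(ident, cross))
}
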