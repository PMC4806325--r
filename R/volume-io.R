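#' Read a 3D volume or mask from NRRD or NIfTI
#'
#' Formats are dispatched on the file extension (`.nrrd`, `.nii`,
#' `.nii.gz`). Spacing is taken from the file header and is required:
#' a file without usable spacing metadata is an error, never silently
#' assumed to be 1 mm isotropic.
#'
#' @param path Path to an existing `.nrrd`, `.nii` or `.nii.gz` file
#'   holding a 3D scalar payload.
#' @return A [voxel_grid()].
#' @seealso [write_volume()], [read_mask()]
#' @export
read_volume <- function(path) {
  raw <- read_any_volume(path)
  voxel_grid(raw$data, raw$spacing, raw$origin)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  raw <- read_any_volume(path)
  segmentation_mask(raw$data, raw$spacing, raw$origin)
}

read_any_volume <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    read_nrrd(path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
      stop("non-3D payload in NIfTI file: ", path, call. = FALSE)
    sp <- RNifti::pixdim(img)[1:3]                # (dx, dy, dz)
    if (anyNA(sp) || any(sp <= 0))
      stop("non-positive spacing in NIfTI header: ", path, call. = FALSE)
    list(data = aperm(unclass(img)[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]),
                                   drop = FALSE], c(3, 2, 1)),
         spacing = rev(sp), origin = c(0, 0, 0))
  } else {
    stop("unsupported format (expect .nrrd, .nii or .nii.gz): ", path,
         call. = FALSE)
  }
}

#' Write a volume or mask to NRRD or NIfTI
#'
#' Integer payloads roundtrip bit-exactly; floating payloads are stored as
#' 64-bit doubles and roundtrip within 1e-6 HU.
#'
#' @param grid A [voxel_grid()] or [segmentation_mask()].
#' @param path Output path ending in `.nrrd`, `.nii` or `.nii.gz`; the parent
#'   directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  is_mask <- inherits(grid, "segmentation_mask")
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_nrrd(grid$data, grid$spacing, grid$origin, path,
               type = if (is_mask) "uint8" else "double")
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    arr <- aperm(grid$data, c(3, 2, 1))           # -> (x, y, z)
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rev(grid$spacing)
    RNifti::writeNifti(img, path,
                       datatype = if (is_mask) "uint8" else "double")
  } else {
    stop("unsupported format (expect .nrrd, .nii or .nii.gz): ", path,
         call. = FALSE)
  }
  invisible(path)
}

#' Load and validate a cohort manifest
#'
#' A cohort directory holds one `manifest.tsv` with columns `subject_id`,
#' `scan` (1 or 2), `setting` (label such as `"2.5S"`), `volume_path`,
#' `mask_path` (paths relative to the directory or absolute). Every subject
#' must have both repeat scans for every setting it lists — the same-day
#' repeat design the concordance analysis assumes.
#'
#' @param root Directory containing `manifest.tsv`.
#' @return A tibble of class `cohort_manifest` with one row per
#'   (subject, scan, setting) entry and resolved absolute paths.
#' @export
load_manifest <- function(root) {
  mf <- file.path(root, "manifest.tsv")
  if (!dir.exists(root) || !file.exists(mf))
    stop("no manifest: expected ", mf, call. = FALSE)
  tab <- utils::read.delim(mf, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("subject_id", "scan", "setting", "volume_path", "mask_path")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("manifest lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  tab <- tibble::as_tibble(tab)
  tab$scan <- as.integer(tab$scan)
  if (!all(tab$scan %in% c(1L, 2L)))
    stop("manifest scan values must be 1 or 2", call. = FALSE)
  for (s in unique(tab$setting)) parse_setting(s)   # validates labels
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(root, p))
  tab$volume_path <- resolve(tab$volume_path)
  tab$mask_path <- resolve(tab$mask_path)

  # pairing invariant: both scans for every (subject, setting)
  gaps <- tab |>
    dplyr::distinct(.data$subject_id, .data$setting, .data$scan) |>
    dplyr::count(.data$subject_id, .data$setting) |>
    dplyr::filter(.data$n != 2L)
  if (nrow(gaps))
    stop("manifest pairing violated (need scans 1 and 2) for: ",
         paste(paste0(gaps$subject_id, "@", gaps$setting), collapse = ", "),
         call. = FALSE)
  missing_files <- tab[!file.exists(tab$volume_path) |
                         !file.exists(tab$mask_path), ]
  if (nrow(missing_files))
    stop("manifest references missing files for: ",
         paste(sprintf("(%s, scan %d, %s)", missing_files$subject_id,
                       missing_files$scan, missing_files$setting),
               collapse = ", "),
         call. = FALSE)
  class(tab) <- c("cohort_manifest", class(tab))
  tab
}
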