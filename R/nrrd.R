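# Minimal NRRD (Nearly Raw Raster Data) reader/writer for 3D scalar volumes.
# Header is plain text; payload is raw little-endian (write) or raw/gzip (read).
# On disk the fastest axis is x (NRRD convention); in memory the package uses
# (z, y, x), so payloads are permuted on the way through.

nrrd_type_map <- c(
  "signed char" = "int8", "int8" = "int8", "int8_t" = "int8",
  "uchar" = "uint8", "unsigned char" = "uint8", "uint8" = "uint8",
  "uint8_t" = "uint8",
  "short" = "int16", "short int" = "int16", "int16" = "int16",
  "int16_t" = "int16",
  "int" = "int32", "signed int" = "int32", "int32" = "int32",
  "int32_t" = "int32",
  "float" = "float", "double" = "double"
)

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD000[0-9]$", magic))
    stop("not an NRRD file: ", path, call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated NRRD header: ", path, call. = FALSE)
    if (line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  dimn <- as.integer(fields[["dimension"]])
  if (is.na(dimn) || dimn != 3L)
    stop("non-3D payload in NRRD file: ", path, call. = FALSE)
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  type <- nrrd_type_map[[tolower(fields[["type"]])]]
  if (is.null(type)) stop("unsupported NRRD type: ", fields[["type"]], call. = FALSE)

  spacing_xyz <- nrrd_spacing(fields, path)
  origin_xyz <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin_xyz <- nrrd_vector(fields[["space origin"]])

  encoding <- tolower(fields[["encoding"]] %||% "raw")
  n <- prod(sizes)
  bytes_per <- switch(type, int8 = 1L, uint8 = 1L, int16 = 2L, int32 = 4L,
                      float = 4L, double = 8L)
  if (encoding == "raw") {
    payload <- readBin(con, "raw", n = n * bytes_per)
  } else if (encoding %in% c("gzip", "gz")) {
    payload <- memDecompress(readBin(con, "raw", n = file.size(path)),
                             type = "gzip")
  } else {
    stop("unsupported NRRD encoding: ", encoding, call. = FALSE)
  }
  what <- switch(type, float = "double", double = "double", "integer")
  size <- switch(type, float = 4L, double = 8L, bytes_per)
  signed <- !identical(type, "uint8")
  vals <- readBin(payload, what, n = n, size = size, signed = signed,
                  endian = tolower(fields[["endian"]] %||% "little"))
  arr <- array(vals, dim = sizes)        # (x, y, z) on disk
  arr <- aperm(arr, c(3, 2, 1))          # -> (z, y, x)
  list(data = arr,
       spacing = rev(spacing_xyz),       # -> (dz, dy, dx)
       origin = rev(origin_xyz),
       type = type)
}

nrrd_vector <- function(s) {
  as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
}

# Spacing must be stated in the header ("spacings" or "space directions");
# absent spacing is an error, never defaulted to 1 mm.
nrrd_spacing <- function(fields, path) {
  if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\([^)]*\\)", fields[["space directions"]]))[[1]]
    sp <- vapply(vecs, function(v) sqrt(sum(nrrd_vector(v)^2)), numeric(1))
  } else {
    stop("NRRD header carries no spacing metadata: ", path, call. = FALSE)
  }
  if (length(sp) != 3L || anyNA(sp) || any(sp <= 0))
    stop("non-positive or malformed spacing in NRRD header: ", path,
         call. = FALSE)
  sp
}

write_nrrd <- function(data, spacing, origin, path, type = c("double", "uint8")) {
  type <- match.arg(type)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  arr <- aperm(data, c(3, 2, 1))         # (z,y,x) -> (x,y,z) on disk
  sp <- rev(spacing)
  or <- rev(origin)
  hdr <- c(
    "NRRD0004",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(dim(arr), collapse = " ")),
    "space: left-posterior-superior",
    sprintf("space directions: (%.9g,0,0) (0,%.9g,0) (0,0,%.9g)",
            sp[1], sp[2], sp[3]),
    sprintf("space origin: (%.9g,%.9g,%.9g)", or[1], or[2], or[3]),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (type == "uint8") {
    writeBin(as.integer(arr), con, size = 1L, endian = "little")
  } else {
    writeBin(as.double(arr), con, size = 8L, endian = "little")
  }
  invisible(path)
}
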