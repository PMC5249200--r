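# Raster-volume file formats.  MHD (MetaImage header + detached RAW) and
# NRRD (attached header + raw payload) cover the interchange needs of the
# pipeline; both round-trip grid, voxel size and origin bit-exactly using
# little-endian doubles.

mhd_types <- c(MET_DOUBLE = "double", MET_FLOAT = "double",
               MET_SHORT = "integer", MET_USHORT = "integer",
               MET_UCHAR = "integer")
mhd_sizes <- c(MET_DOUBLE = 8, MET_FLOAT = 4, MET_SHORT = 2,
               MET_USHORT = 2, MET_UCHAR = 1)

#' Write a voxel volume as MHD + RAW
#'
#' MetaImage text header (`.mhd`) next to a little-endian raw payload
#' (`.raw`), `MET_DOUBLE` element type for a bit-exact round trip.
#'
#' @param volume A [voxel_volume()].
#' @param path Output header path ending in `.mhd`.
#' @return `path`, invisibly.
#' @export
write_mhd <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (!grepl("\\.mhd$", path)) stop_validation("path must end in .mhd")
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  d <- dim(volume$grid)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
           sprintf("ElementSpacing = %.17g %.17g %.17g", volume$voxel_size,
                   volume$voxel_size, volume$voxel_size),
           sprintf("Offset = %.17g %.17g %.17g", volume$origin[1],
                   volume$origin[2], volume$origin[3]),
           "ElementType = MET_DOUBLE",
           sprintf("ElementDataFile = %s", raw_name))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.vector(volume$grid), con, size = 8, endian = "little")
  invisible(path)
}

parse_kv_header <- function(lines, sep) {
  pos <- regexpr(sep, lines, fixed = TRUE)
  lines <- lines[pos > 0]
  pos <- pos[pos > 0]
  attr(pos, "match.length") <- rep(nchar(sep), length(pos))
  key <- trimws(substr(lines, 1, pos - 1))
  val <- trimws(substr(lines, pos + attr(pos, "match.length"),
                       nchar(lines)))
  stats::setNames(as.list(val), key)
}

#' Read an MHD + RAW voxel volume
#'
#' Malformed headers raise an error naming the offending field; a RAW
#' payload whose size does not match `DimSize` raises an explicit
#' size-mismatch error.
#'
#' @param path Path to a `.mhd` header.
#' @return A [voxel_volume()].
#' @export
read_mhd <- function(path) {
  hdr <- parse_kv_header(readLines(path), "=")
  need <- function(field) {
    v <- hdr[[field]]
    if (is.null(v)) stop_validation("MHD header missing field: ", field)
    v
  }
  ndims <- as.integer(need("NDims"))
  if (is.na(ndims) || ndims != 3)
    stop_validation("MHD field NDims: only 3-D volumes supported")
  dims <- as.integer(strsplit(need("DimSize"), "[ \t]+")[[1]])
  if (length(dims) != 3 || any(is.na(dims)) || any(dims < 2))
    stop_validation("MHD field DimSize: need three integers >= 2")
  spacing <- as.numeric(strsplit(need("ElementSpacing"), "[ \t]+")[[1]])
  if (length(spacing) != 3 || any(is.na(spacing)) || any(spacing <= 0))
    stop_validation("MHD field ElementSpacing: need three positive numbers")
  if (max(abs(spacing - spacing[1])) > 1e-12 * spacing[1])
    stop_validation("MHD field ElementSpacing: only isotropic spacing supported")
  origin <- if (!is.null(hdr$Offset)) {
    o <- as.numeric(strsplit(hdr$Offset, "[ \t]+")[[1]])
    if (length(o) != 3 || any(is.na(o)))
      stop_validation("MHD field Offset: need three numbers")
    o
  } else c(0, 0, 0)
  type <- need("ElementType")
  if (!type %in% names(mhd_types))
    stop_validation("MHD field ElementType: unsupported type ", type)
  if (!is.null(hdr$BinaryDataByteOrderMSB) &&
      tolower(hdr$BinaryDataByteOrderMSB) == "true")
    stop_validation("MHD field BinaryDataByteOrderMSB: big-endian unsupported")
  raw_path <- file.path(dirname(path), need("ElementDataFile"))
  if (!file.exists(raw_path))
    stop_validation("MHD field ElementDataFile: file not found: ", raw_path)
  n <- prod(dims)
  esize <- mhd_sizes[[type]]
  actual <- file.info(raw_path)$size
  if (actual != n * esize)
    stop_validation(sprintf(
      "MHD raw payload size mismatch: expected %d bytes (%d x %d), found %d",
      n * esize, n, esize, actual))
  con <- file(raw_path, "rb")
  on.exit(close(con))
  what <- mhd_types[[type]]
  vals <- readBin(con, what, n = n,
                  size = if (type == "MET_FLOAT") 4 else esize,
                  signed = !type %in% c("MET_UCHAR", "MET_USHORT"),
                  endian = "little")
  voxel_volume(array(as.numeric(vals), dim = dims), spacing[1], origin,
               metadata = list(source = path, element_type = type))
}

#' Write a voxel volume as NRRD
#'
#' Single-file NRRD (text header, blank line, little-endian raw doubles).
#' Extra metadata entries with scalar/numeric values are stored as NRRD
#' `key:=value` pairs and restored on read.
#'
#' @param volume A [voxel_volume()].
#' @param path Output path ending in `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  d <- dim(volume$grid)
  hdr <- c("NRRD0004",
           "# ctwear voxel volume",
           "type: double",
           "dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("spacings: %.17g %.17g %.17g", volume$voxel_size,
                   volume$voxel_size, volume$voxel_size),
           "endian: little",
           "encoding: raw",
           sprintf("axis origin: %.17g %.17g %.17g", volume$origin[1],
                   volume$origin[2], volume$origin[3]))
  md <- volume$metadata
  md <- md[vapply(md, function(v)
    is.atomic(v) && length(v) == 1 && !is.null(v), logical(1))]
  for (nm in names(md))
    hdr <- c(hdr, sprintf("%s:=%s", nm, format(md[[nm]], digits = 17)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, ""), con, sep = "\n")
  writeBin(as.vector(volume$grid), con, size = 8, endian = "little")
  invisible(path)
}

#' Read an NRRD voxel volume
#'
#' Supports the subset written by [write_nrrd()] (3-D, raw encoding,
#' little-endian double/float).  Errors name the offending header field;
#' truncated payloads raise a size-mismatch error.
#'
#' @param path Path to a `.nrrd` file.
#' @return A [voxel_volume()].
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # read header lines up to the blank separator
  lines <- character(0)
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) stop_validation("NRRD: no blank line ending header")
    if (ln == "") break
    lines <- c(lines, ln)
  }
  if (!grepl("^NRRD", lines[1])) stop_validation("NRRD: missing magic")
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[-1]  # magic line
  kv_meta <- parse_kv_header(lines[grepl(":=", lines)], ":=")
  fields <- parse_kv_header(lines[!grepl(":=", lines)], ": ")
  need <- function(f) {
    v <- fields[[f]]
    if (is.null(v)) stop_validation("NRRD header missing field: ", f)
    v
  }
  type <- need("type")
  if (!type %in% c("double", "float"))
    stop_validation("NRRD field type: unsupported type ", type)
  if (as.integer(need("dimension")) != 3)
    stop_validation("NRRD field dimension: only 3-D supported")
  if (need("encoding") != "raw")
    stop_validation("NRRD field encoding: only raw supported")
  if (!is.null(fields$endian) && fields$endian != "little")
    stop_validation("NRRD field endian: only little supported")
  dims <- as.integer(strsplit(need("sizes"), "[ \t]+")[[1]])
  if (length(dims) != 3 || any(is.na(dims)) || any(dims < 2))
    stop_validation("NRRD field sizes: need three integers >= 2")
  spacing <- as.numeric(strsplit(need("spacings"), "[ \t]+")[[1]])
  if (length(spacing) != 3 || any(is.na(spacing)) || any(spacing <= 0))
    stop_validation("NRRD field spacings: need three positive numbers")
  origin <- if (!is.null(fields[["axis origin"]]))
    as.numeric(strsplit(fields[["axis origin"]], "[ \t]+")[[1]])
  else c(0, 0, 0)
  n <- prod(dims)
  esize <- if (type == "double") 8L else 4L
  vals <- readBin(con, "numeric", n = n, size = esize, endian = "little")
  if (length(vals) != n)
    stop_validation(sprintf(
      "NRRD payload size mismatch: expected %d values, found %d", n,
      length(vals)))
  meta <- lapply(kv_meta, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  voxel_volume(array(vals, dim = dims), spacing[1], origin, metadata = meta)
}

#' Read or write a volume, dispatching on file extension
#'
#' `.mhd` uses MHD + RAW, `.nrrd` uses NRRD.
#'
#' @param path File path.
#' @param volume A [voxel_volume()] (write only).
#' @return `read_volume()` returns a [voxel_volume()]; `write_volume()`
#'   returns `path` invisibly.
#' @export
read_volume <- function(path) {
  if (grepl("\\.mhd$", path, ignore.case = TRUE)) return(read_mhd(path))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return(read_nrrd(path))
  stop_validation("unsupported volume format (use .mhd or .nrrd): ", path)
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  if (grepl("\\.mhd$", path, ignore.case = TRUE))
    return(write_mhd(volume, path))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE))
    return(write_nrrd(volume, path))
  stop_validation("unsupported volume format (use .mhd or .nrrd): ", path)
}
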