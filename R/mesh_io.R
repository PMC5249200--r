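#' Write a mesh as binary STL
#'
#' @param mesh A `surface_model`.
#' @param path Output path (`.stl`).
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_model"))
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "ctwear binary STL"))[1:80]
  writeBin(header, con)
  nt <- nrow(mesh$triangles)
  writeBin(as.integer(nt), con, size = 4, endian = "little")
  fn <- mesh_face_normals(mesh)
  nrm <- sqrt(rowSums(fn^2))
  fn <- fn / ifelse(nrm > 0, nrm, 1)
  v <- mesh$vertices
  tr <- mesh$triangles
  # 12 floats + uint16 attribute per facet
  block <- rbind(t(fn), t(v[tr[, 1], , drop = FALSE]),
                 t(v[tr[, 2], , drop = FALSE]), t(v[tr[, 3], , drop = FALSE]))
  raw_f <- writeBin(as.vector(block), raw(), size = 4, endian = "little")
  raw_f <- matrix(raw_f, nrow = 48)
  attr16 <- as.raw(c(0, 0))
  payload <- rbind(raw_f, matrix(rep(attr16, nt), nrow = 2))
  writeBin(as.vector(payload), con)
  invisible(path)
}

#' Read a binary STL mesh
#'
#' Triangle soups are welded on exact vertex coordinates before the
#' closedness check.
#'
#' @param path Path to a binary `.stl` file.
#' @param check Passed to [surface_model()].
#' @return A [surface_model()].
#' @export
read_stl <- function(path, check = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  nt <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!length(nt) || nt < 1) stop_validation("STL: bad triangle count")
  payload <- readBin(con, "raw", nt * 50)
  if (length(payload) < nt * 50)
    stop_validation("STL: truncated facet payload")
  m <- matrix(payload, nrow = 50)
  floats <- readBin(as.vector(m[1:48, ]), "numeric", n = 12 * nt, size = 4,
                    endian = "little")
  fl <- matrix(floats, nrow = 12)
  verts <- matrix(as.vector(fl[4:12, ]), ncol = 3, byrow = TRUE)
  key <- apply(verts, 1, paste, collapse = "|")
  uid <- match(key, unique(key))
  uverts <- verts[!duplicated(key), , drop = FALSE]
  tris <- matrix(uid, ncol = 3, byrow = TRUE)
  surface_model(uverts, tris, check = check)
}

#' Write a mesh as ASCII PLY, optionally with a per-vertex scalar
#'
#' @param mesh A `surface_model`.
#' @param path Output path (`.ply`).
#' @param scalar Optional numeric per-vertex scalar written as property
#'   `quality` (e.g. a wear deviation).
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, scalar = NULL) {
  stopifnot(inherits(mesh, "surface_model"))
  nv <- nrow(mesh$vertices)
  nt <- nrow(mesh$triangles)
  if (!is.null(scalar) && length(scalar) != nv)
    stop_validation("scalar must have one value per vertex")
  hdr <- c("ply", "format ascii 1.0", "comment ctwear surface",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           if (!is.null(scalar)) "property float quality",
           sprintf("element face %d", nt),
           "property list uchar int vertex_indices", "end_header")
  v <- mesh$vertices
  vtxt <- if (is.null(scalar))
    sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
  else
    sprintf("%.9g %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3], scalar)
  ftxt <- paste(3, mesh$triangles[, 1] - 1, mesh$triangles[, 2] - 1,
                mesh$triangles[, 3] - 1)
  writeLines(c(hdr, vtxt, ftxt), path)
  invisible(path)
}

#' Read an ASCII PLY mesh
#'
#' @param path Path to an ASCII `.ply` file.
#' @param check Passed to [surface_model()].
#' @return A [surface_model()]; a `quality` per-vertex property, when
#'   present, is attached as attribute `"scalar"`.
#' @export
read_ply <- function(path, check = TRUE) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop_validation("PLY: missing magic line")
  end <- match("end_header", lines)
  if (is.na(end)) stop_validation("PLY: missing end_header")
  hdr <- lines[1:end]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", hdr,
                                                   value = TRUE)))
  nt <- as.integer(sub("element face ", "", grep("^element face ", hdr,
                                                 value = TRUE)))
  if (!length(nv) || !length(nt)) stop_validation("PLY: missing elements")
  has_scalar <- any(grepl("^property float quality", hdr))
  vlines <- lines[(end + 1):(end + nv)]
  vm <- matrix(as.numeric(unlist(strsplit(vlines, " +"))), nrow = nv,
               byrow = TRUE)
  flines <- lines[(end + nv + 1):(end + nv + nt)]
  fm <- matrix(as.integer(unlist(strsplit(flines, " +"))), nrow = nt,
               byrow = TRUE)
  if (any(fm[, 1] != 3)) stop_validation("PLY: only triangle faces supported")
  m <- surface_model(vm[, 1:3, drop = FALSE], fm[, 2:4, drop = FALSE] + 1L,
                     check = check)
  if (has_scalar) attr(m, "scalar") <- vm[, 4]
  m
}
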