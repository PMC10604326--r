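#' Read a triangle mesh from STL, PLY or OBJ
#'
#' Binary and ASCII STL are both accepted. STL stores facets independently,
#' so vertices duplicated within 1e-6 mm are merged on read to recover
#' shared topology (required for correspondence bookkeeping). Units are
#' taken to be millimetres.
#'
#' @param path file path.
#' @param format one of `"stl"`, `"ply"`, `"obj"`; inferred from the file
#'   extension when `NULL`.
#' @return a [surface_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("cannot read mesh: no such file: ", path)
  format <- infer_format(path, format)
  switch(format,
         stl = read_stl(path),
         ply = read_ply(path),
         obj = read_obj(path))
}

#' Write a triangle mesh to STL, PLY or OBJ
#'
#' STL is written in binary form (`ascii = TRUE` for the text variant);
#' PLY and OBJ are written as ASCII.
#'
#' @param mesh a [surface_mesh()].
#' @param path output file path.
#' @param format one of `"stl"`, `"ply"`, `"obj"`; inferred from the file
#'   extension when `NULL`.
#' @param ascii write ASCII STL instead of binary STL.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, ascii = FALSE) {
  stopifnot_mesh(mesh)
  format <- infer_format(path, format)
  switch(format,
         stl = if (ascii) write_stl_ascii(mesh, path) else write_stl_binary(mesh, path),
         ply = write_ply(mesh, path),
         obj = write_obj(mesh, path))
  invisible(path)
}

infer_format <- function(path, format) {
  if (is.null(format)) {
    ext <- tolower(sub(".*\\.", "", path))
    format <- ext
  }
  format <- tolower(format)
  if (!format %in% c("stl", "ply", "obj"))
    stop("unsupported mesh format: ", format)
  format
}

# Merge duplicate vertices within `tol` mm; returns surface_mesh.
merge_vertices <- function(vertices, faces, tol = 1e-6) {
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  first <- !duplicated(key)
  remap <- match(key, key[first])   # position in the deduplicated list
  faces <- matrix(remap[faces], ncol = 3)
  surface_mesh(vertices[first, , drop = FALSE], faces)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 80L)
  if (length(head) < 80L) stop("not an STL file (truncated header): ", path)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  fsize <- file.info(path)$size
  is_binary <- length(ntri) == 1L && !is.na(ntri) &&
    fsize == 84 + 50 * as.numeric(ntri)
  close(con)
  on.exit()
  if (is_binary) read_stl_binary(path, ntri) else read_stl_ascii(path)
}

read_stl_binary <- function(path, ntri) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 84L))
  rec <- readBin(con, "raw", 50L * ntri)
  if (length(rec) < 50L * ntri) stop("truncated binary STL: ", path)
  rec <- matrix(rec, nrow = 50L)
  coords <- readBin(as.raw(rec[13:48, ]), "numeric", size = 4L,
                    n = 9L * ntri, endian = "little")
  coords <- matrix(coords, ncol = 3L, byrow = TRUE)   # 3*ntri vertex rows
  faces <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  merge_vertices(coords, faces)
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vlines) == 0L || length(vlines) %% 3L != 0L)
    stop("not a valid ASCII STL file: ", path)
  nums <- lapply(strsplit(trimws(vlines), "\\s+"),
                 function(p) as.numeric(p[2:4]))
  coords <- do.call(rbind, nums)
  if (any(!is.finite(coords))) stop("non-numeric vertex in STL: ", path)
  ntri <- nrow(coords) / 3L
  faces <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  merge_vertices(coords, faces)
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80L), con)
  f <- mesh$faces
  ntri <- nrow(f)
  writeBin(as.integer(ntri), con, size = 4L, endian = "little")
  n <- face_normals(mesh)
  v <- mesh$vertices
  # 12 little-endian floats + 2-byte attribute per facet, assembled in bulk
  flt <- t(cbind(n, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                 v[f[, 3], , drop = FALSE]))          # 12 x ntri
  bytes <- writeBin(as.numeric(flt), raw(), size = 4L, endian = "little")
  rec <- rbind(matrix(bytes, nrow = 48L), matrix(raw(2L * ntri), nrow = 2L))
  writeBin(as.vector(rec), con)
}

write_stl_ascii <- function(mesh, path) {
  f <- mesh$faces
  v <- mesh$vertices
  n <- face_normals(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]), con)
    writeLines("    outer loop", con)
    for (k in 1:3) {
      p <- v[f[i, k], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
    }
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid mesh", con)
}

read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) < 3L || txt[1] != "ply") stop("not a PLY file: ", path)
  if (!any(grepl("format ascii", txt[1:5])))
    stop("only ASCII PLY is supported: ", path)
  endh <- match("end_header", txt)
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", txt[1:endh], value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", txt[1:endh], value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("malformed PLY header: ", path)
  vl <- txt[(endh + 1):(endh + nv)]
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(p) as.numeric(p[1:3])))
  fl <- txt[(endh + nv + 1):(endh + nv + nf)]
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(p) {
    p <- as.integer(p)
    if (p[1] != 3L) stop("only triangle faces are supported in PLY")
    p[2:4] + 1L
  }))
  surface_mesh(verts, faces)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.12g %.12g %.12g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
}

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", txt, value = TRUE)
  fl <- grep("^f\\s", txt, value = TRUE)
  if (length(vl) == 0L || length(fl) == 0L) stop("not a valid OBJ file: ", path)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(p) as.numeric(p[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(p) {
    idx <- as.integer(sub("/.*", "", p[-1]))
    if (length(idx) != 3L) stop("only triangle faces are supported in OBJ")
    idx
  }))
  surface_mesh(verts, faces)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(sprintf("v %.12g %.12g %.12g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
}
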