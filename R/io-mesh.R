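# Triangle-mesh readers and writers for STL (binary and ASCII), OBJ and
# PLY (ASCII).  STL is a triangle soup, so reading rebuilds an indexed
# mesh by merging exactly coincident vertices; OBJ faces are 1-based per
# that format, PLY faces 0-based, and both map to the package's internal
# 1-based indexing.

.mesh_format_from_ext <- function(file) {
  ext <- tolower(sub(".*\\.", "", file))
  if (!ext %in% c("stl", "obj", "ply"))
    stop(io_error(paste0("unknown mesh file extension: .", ext)))
  ext
}

# soup (3m x 3 matrix of vertex rows, consecutive triples) -> indexed
.soup_to_mesh <- function(tri_vertices) {
  key <- apply(tri_vertices, 1L, function(r) paste(sprintf("%.9g", r),
                                                   collapse = "_"))
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  triangle_mesh(tri_vertices[uk, , drop = FALSE],
                matrix(idx, ncol = 3L, byrow = TRUE))
}

.face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Read and write triangle meshes
#'
#' Formats are inferred from the file extension (`.stl`, `.obj`,
#' `.ply`).  STL can be written in `binary` (default) or `ascii`
#' flavour.  Loaders validate the mesh invariants and raise an IO error
#' (class `pathclip_io`) naming the offending record on malformed
#' input.
#'
#' @param file Path to the mesh file.
#' @param mesh A [triangle_mesh()].
#' @param format For STL writing: `"binary"` or `"ascii"`; ignored for
#'   other extensions.
#' @return `read_mesh()` returns a `triangle_mesh`; `write_mesh()`
#'   returns `file` invisibly.
#' @export
read_mesh <- function(file) {
  if (!file.exists(file)) stop(io_error(paste0("no such file: ", file)))
  switch(.mesh_format_from_ext(file),
         stl = .read_stl(file), obj = .read_obj(file), ply = .read_ply(file))
}

#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, file, format = c("binary", "ascii")) {
  stopifnot(is_triangle_mesh(mesh))
  format <- match.arg(format)
  switch(.mesh_format_from_ext(file),
         stl = if (format == "binary") .write_stl_binary(mesh, file)
               else .write_stl_ascii(mesh, file),
         obj = .write_obj(mesh, file),
         ply = .write_ply(mesh, file))
  invisible(file)
}

.read_stl <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 80L)
  if (length(head) < 80L) {
    # could still be a tiny ASCII file
    seek(con, 0L)
    txt <- rawToChar(readBin(con, "raw", file.size(file)))
    if (grepl("^\\s*solid", txt)) return(.parse_stl_ascii(txt, file))
    stop(io_error(paste0("truncated STL file: ", file)))
  }
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  expected <- 84 + 50 * as.numeric(n)
  if (length(n) == 1L && !is.na(n) && file.size(file) == expected) {
    rec <- readBin(con, "raw", 50L * n)
    if (length(rec) < 50L * n)
      stop(io_error(paste0("truncated binary STL: ", file)))
    m <- matrix(rec, nrow = 50L)
    floats <- readBin(as.raw(m[1:48, ]), "numeric", 12L * n, size = 4L,
                      endian = "little")
    fm <- matrix(floats, ncol = 12L, byrow = TRUE)
    tri <- matrix(t(fm[, 4:12, drop = FALSE]), ncol = 3L, byrow = TRUE)
    if (!all(is.finite(tri)))
      stop(io_error(paste0("non-finite vertex in binary STL: ", file)))
    return(.soup_to_mesh(tri))
  }
  # not a consistent binary STL; try ASCII
  txt <- tryCatch(paste(readLines(file, warn = FALSE), collapse = "\n"),
                  error = function(e) NULL)
  if (!is.null(txt) && grepl("^\\s*solid", txt))
    return(.parse_stl_ascii(txt, file))
  stop(io_error(paste0("malformed STL file: ", file)))
}

.parse_stl_ascii <- function(txt, file) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  vl <- grep("^\\s*vertex\\s", lines)
  if (!length(vl) || length(vl) %% 3L != 0L)
    stop(io_error(paste0("malformed ASCII STL (vertex count not a ",
                         "multiple of 3): ", file)))
  nums <- lapply(strsplit(trimws(lines[vl]), "\\s+"), function(tok) {
    x <- suppressWarnings(as.numeric(tok[-1L]))
    if (length(x) != 3L || any(!is.finite(x))) NULL else x
  })
  bad <- which(vapply(nums, is.null, TRUE))
  if (length(bad))
    stop(io_error(sprintf("malformed ASCII STL at line %d: %s",
                          vl[bad[1L]], file)))
  .soup_to_mesh(do.call(rbind, nums))
}

.write_stl_ascii <- function(mesh, file) {
  nrm <- .face_normals(mesh)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("solid pathclip", con)
  v <- mesh$vertices; f <- mesh$faces
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                       nrm[i, 1L], nrm[i, 2L], nrm[i, 3L]), con)
    writeLines("    outer loop", con)
    for (j in 1:3) {
      p <- v[f[i, j], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g",
                         p[1L], p[2L], p[3L]), con)
    }
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid pathclip", con)
}

.write_stl_binary <- function(mesh, file) {
  con <- file(file, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "pathclip binary STL"))[1:80]
  writeBin(header, con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  nrm <- .face_normals(mesh)
  v <- mesh$vertices; f <- mesh$faces
  attr_raw <- as.raw(c(0L, 0L))
  for (i in seq_len(nf)) {
    writeBin(c(nrm[i, ], v[f[i, 1L], ], v[f[i, 2L], ], v[f[i, 3L], ]),
             con, size = 4L, endian = "little")
    writeBin(attr_raw, con)
  }
}

.read_obj <- function(file) {
  lines <- readLines(file, warn = FALSE)
  vl <- grep("^v\\s", lines)
  fl <- grep("^f\\s", lines)
  if (!length(vl) || !length(fl))
    stop(io_error(paste0("malformed OBJ (no vertices or faces): ", file)))
  verts <- t(vapply(strsplit(trimws(lines[vl]), "\\s+"), function(tok) {
    x <- suppressWarnings(as.numeric(tok[2:4]))
    x
  }, numeric(3L)))
  if (!all(is.finite(verts)))
    stop(io_error(paste0("non-finite vertex coordinate in OBJ: ", file)))
  faces <- t(vapply(strsplit(trimws(lines[fl]), "\\s+"), function(tok) {
    idx <- suppressWarnings(as.integer(sub("/.*", "", tok[-1L])))
    if (length(idx) != 3L) stop(io_error(
      paste0("only triangular faces are supported: ", file)))
    idx
  }, integer(3L)))
  tryCatch(triangle_mesh(verts, faces), error = function(e)
    stop(io_error(paste0("invalid OBJ mesh (", conditionMessage(e), "): ",
                         file))))
}

.write_obj <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# pathclip OBJ", con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1L], mesh$faces[, 2L],
                     mesh$faces[, 3L]), con)
}

.read_ply <- function(file) {
  lines <- readLines(file, warn = FALSE)
  if (!length(lines) || lines[1L] != "ply")
    stop(io_error(paste0("not a PLY file: ", file)))
  endh <- match("end_header", lines)
  if (is.na(endh)) stop(io_error(paste0("PLY header not terminated: ", file)))
  head <- lines[seq_len(endh)]
  if (!any(grepl("^format ascii", head)))
    stop(io_error(paste0("only ASCII PLY is supported: ", file)))
  nv <- as.integer(sub("element vertex\\s+", "",
                       grep("^element vertex", head, value = TRUE)[1L]))
  nf <- as.integer(sub("element face\\s+", "",
                       grep("^element face", head, value = TRUE)[1L]))
  if (is.na(nv) || is.na(nf))
    stop(io_error(paste0("PLY vertex/face counts missing: ", file)))
  body <- lines[(endh + 1L):length(lines)]
  if (length(body) < nv + nf)
    stop(io_error(paste0("truncated PLY body: ", file)))
  verts <- t(vapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                    function(tok) suppressWarnings(as.numeric(tok[1:3])),
                    numeric(3L)))
  if (!all(is.finite(verts)))
    stop(io_error(paste0("non-finite vertex coordinate in PLY: ", file)))
  faces <- t(vapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                    function(tok) {
    cnt <- suppressWarnings(as.integer(tok[1L]))
    if (is.na(cnt) || cnt != 3L)
      stop(io_error(paste0("only triangular PLY faces are supported: ",
                           file)))
    suppressWarnings(as.integer(tok[2:4])) + 1L
  }, integer(3L)))
  tryCatch(triangle_mesh(verts, faces), error = function(e)
    stop(io_error(paste0("invalid PLY mesh (", conditionMessage(e), "): ",
                         file))))
}

.write_ply <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0", "comment pathclip",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"),
             con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1L] - 1L,
                     mesh$faces[, 2L] - 1L, mesh$faces[, 3L] - 1L), con)
}
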