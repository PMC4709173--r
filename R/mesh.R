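# Indexed triangle surface meshes.

#' Create a triangle mesh
#'
#' @param vertices n x 3 numeric matrix of vertex positions (model
#'   units, typically mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (length(faces) == 0L) {
    faces <- matrix(integer(0), 0L, 3L)
  } else {
    faces <- as.matrix(faces)
    storage.mode(faces) <- "integer"
    if (ncol(faces) != 3L) stop("faces must be an m x 3 index matrix")
    if (any(faces < 1L) || any(faces > nrow(vertices)))
      stop("face index out of range")
    if (any(faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
            faces[, 1L] == faces[, 3L]))
      stop("a face references the same vertex twice")
  }
  structure(list(vertices = vertices, faces = faces),
            class = "triangle_mesh")
}

is_triangle_mesh <- function(x) inherits(x, "triangle_mesh")

#' Mesh summaries
#'
#' `mesh_area()` returns the total surface area; `mesh_bbox_diag()` the
#' bounding-box diagonal (used as the default scale for tolerances).
#'
#' @param mesh A [triangle_mesh()].
#' @return A single number.
#' @export
mesh_area <- function(mesh) {
  stopifnot(is_triangle_mesh(mesh))
  if (nrow(mesh$faces) == 0L) return(0)
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' @rdname mesh_area
#' @export
mesh_bbox_diag <- function(mesh) {
  stopifnot(is_triangle_mesh(mesh))
  if (nrow(mesh$vertices) == 0L) return(0)
  rng <- apply(mesh$vertices, 2L, range)
  vnorm(rng[2L, ] - rng[1L, ])
}

# Sub-mesh of selected faces, with unreferenced vertices dropped.
sub_mesh <- function(mesh, face_idx) {
  f <- mesh$faces[face_idx, , drop = FALSE]
  used <- sort(unique(as.integer(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  triangle_mesh(mesh$vertices[used, , drop = FALSE],
                matrix(remap[f], ncol = 3L))
}

#' Split a mesh into connected components
#'
#' Partitions faces by shared-vertex connectivity and returns one mesh
#' per component (faces touching a common vertex belong to the same
#' component).  The union of the parts is the input mesh.
#'
#' @param mesh A [triangle_mesh()].
#' @return List of `triangle_mesh` objects, largest first.
#' @export
connected_components <- function(mesh) {
  stopifnot(is_triangle_mesh(mesh))
  if (nrow(mesh$faces) == 0L) return(list())
  f <- mesh$faces
  edges <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  comp <- igraph::components(g)$membership
  face_comp <- comp[f[, 1L]]
  parts <- lapply(split(seq_len(nrow(f)), face_comp),
                  function(idx) sub_mesh(mesh, idx))
  parts[order(-vapply(parts, function(m) nrow(m$faces), numeric(1L)))]
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces, area %.4g\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}
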