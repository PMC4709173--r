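# Synthetic triangle meshes: icosphere refinements and smooth
# star-shaped deformations of them.  These stand in for CT-reconstructed
# anatomy (skull, pelvis, tumour-bearing bone) in tests and examples;
# all are watertight single-component surfaces.

.icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

.subdivide_sphere <- function(v, f) {
  key_of <- function(a, b) if (a < b) paste0(a, "_", b) else paste0(b, "_", a)
  midpoint <- new.env(parent = emptyenv())
  nv <- nrow(v)
  vlist <- list(v)
  get_mid <- function(a, b) {
    k <- key_of(a, b)
    idx <- midpoint[[k]]
    if (!is.null(idx)) return(idx)
    m <- (v[a, ] + v[b, ]) / 2
    m <- m / vnorm(m)
    nv <<- nv + 1L
    vlist[[length(vlist) + 1L]] <<- m
    midpoint[[k]] <- nv
    nv
  }
  nf <- matrix(0L, nrow(f) * 4L, 3L)
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1L]; b <- f[i, 2L]; c3 <- f[i, 3L]
    ab <- get_mid(a, b); bc <- get_mid(b, c3); ca <- get_mid(c3, a)
    nf[(i - 1L) * 4L + 1L, ] <- c(a, ab, ca)
    nf[(i - 1L) * 4L + 2L, ] <- c(b, bc, ab)
    nf[(i - 1L) * 4L + 3L, ] <- c(c3, ca, bc)
    nf[(i - 1L) * 4L + 4L, ] <- c(ab, bc, ca)
  }
  list(vertices = do.call(rbind, vlist), faces = nf)
}

.icosphere <- function(subdiv) {
  m <- .icosahedron()
  for (i in seq_len(subdiv)) m <- .subdivide_sphere(m$vertices, m$faces)
  m
}

#' Generate a synthetic test mesh
#'
#' Deterministic watertight surfaces built from an icosphere of the
#' requested subdivision level (`20 * 4^subdiv` faces):
#' \describe{
#'   \item{SPHERE}{radius `radius` (default 1).}
#'   \item{ELLIPSOID}{semi-axes `axes` (default `c(2, 1.5, 1)`).}
#'   \item{BLOB_BUMP}{ellipsoid with a smooth Gaussian bump protruding
#'     along `bump_dir` (default `+z`), a tumour-on-bone stand-in;
#'     `bump_amp` (default 0.6) and `bump_width` (radians, default 0.4)
#'     shape the protrusion.}
#'   \item{TWO_LOBES}{dumbbell with a waist at the equator
#'     (`waist` depth, default 0.45).}
#' }
#'
#' @param kind One of `"SPHERE"`, `"ELLIPSOID"`, `"BLOB_BUMP"`,
#'   `"TWO_LOBES"`.
#' @param params Named list of kind parameters, including `subdiv`
#'   (0..6, default 3) and `center` (default origin).
#' @param seed Unused (all mesh kinds are deterministic); accepted for
#'   interface uniformity.
#' @return A [triangle_mesh()].
#' @examples
#' m <- gen_mesh("SPHERE", list(subdiv = 3))
#' nrow(m$faces)  # 20 * 4^3 = 1280
#' @export
gen_mesh <- function(kind = c("SPHERE", "ELLIPSOID", "BLOB_BUMP",
                              "TWO_LOBES"),
                     params = list(), seed = NULL) {
  kind <- match.arg(kind)
  subdiv <- params$subdiv %||% 3L
  if (subdiv < 0L || subdiv > 6L) stop("subdiv must be in 0..6")
  center <- params$center %||% c(0, 0, 0)
  base <- .icosphere(as.integer(subdiv))
  u <- base$vertices
  v <- switch(kind,
    SPHERE = u * (params$radius %||% 1),
    ELLIPSOID = u %*% diag(params$axes %||% c(2, 1.5, 1)),
    BLOB_BUMP = {
      dir <- normalize(params$bump_dir %||% c(0, 0, 1))
      amp <- params$bump_amp %||% 0.6
      width <- params$bump_width %||% 0.4
      ang <- acos(pmin(1, pmax(-1, as.numeric(u %*% dir))))
      r <- 1 + amp * exp(-(ang / width)^2)
      (u * r) %*% diag(params$axes %||% c(2, 1.5, 1))
    },
    TWO_LOBES = {
      waist <- params$waist %||% 0.45
      width <- params$waist_width %||% 0.35
      r <- 1 - waist * exp(-(u[, 3L] / width)^2)
      u * r * (params$radius %||% 1)
    })
  triangle_mesh(v + matrix(center, nrow(v), 3L, byrow = TRUE), base$faces)
}
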