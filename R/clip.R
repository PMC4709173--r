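# Scalar-field clipping of triangle meshes.  Each vertex gets the
# signed value of the implicit expression; triangles straddling the zero
# set are split by linear interpolation along their sign-crossing edges.
# Cut faces stay open (no capping), matching how clipped surgical models
# are rendered.

#' Clip a triangle mesh by an implicit expression
#'
#' Vertices with signed value below `-eps` belong to the inside part,
#' above `eps` to the outside part; vertices within the tolerance band
#' are duplicated into both.  A mixed triangle is split at points
#' interpolated on its sign-crossing edges at `t = s_a / (s_a - s_b)`,
#' giving one triangle and one quad (triangulated by its shorter
#' diagonal).  Interpolated cut vertices are shared between adjacent
#' faces of a part.  Total surface area is conserved: the two parts'
#' areas sum to the input area.
#'
#' @param mesh A [triangle_mesh()].
#' @param expr An implicit expression ([imp_leaf()] etc., or a
#'   [combine_path()] result's `expr`).
#' @param eps Non-negative ON tolerance; default `1e-9` times the mesh
#'   bounding-box diagonal.
#' @return An object of class `clip_result`: list with `inside` and
#'   `outside` meshes and `cut_vertex_count`.
#' @export
clip_mesh <- function(mesh, expr, eps = NULL) {
  stopifnot(is_triangle_mesh(mesh), is_implicit_expr(expr))
  if (nrow(mesh$faces) == 0L)
    return(structure(list(inside = mesh, outside = mesh,
                          cut_vertex_count = 0L), class = "clip_result"))
  if (is.null(eps)) eps <- 1e-9 * mesh_bbox_diag(mesh)
  s <- eval_expr(expr, mesh$vertices)
  if (!all(is.finite(s))) stop("expression evaluated to non-finite values")
  sgn <- ifelse(s < -eps, -1L, ifelse(s > eps, 1L, 0L))

  f <- mesh$faces
  fs <- matrix(sgn[f], ncol = 3L)
  has_neg <- rowSums(fs == -1L) > 0L
  has_pos <- rowSums(fs == 1L) > 0L
  mixed <- which(has_neg & has_pos)
  inside_whole <- which(!has_pos)                 # all values <= eps
  outside_whole <- which(!has_neg)                # all values >= -eps

  verts <- mesh$vertices
  svals <- s
  edge_cache <- new.env(parent = emptyenv())
  n_new <- 0L
  cut_point <- function(a, b) {
    key <- if (a < b) paste0(a, "_", b) else paste0(b, "_", a)
    idx <- edge_cache[[key]]
    if (!is.null(idx)) return(idx)
    t <- svals[a] / (svals[a] - svals[b])
    p <- verts[a, ] + t * (verts[b, ] - verts[a, ])
    verts <<- rbind(verts, p)
    svals <<- c(svals, 0)
    n_new <<- n_new + 1L
    idx <- nrow(verts)
    edge_cache[[key]] <- idx
    idx
  }

  tri_in <- vector("list", length(mixed) * 2L)
  tri_out <- vector("list", length(mixed) * 2L)
  n_in <- 0L; n_out <- 0L
  push_in <- function(tr) { n_in <<- n_in + 1L; tri_in[[n_in]] <<- tr }
  push_out <- function(tr) { n_out <<- n_out + 1L; tri_out[[n_out]] <<- tr }
  quad_split <- function(a, b, c, d) {
    # quad a-b-c-d, split by the shorter diagonal (deterministic)
    if (vnorm(verts[a, ] - verts[c, ]) <= vnorm(verts[b, ] - verts[d, ]))
      list(c(a, b, c), c(a, c, d))
    else
      list(c(a, b, d), c(b, c, d))
  }

  for (fi in mixed) {
    idx <- f[fi, ]
    sg <- fs[fi, ]
    # rotate so the pattern is canonical
    for (r in 0:2) {
      if (r > 0L) { idx <- idx[c(2L, 3L, 1L)]; sg <- sg[c(2L, 3L, 1L)] }
      if (any(sg == 0L)) { if (sg[1L] == 0L) break } else {
        if (sum(sg == -1L) == 1L) { if (sg[1L] == -1L) break }
        else { if (sg[3L] == 1L) break }
      }
    }
    if (any(sg == 0L)) {
      # one vertex on the cut, the other two on opposite sides
      x <- cut_point(idx[2L], idx[3L])
      if (sg[2L] == -1L) {
        push_in(c(idx[1L], idx[2L], x))
        push_out(c(idx[1L], x, idx[3L]))
      } else {
        push_out(c(idx[1L], idx[2L], x))
        push_in(c(idx[1L], x, idx[3L]))
      }
    } else if (sum(sg == -1L) == 1L) {
      # A negative; B, C positive
      xab <- cut_point(idx[1L], idx[2L])
      xca <- cut_point(idx[3L], idx[1L])
      push_in(c(idx[1L], xab, xca))
      for (tr in quad_split(xab, idx[2L], idx[3L], xca)) push_out(tr)
    } else {
      # A, B negative; C positive
      xbc <- cut_point(idx[2L], idx[3L])
      xca <- cut_point(idx[3L], idx[1L])
      push_out(c(xbc, idx[3L], xca))
      for (tr in quad_split(idx[1L], idx[2L], xbc, xca)) push_in(tr)
    }
  }

  collect <- function(whole_idx, tris, ntri) {
    fl <- rbind(f[whole_idx, , drop = FALSE],
                if (ntri) do.call(rbind, tris[seq_len(ntri)]))
    if (is.null(fl) || nrow(fl) == 0L)
      return(triangle_mesh(matrix(0, 0L, 3L), matrix(integer(0), 0L, 3L)))
    used <- sort(unique(as.integer(fl)))
    remap <- integer(nrow(verts))
    remap[used] <- seq_along(used)
    triangle_mesh(verts[used, , drop = FALSE], matrix(remap[fl], ncol = 3L))
  }

  structure(list(inside = collect(inside_whole, tri_in, n_in),
                 outside = collect(outside_whole, tri_out, n_out),
                 cut_vertex_count = n_new),
            class = "clip_result")
}

#' @export
print.clip_result <- function(x, ...) {
  cat(sprintf("<clip_result> inside: %d faces, outside: %d faces, %d cut vertices\n",
              nrow(x$inside$faces), nrow(x$outside$faces),
              x$cut_vertex_count))
  invisible(x)
}

#' Limit a clipping region in depth with a thickness plane
#'
#' Intersects the clipping path's implicit function with a thickness
#' plane widget so that only a slab of the model is removed instead of
#' cutting all the way through.  With `reverse = TRUE` the thickness
#' plane's normal is flipped first, which swaps the side that survives.
#'
#' @param path_expr Implicit expression of the peripheral clipping path.
#' @param thickness_widget A [plane_widget()].
#' @param reverse Logical; reverse the thickness plane.
#' @return The combined implicit expression
#'   `intersection(path_expr, thickness)`.
#' @export
apply_thickness <- function(path_expr, thickness_widget, reverse = FALSE) {
  stopifnot(is_implicit_expr(path_expr), is_plane_widget(thickness_widget))
  w <- if (isTRUE(reverse)) reverse_widget(thickness_widget) else thickness_widget
  w$id <- 0L  # thickness planes sit outside the 1..N chain numbering
  imp_intersection(path_expr, imp_leaf(w))
}

# Resolve a stage spec: either a clipping_path or
# list(path =, remove = "inside"|"outside").
.as_stage <- function(stage) {
  if (is_clipping_path(stage)) return(list(path = stage, remove = "inside"))
  if (is.list(stage) && is_clipping_path(stage$path))
    return(list(path = stage$path,
                remove = match.arg(stage$remove %||% "inside",
                                   c("inside", "outside"))))
  stop("each stage must be a clipping_path or list(path =, remove =)")
}

#' Clip a mesh by several paths in sequence
#'
#' Stage 1 clips the input mesh into a removed part and a remainder;
#' each later stage clips the previous remainder.  This mirrors the
#' sequential surgical workflow where successive path extensions carve
#' off one fragment after another.  A stage whose removal region misses
#' the current remainder yields an empty part (allowed, logged as WARN).
#'
#' @param mesh A [triangle_mesh()].
#' @param stages List of stages: each a [clipping_path()] (its inside
#'   region is removed; a path's thickness plane, if any, is applied) or
#'   `list(path =, remove = "inside"/"outside")`.
#' @param eps Optional ON tolerance forwarded to [clip_mesh()].
#' @return List of meshes: one removed part per stage, then the final
#'   remainder (names `part1..partK`, `remainder`).
#' @export
sequential_clip <- function(mesh, stages, eps = NULL) {
  stopifnot(is_triangle_mesh(mesh), length(stages) >= 1L)
  stages <- lapply(stages, .as_stage)
  out <- vector("list", length(stages) + 1L)
  remainder <- mesh
  for (si in seq_along(stages)) {
    st <- stages[[si]]
    comb <- combine_path(st$path)
    expr <- comb$expr
    if (!is.null(st$path$thickness))
      expr <- apply_thickness(expr, st$path$thickness,
                              st$path$reverse_thickness)
    res <- clip_mesh(remainder, expr, eps = eps)
    removed <- if (st$remove == "inside") res$inside else res$outside
    remainder <- if (st$remove == "inside") res$outside else res$inside
    if (nrow(removed$faces) == 0L)
      log_msg("WARN", "stage ", si, " removed nothing from the remainder")
    out[[si]] <- removed
  }
  out[[length(stages) + 1L]] <- remainder
  names(out) <- c(paste0("part", seq_along(stages)), "remainder")
  out
}
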