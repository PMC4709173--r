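# Reduction of the 3D chain to a 2D polyline on the transection plane.
# The transection plane (beta) is perpendicular to the first two widget
# planes; every widget plane cuts beta in a line, consecutive lines meet
# at the hinge vertices, and the resulting polyline (plus an extension
# ray at each end) carries all the information the recursive Boolean
# combination needs.

#' Transection frame of a clipping path
#'
#' Builds an orthonormal frame \{u, v, n_beta\} for the transection
#' plane: `n_beta` is the normalized cross product of the first two
#' widget normals (so beta is perpendicular to both widget planes) and
#' the origin lies on the hinge line shared by those planes.
#'
#' @param path A [clipping_path()] with at least 2 widgets.
#' @return An object of class `transection_frame` with fields `origin`,
#'   `u`, `v`, `n_beta`.
#' @export
transection_frame <- function(path) {
  stopifnot(is_clipping_path(path))
  if (path_n_widgets(path) < 2L)
    stop(degenerate_path_error("transection needs at least 2 widgets"))
  w1 <- path$widgets[[1L]]
  w2 <- path$widgets[[2L]]
  nb <- cross3(w1$normal, w2$normal)
  if (vnorm(nb) <= 1e-6)
    stop(degenerate_path_error(
      "first two widget planes are (near-)parallel; no transection plane"))
  nb <- normalize(nb)
  # point on the hinge line of widgets 1 and 2
  A <- rbind(w1$normal, w2$normal, nb)
  b <- c(sum(w1$normal * w1$center), sum(w2$normal * w2$center), 0)
  origin <- as.numeric(solve(A, b))
  u <- normalize(cross3(w1$normal, nb))  # direction of widget 1's trace line
  v <- cross3(nb, u)
  structure(list(origin = origin, u = u, v = v, n_beta = nb),
            class = "transection_frame")
}

#' Convert between 3D model coordinates and 2D frame coordinates
#'
#' `frame_to_2d()` projects 3D points into the (u, v) coordinates of a
#' transection frame; `frame_to_3d()` lifts 2D frame coordinates back
#' onto the transection plane.
#'
#' @param frame A [transection_frame()].
#' @param points n x 3 matrix (or length-3 point) for `frame_to_2d()`;
#'   n x 2 matrix (or length-2 point) for `frame_to_3d()`.
#' @return n x 2 (resp. n x 3) coordinate matrix.
#' @export
frame_to_2d <- function(frame, points) {
  p <- as_point_matrix(points)
  d <- p - matrix(frame$origin, nrow(p), 3L, byrow = TRUE)
  cbind(as.numeric(d %*% frame$u), as.numeric(d %*% frame$v))
}

#' @rdname frame_to_2d
#' @export
frame_to_3d <- function(frame, points2d) {
  p <- matrix(as.numeric(points2d), ncol = 2L)
  matrix(frame$origin, nrow(p), 3L, byrow = TRUE) +
    p[, 1L] %o% frame$u + p[, 2L] %o% frame$v
}

# 2D trace line of one widget plane on beta: list(point, dir), both 2D.
.widget_trace <- function(widget, frame) {
  align <- abs(sum(widget$normal * frame$n_beta))
  if (align >= 1 - 1e-9)
    stop(transection_error(sprintf(
      "widget %d is parallel to the transection plane", widget$id)))
  d3 <- normalize(cross3(widget$normal, frame$n_beta))
  A <- rbind(widget$normal, frame$n_beta, d3)
  b <- c(sum(widget$normal * widget$center),
         sum(frame$n_beta * frame$origin),
         sum(d3 * frame$origin))
  p3 <- as.numeric(solve(A, b))
  list(point = as.numeric(frame_to_2d(frame, p3)),
       dir = c(sum(d3 * frame$u), sum(d3 * frame$v)))
}

.intersect_lines2d <- function(l1, l2, tol) {
  den <- cross2(l1$dir, l2$dir)
  if (abs(den) <= tol)
    stop(degenerate_path_error("consecutive trace lines are parallel on beta"))
  t <- cross2(l2$point - l1$point, l2$dir) / den
  l1$point + t * l1$dir
}

# Endpoint of the open chain on the first/last trace line.  With quad
# corners, the widget boundary is authoritative: take the intersection
# points of the quad edges with beta and keep the one farthest from the
# hinge vertex.  Without corners, step a bounding-box diagonal from the
# hinge on the side opposite the adjacent interior vertex (only the side
# matters downstream: the chain segment plus its extension ray form a
# half-line).
.chain_endpoint <- function(widget, trace, hinge2d, ref2d, frame, diameter) {
  if (!is.null(widget$corners)) {
    co <- widget$corners
    edges <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L))
    pts <- NULL
    for (r in seq_len(4L)) {
      p <- co[edges[r, 1L], ]
      q <- co[edges[r, 2L], ]
      fp <- sum(frame$n_beta * (p - frame$origin))
      fq <- sum(frame$n_beta * (q - frame$origin))
      if ((fp <= 0 && fq >= 0) || (fp >= 0 && fq <= 0)) {
        if (abs(fp - fq) > .Machine$double.eps) {
          t <- fp / (fp - fq)
          pts <- rbind(pts, p + t * (q - p))
        }
      }
    }
    if (!is.null(pts) && nrow(pts) > 0L) {
      pts2 <- frame_to_2d(frame, pts)
      d <- sqrt(rowSums((pts2 - matrix(hinge2d, nrow(pts2), 2L,
                                       byrow = TRUE))^2))
      return(as.numeric(pts2[which.max(d), ]))
    }
  }
  w <- trace$dir / vnorm(trace$dir)
  if (sum(w * (ref2d - hinge2d)) > 0) w <- -w
  hinge2d + diameter * w
}

#' Transect a clipping path into its 2D polyline
#'
#' Computes the trace line of every widget plane on the transection
#' plane, the hinge vertices where consecutive traces meet, the two
#' open-chain endpoints, the unit extension-ray directions beyond each
#' endpoint, and the per-segment 2D inside directions (projection of the
#' negated widget normal into beta).  For a closed path the first and
#' last point coincide on the hinge shared by the last and first
#' widgets.
#'
#' @param path A [clipping_path()].
#' @param frame A [transection_frame()]; required for single-widget
#'   paths, otherwise defaults to `transection_frame(path)`.
#' @return An object of class `transection_polyline` with fields
#'   `points` ((N+1) x 2), `head_ray_dir`, `tail_ray_dir`,
#'   `inside_dirs` (N x 2), `scale`, `closed`.
#' @export
transect <- function(path, frame = NULL) {
  stopifnot(is_clipping_path(path))
  n <- path_n_widgets(path)
  if (is.null(frame)) frame <- transection_frame(path)
  traces <- lapply(path$widgets, .widget_trace, frame = frame)

  inside <- t(vapply(seq_len(n), function(i) {
    m <- -path$widgets[[i]]$normal
    q <- c(sum(m * frame$u), sum(m * frame$v))
    q / vnorm(q)
  }, numeric(2L)))

  if (n == 1L) {
    c2 <- as.numeric(frame_to_2d(frame, path$widgets[[1L]]$center))
    d <- traces[[1L]]$dir
    pts <- rbind(c2 - d, c2 + d)
    return(structure(list(points = pts, head_ray_dir = -d, tail_ray_dir = d,
                          inside_dirs = inside,
                          scale = max(vnorm(pts[2L, ] - pts[1L, ]), 1),
                          closed = FALSE),
                     class = "transection_polyline"))
  }

  hinge_tol <- 1e-9
  hinges <- matrix(0, n - 1L, 2L)   # interior vertices P_2..P_N
  for (i in seq_len(n - 1L))
    hinges[i, ] <- .intersect_lines2d(traces[[i]], traces[[i + 1L]], hinge_tol)
  diam <- if (n > 2L) {
    rng <- apply(hinges, 2L, range)
    max(vnorm(rng[2L, ] - rng[1L, ]), max(dist(hinges)))
  } else 0
  centers2d <- frame_to_2d(frame, t(vapply(path$widgets, `[[`, numeric(3L),
                                           "center")))
  diam <- max(diam, max(dist(rbind(hinges, centers2d))), 1e-6)

  pts <- matrix(0, n + 1L, 2L)
  pts[2:n, ] <- hinges
  if (path$closed && n > 2L) {
    wrap <- .intersect_lines2d(traces[[n]], traces[[1L]], hinge_tol)
    pts[1L, ] <- wrap
    pts[n + 1L, ] <- wrap
  } else {
    ref_head <- if (n >= 3L) pts[3L, ] else centers2d[2L, ]
    ref_tail <- if (n >= 3L) pts[n - 1L, ] else centers2d[1L, ]
    pts[1L, ] <- .chain_endpoint(path$widgets[[1L]], traces[[1L]],
                                 pts[2L, ], ref_head, frame, diam)
    pts[n + 1L, ] <- .chain_endpoint(path$widgets[[n]], traces[[n]],
                                     pts[n, ], ref_tail, frame, diam)
  }

  seg <- diff(pts)
  seglen <- sqrt(rowSums(seg^2))
  scale <- {
    rng <- apply(pts, 2L, range)
    max(vnorm(rng[2L, ] - rng[1L, ]), 1e-12)
  }
  if (any(seglen <= 1e-9 * scale))
    stop(degenerate_path_error("degenerate polyline: consecutive points coincide"))

  structure(list(points = pts,
                 head_ray_dir = (pts[1L, ] - pts[2L, ]) / seglen[1L],
                 tail_ray_dir = (pts[n + 1L, ] - pts[n, ]) / seglen[n],
                 inside_dirs = inside, scale = scale, closed = path$closed),
            class = "transection_polyline")
}

#' Orient widget normals consistently along the polyline
#'
#' The recursive combination requires every widget's inside region to
#' lie on the same side of the transection polyline (all normal-handle
#' initial points on one side, endpoints on the other).  Because each
#' inside direction is exactly perpendicular to its polyline segment,
#' side consistency reduces to traversal handedness: the sign of
#' `cross(segment_dir, inside_dir)` must be equal for all widgets.
#' Widgets disagreeing with widget 1 are flipped.  Self-intersecting
#' polylines, whose sides are ill-defined, are rejected.
#'
#' @param path A [clipping_path()].
#' @param polyline The matching [transect()] result.
#' @return The re-oriented `clipping_path`, with an integer attribute
#'   `"flipped"` listing the indices of reversed widgets.
#' @export
orient_normals <- function(path, polyline) {
  stopifnot(is_clipping_path(path), inherits(polyline, "transection_polyline"))
  n <- path_n_widgets(path)
  if (n == 1L) {
    attr(path, "flipped") <- integer(0)
    return(path)
  }
  if (.polyline_self_intersects(polyline))
    stop(orientation_error(
      "polyline self-intersects; polyline sides are ill-defined"))
  pts <- polyline$points
  hand <- vapply(seq_len(n), function(i) {
    d <- pts[i + 1L, ] - pts[i, ]
    sign(cross2(d, polyline$inside_dirs[i, ]))
  }, numeric(1L))
  if (any(hand == 0))
    stop(orientation_error("inside direction parallel to its segment"))
  flip <- which(hand != hand[1L])
  for (i in flip) path$widgets[[i]] <- reverse_widget(path$widgets[[i]])
  attr(path, "flipped") <- flip
  path
}

.polyline_self_intersects <- function(polyline) {
  pts <- polyline$points
  m <- nrow(pts) - 1L
  if (m < 3L && !polyline$closed) return(FALSE)
  tol <- 1e-9 * polyline$scale
  for (i in seq_len(m - 2L)) {
    for (j in (i + 2L):m) {
      if (polyline$closed && i == 1L && j == m) next  # wrap adjacency
      if (.segments_cross(pts[i, ], pts[i + 1L, ], pts[j, ], pts[j + 1L, ],
                          tol))
        return(TRUE)
    }
  }
  FALSE
}

.segments_cross <- function(a, b, p, q, tol) {
  d1 <- b - a
  d2 <- q - p
  den <- cross2(d1, d2)
  if (abs(den) <= tol * max(vnorm(d1), vnorm(d2))) {
    if (abs(cross2(d1, p - a)) > tol * vnorm(d1)) return(FALSE)
    t1 <- sum((p - a) * d1) / sum(d1 * d1)
    t2 <- sum((q - a) * d1) / sum(d1 * d1)
    lo <- max(min(t1, t2), 0)
    hi <- min(max(t1, t2), 1)
    return(hi - lo > tol)
  }
  t <- cross2(p - a, d2) / den
  s <- cross2(p - a, d1) / den
  t > tol && t < 1 - tol && s > tol && s < 1 - tol
}
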