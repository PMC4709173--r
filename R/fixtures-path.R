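# Synthetic clipping paths.  Every path is designed as a 2D polyline
# (the intended transection polyline) and lifted to 3D plane widgets;
# the widget quads span exactly the designed segments, so transection
# reproduces the design.  Coordinates are free: what each fixture pins
# down is the intersection topology of the polyline — which loop
# conditions fire during combination — not any particular figure.

#' Lift a 2D polyline to a clipping path of plane widgets
#'
#' Segment `i` of the polyline becomes widget `i`: a planar quad
#' containing the segment, extruded `height` on both sides, optionally
#' tilted about its own trace line.  The widget normal points away from
#' the requested inside side of the polyline.  An optional rigid pose
#' (rotation + translation) places the design plane in 3D; with the
#' identity pose the polyline lies in the z = 0 plane.
#'
#' @param points2d (N+1) x 2 matrix of polyline vertices (first equals
#'   last when `closed`).
#' @param inside `"left"` or `"right"`: which side of the travel
#'   direction is the inside region.
#' @param closed Logical; enclosure path (first and last vertex must
#'   coincide).
#' @param height Quad half-height in the extrusion direction.
#' @param tilts Optional numeric vector (radians, length N): rotation of
#'   each widget plane about its trace line (0 = perpendicular to the
#'   design plane).  The trace, and hence the polyline, is unchanged.
#' @param rotation Optional 3 x 3 rotation matrix (pose).
#' @param translation Optional length-3 offset (pose).
#' @param corners Logical; attach quad corners (default `TRUE`).
#' @return A [clipping_path()].
#' @export
polyline_to_path <- function(points2d, inside = c("left", "right"),
                             closed = FALSE, height = 2, tilts = NULL,
                             rotation = NULL, translation = NULL,
                             corners = TRUE) {
  inside <- match.arg(inside)
  pts <- matrix(as.numeric(points2d), ncol = 2L)
  n <- nrow(pts) - 1L
  if (n < 1L) stop("need at least 2 polyline points")
  if (closed && vnorm(pts[1L, ] - pts[n + 1L, ]) > 1e-9)
    stop("closed polyline must end where it starts")
  if (is.null(tilts)) tilts <- rep(0, n)
  stopifnot(length(tilts) == n)
  R <- rotation %||% diag(3)
  tr <- translation %||% c(0, 0, 0)
  lift <- function(p2, z = 0) as.numeric(R %*% c(p2, z) + tr)

  widgets <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pts[i, ]; q <- pts[i + 1L, ]
    d2 <- (q - p) / vnorm(q - p)
    left2 <- c(-d2[2L], d2[1L])
    inside2 <- if (inside == "left") left2 else -left2
    n0 <- c(-inside2, 0)                      # outward, in design plane
    d3 <- c(d2, 0)
    tn <- n0 * cos(tilts[i]) + cross3(d3, n0) * sin(tilts[i])
    m <- normalize(cross3(tn, d3))            # in-plane, crosses design plane
    p3 <- lift(p); q3 <- lift(q)
    mid <- (p3 + q3) / 2
    m3 <- as.numeric(R %*% m)
    co <- if (corners)
      rbind(p3 - height * m3, q3 - height * m3,
            q3 + height * m3, p3 + height * m3)
    widgets[[i]] <- plane_widget(center = mid,
                                 normal = as.numeric(R %*% tn),
                                 corners = co, id = i)
  }
  clipping_path(widgets, closed = closed)
}

# Inward logarithmic-spiral polyline: constant turn angle, geometric
# length decay.  Every later segment's line re-crosses the leading
# chain, so the combination loop runs its maximum j - i - 1 times in
# every composite call (the quadratic-cost regime).
.spiral_points <- function(n, turn_deg = 100, ratio = 0.8,
                           last_turn_deg = NULL) {
  dirs <- (seq_len(n) - 1L) * turn_deg
  if (!is.null(last_turn_deg) && n >= 2L)
    dirs[n] <- dirs[n - 1L] + last_turn_deg
  th <- dirs * pi / 180
  lens <- ratio^(seq_len(n) - 1L)
  steps <- cbind(lens * cos(th), lens * sin(th))
  rbind(c(0, 0), apply(steps, 2L, cumsum))
}

.arc_points <- function(n, radius = 10, span_deg = 150) {
  th <- seq(-span_deg / 2, span_deg / 2, length.out = n + 1L) * pi / 180
  radius * cbind(cos(th), sin(th))
}

.ring_points <- function(n, radius = 0.6, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)
  cbind(center[1L] + radius * cos(th), center[2L] + radius * sin(th))
}

# V-shaped two-widget wedge whose inside is the dihedral region beyond
# offset `c0` along `axis`; used by the COMPLEX4 stages.
.wedge_stage <- function(axis, c0, tilt_deg = 15, arm = 1.5, height = 2.5) {
  axis <- normalize(axis)
  w <- if (abs(axis[1L]) < 0.9) normalize(cross3(axis, c(1, 0, 0))) else
    normalize(cross3(axis, c(0, 1, 0)))
  v <- cross3(w, axis)
  Rm <- cbind(w, axis, v)           # design x -> w, y -> axis, z -> v
  tphi <- tan(tilt_deg * pi / 180)
  pts <- rbind(c(-arm, arm * tphi + c0), c(0, c0), c(arm, arm * tphi + c0))
  polyline_to_path(pts, inside = "left", height = height, rotation = Rm)
}

#' Generate a synthetic clipping path
#'
#' Path families with pinned combination topology:
#' \describe{
#'   \item{CONVEX}{`n` widgets along a circular arc (convex position);
#'     the combination loop never fires and the instrumented cost is
#'     `2n - 3`.  `params$inside = "concave"` (default) yields the
#'     all-intersection chain, `"convex"` the all-union chain.}
#'   \item{STAIRCASE_WORST}{inward spiral; the loop runs its maximum
#'     number of iterations in every composite call and the cost is
#'     `(n+3)(n-2)/2 + 1`.}
#'   \item{EXAMPLE1}{4-widget spiral whose last segment turns back
#'     across the chain; combines to `a1 U (a2 U (a3 ^ a4))`.}
#'   \item{EXAMPLE2}{4-widget variant whose last line misses the inner
#'     sub-chain; combines to `a1 U ((a2 U a3) ^ a4)`.}
#'   \item{EXAMPLE3}{4-widget variant reaching the same expression as
#'     EXAMPLE2 through the ray loop condition instead of the line
#'     condition.}
#'   \item{ENCLOSURE}{closed regular `n`-gon ring (default `n = 29`)
#'     of radius `params$radius` around `params$center`, widgets
#'     parallel to `params$axis` (default z); inside is the enclosed
#'     prism.  `params$thickness_offset` attaches a thickness plane
#'     perpendicular to the axis at that offset (inside on the +axis
#'     side).}
#'   \item{COMPLEX4}{returns a list of three 2-widget wedge stages
#'     whose removal regions are disjoint caps (default axes +z, +x,
#'     -y at offset `params$offset`, default 0.75); clipping a sphere
#'     with them in sequence yields four parts.}
#' }
#'
#' @param kind Fixture family name (see above).
#' @param params Named list of parameters (`n`, `radius`, ...).
#' @param seed Unused for these deterministic families; accepted for
#'   interface uniformity.
#' @return A [clipping_path()], or a list of stages for `COMPLEX4`.
#' @examples
#' expr_to_string(combine_path(gen_path("EXAMPLE1"))$expr)
#' @export
gen_path <- function(kind = c("CONVEX", "STAIRCASE_WORST", "EXAMPLE1",
                              "EXAMPLE2", "EXAMPLE3", "ENCLOSURE",
                              "COMPLEX4"),
                     params = list(), seed = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    CONVEX = {
      n <- params$n %||% 4L
      stopifnot(n >= 2L)
      side <- if ((params$inside %||% "concave") == "concave") "left"
      else "right"
      polyline_to_path(.arc_points(n, params$radius %||% 10,
                                   params$span_deg %||% 150),
                       inside = side, height = params$height %||% 25)
    },
    STAIRCASE_WORST = {
      n <- params$n %||% 4L
      stopifnot(n >= 2L)
      polyline_to_path(.spiral_points(n), inside = "right",
                       height = params$height %||% 3)
    },
    EXAMPLE1 = polyline_to_path(
      .spiral_points(4L, last_turn_deg = -80), inside = "right", height = 3),
    EXAMPLE2 = {
      pts <- .spiral_points(3L)
      p5 <- pts[4L, ] + 0.64 * c(cos(95 * pi / 180), sin(95 * pi / 180))
      polyline_to_path(rbind(pts, p5), inside = "right", height = 3)
    },
    EXAMPLE3 = {
      deg <- pi / 180
      p1 <- c(0, 0); p2 <- c(1, 0)
      p3 <- p2 + 0.8 * c(cos(80 * deg), sin(80 * deg))
      p4 <- p3 + 0.7 * c(cos(150 * deg), sin(150 * deg))
      p5 <- p4 + 0.8 * c(cos(20 * deg), sin(20 * deg))
      polyline_to_path(rbind(p1, p2, p3, p4, p5), inside = "right",
                       height = 3)
    },
    ENCLOSURE = {
      n <- params$n %||% 29L
      stopifnot(n >= 3L)
      center <- params$center %||% c(0, 0)
      path <- polyline_to_path(
        .ring_points(n, params$radius %||% 0.6, center),
        inside = "left", closed = TRUE, height = params$height %||% 3)
      if (!is.null(params$thickness_offset)) {
        off <- params$thickness_offset
        path$thickness <- plane_widget(center = c(center[1L], center[2L], off),
                                       normal = c(0, 0, -1), id = 0L)
      }
      path
    },
    COMPLEX4 = {
      off <- params$offset %||% 0.75
      tilt <- params$tilt_deg %||% 15
      axes <- params$axes %||% list(c(0, 0, 1), c(1, 0, 0), c(0, -1, 0))
      lapply(axes, .wedge_stage, c0 = off, tilt_deg = tilt)
    })
}

#' Generate a random valid open chain
#'
#' Rejection-samples an open polyline with turn angles uniform in
#' (-150, 150) degrees (at least 5 degrees in magnitude, so
#' consecutive planes are never parallel) and segment lengths uniform
#' in (0.5, 1.5), then lifts it to widgets with random per-widget
#' tilts, a random rigid pose, a random inside side, and each widget's
#' normal randomly flipped (exercising [orient_normals()]).  Because
#' tilted widgets change the transection plane, the candidate is
#' re-transected and kept only if the actual transection polyline is
#' itself well-behaved: non-self-intersecting including its extension
#' rays, turn angles within (-150, 150) degrees, and no near-degenerate
#' segment.  Deterministic per `(n, seed)`.
#'
#' @param n Number of widgets (>= 2).
#' @param seed Integer seed; RNG state is restored on exit.
#' @param max_tries Rejection limit.
#' @return A [clipping_path()].
#' @export
gen_random_chain <- function(n, seed = NULL, max_tries = 1000L) {
  stopifnot(n >= 2L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
  }
  for (try in seq_len(max_tries)) {
    turns <- runif(n - 1L, -150, 150)
    turns <- ifelse(abs(turns) < 5, sign(turns + (turns == 0)) * 5, turns)
    th <- cumsum(c(runif(1L, 0, 360), turns)) * pi / 180
    lens <- runif(n, 0.5, 1.5)
    pts <- rbind(c(0, 0), apply(cbind(lens * cos(th), lens * sin(th)),
                                2L, cumsum))
    tilts <- runif(n, -35, 35) * pi / 180
    ang <- runif(3L, 0, 2 * pi)
    side <- sample(c("left", "right"), 1L)
    flip_mask <- runif(n) < 0.5
    shift <- runif(3L, -5, 5)
    if (!.chain_extensions_simple(pts)) next
    Rz <- matrix(c(cos(ang[1L]), -sin(ang[1L]), 0,
                   sin(ang[1L]), cos(ang[1L]), 0, 0, 0, 1), 3L,
                 byrow = TRUE)
    Ry <- matrix(c(cos(ang[2L]), 0, sin(ang[2L]), 0, 1, 0,
                   -sin(ang[2L]), 0, cos(ang[2L])), 3L, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cos(ang[3L]), -sin(ang[3L]),
                   0, sin(ang[3L]), cos(ang[3L])), 3L, byrow = TRUE)
    path <- polyline_to_path(pts, inside = side, tilts = tilts,
                             rotation = Rz %*% Ry %*% Rx,
                             translation = shift, height = 4)
    for (i in which(flip_mask))
      path$widgets[[i]] <- reverse_widget(path$widgets[[i]])
    if (.transected_chain_ok(path)) return(path)
  }
  stop("gen_random_chain: rejection limit exceeded")
}

# Accept a candidate only if its actual transection polyline is simple
# (with extensions), has turns in (-150, 150) degrees away from zero,
# and no tiny segment.
.transected_chain_ok <- function(path) {
  poly <- tryCatch(transect(path), error = function(e) NULL)
  if (is.null(poly)) return(FALSE)
  pts <- poly$points
  seg <- diff(pts)
  seglen <- sqrt(rowSums(seg^2))
  if (any(seglen < 0.02 * poly$scale)) return(FALSE)
  dirs <- seg / seglen
  m <- nrow(dirs)
  if (m >= 2L) {
    for (i in seq_len(m - 1L)) {
      ca <- sum(dirs[i, ] * dirs[i + 1L, ])
      turn <- atan2(cross2(dirs[i, ], dirs[i + 1L, ]), ca) * 180 / pi
      if (abs(turn) >= 150 || abs(turn) <= 4) return(FALSE)
    }
  }
  if (!.chain_extensions_simple(pts)) return(FALSE)
  ok <- tryCatch({ orient_normals(path, poly); TRUE },
                 error = function(e) FALSE)
  ok
}

# Simplicity of the extended polyline: no two non-adjacent segments
# cross, and neither end ray (truncated far beyond the chain) re-crosses
# any non-adjacent segment.
.chain_extensions_simple <- function(pts) {
  m <- nrow(pts) - 1L
  rng <- apply(pts, 2L, range)
  diag_len <- max(vnorm(rng[2L, ] - rng[1L, ]), 1)
  tol <- 1e-7 * diag_len
  seg_list <- lapply(seq_len(m), function(i)
    list(p = pts[i, ], q = pts[i + 1L, ]))
  head_end <- pts[1L, ] + 100 * diag_len *
    (pts[1L, ] - pts[2L, ]) / vnorm(pts[1L, ] - pts[2L, ])
  tail_end <- pts[m + 1L, ] + 100 * diag_len *
    (pts[m + 1L, ] - pts[m, ]) / vnorm(pts[m + 1L, ] - pts[m, ])
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j > i + 1L &&
          .segments_cross(seg_list[[i]]$p, seg_list[[i]]$q,
                          seg_list[[j]]$p, seg_list[[j]]$q, tol))
        return(FALSE)
    }
    if (i > 1L && .segments_cross(pts[1L, ], head_end,
                                  seg_list[[i]]$p, seg_list[[i]]$q, tol))
      return(FALSE)
    if (i < m && .segments_cross(pts[m + 1L, ], tail_end,
                                 seg_list[[i]]$p, seg_list[[i]]$q, tol))
      return(FALSE)
  }
  # the two rays themselves
  if (m >= 2L && .segments_cross(pts[1L, ], head_end, pts[m + 1L, ],
                                 tail_end, tol))
    return(FALSE)
  TRUE
}
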