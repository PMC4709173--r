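# Independent geometric oracles, kept deliberately separate from the
# package's code paths.

# Parity of crossings along the straight segment from point `a` to
# point `b` against the extended transection polyline (end rays
# truncated far beyond the sampling region).  Two points are on the
# same side of the extended polyline iff the crossing count is even.
oracle_crossings <- function(poly, a, b) {
  pts <- poly$points
  m <- nrow(pts) - 1L
  far <- 1000 * poly$scale
  segs <- lapply(seq_len(m), function(i) rbind(pts[i, ], pts[i + 1L, ]))
  if (!poly$closed) {
    segs <- c(list(rbind(pts[1L, ] + far * poly$head_ray_dir, pts[1L, ])),
              segs,
              list(rbind(pts[m + 1L, ], pts[m + 1L, ] +
                           far * poly$tail_ray_dir)))
  }
  d1 <- b - a
  cr <- 0L
  for (s in segs) {
    p <- s[1L, ]
    d2 <- s[2L, ] - s[1L, ]
    den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
    if (abs(den) < 1e-14) next
    t <- ((p[1L] - a[1L]) * d2[2L] - (p[2L] - a[2L]) * d2[1L]) / den
    u <- ((p[1L] - a[1L]) * d1[2L] - (p[2L] - a[2L]) * d1[1L]) / den
    if (t > 0 && t < 1 && u > 0 && u < 1) cr <- cr + 1L
  }
  cr
}

# Inside-witness of the first widget on the oriented polyline.
oracle_witness <- function(poly) {
  (poly$points[1L, ] + poly$points[2L, ]) / 2 +
    1e-3 * poly$scale * poly$inside_dirs[1L, ]
}

# TRUE for points (2D, on the transection plane) on the inside side of
# the extended polyline.
oracle_inside <- function(poly, pts2) {
  w <- oracle_witness(poly)
  vapply(seq_len(nrow(pts2)), function(i)
    oracle_crossings(poly, pts2[i, ], w) %% 2L == 0L, TRUE)
}

# Brute-force expression evaluator: collect leaf values, then fold
# min/max following the tree shape (no pmin/pmax, scalar recursion).
oracle_eval <- function(expr, point) {
  if (expr$op == "plane")
    return(sum(expr$widget$normal * (point - expr$widget$center)))
  l <- oracle_eval(expr$left, point)
  r <- oracle_eval(expr$right, point)
  if (expr$op == "union") min(l, r) else max(l, r)
}

# Brute-force segment-segment intersection via orientation tests
# (inclusive of endpoint contact), for checking the package predicate.
oracle_segs_intersect <- function(p1, p2, q1, q2) {
  o <- function(a, b, c)
    sign((b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L]))
  on_seg <- function(a, b, c)
    min(a[1L], b[1L]) <= c[1L] && c[1L] <= max(a[1L], b[1L]) &&
      min(a[2L], b[2L]) <= c[2L] && c[2L] <= max(a[2L], b[2L])
  o1 <- o(p1, p2, q1); o2 <- o(p1, p2, q2)
  o3 <- o(q1, q2, p1); o4 <- o(q1, q2, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && on_seg(p1, p2, q1)) || (o2 == 0 && on_seg(p1, p2, q2)) ||
    (o3 == 0 && on_seg(q1, q2, p1)) || (o4 == 0 && on_seg(q1, q2, p2))
}

# Uniform random sample points around a polyline's bounding box.
sample_box_points <- function(poly, n, seed, margin = 0.5) {
  set.seed(seed)
  rngx <- range(poly$points[, 1L])
  rngy <- range(poly$points[, 2L])
  mx <- margin * max(diff(rngx), diff(rngy), 1)
  cbind(runif(n, rngx[1L] - mx, rngx[2L] + mx),
        runif(n, rngy[1L] - mx, rngy[2L] + mx))
}

# Agreement of the combined expression's sign with the 2D side oracle
# for one path; returns c(checked, agreed).
oracle_agreement <- function(path, npts, seed) {
  comb <- combine_path(path)
  poly <- comb$polyline
  pts2 <- sample_box_points(poly, npts, seed)
  pts3 <- frame_to_3d(comb$frame, pts2)
  v <- eval_expr(comb$expr, pts3)
  eps <- 1e-9 * (1 + sqrt(rowSums(pts3^2)))
  keep <- abs(v) > 10 * eps
  inside_pred <- oracle_inside(poly, pts2[keep, , drop = FALSE])
  c(checked = sum(keep), agreed = sum((v[keep] < 0) == inside_pred))
}

vertex_key <- function(m) {
  k <- apply(m, 1L, function(r) paste(sprintf("%.12g", r), collapse = "_"))
  sort(unname(k))
}
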