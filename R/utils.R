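# Small numeric helpers shared across modules.

vnorm <- function(x) sqrt(sum(x * x))

normalize <- function(x) {
  n <- vnorm(x)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  x / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# z-component of the 2D cross product; sign gives the turn handedness
cross2 <- function(a, b) a[1L] * b[2L] - a[2L] * b[1L]

as_point_matrix <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 3L)
      stop("a point must have exactly 3 coordinates")
    points <- matrix(points, nrow = 1L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop("points must be an n x 3 matrix")
  if (!all(is.finite(points)))
    stop("non-finite point coordinates")
  storage.mode(points) <- "double"
  points
}

`%||%` <- function(a, b) if (is.null(a)) b else a
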