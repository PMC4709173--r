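# Plane widgets: bounded planar quads with an oriented unit normal.  The
# normal points from the inside region toward the outside region, so the
# signed value dot(normal, p - center) is negative on the inside.

#' Create a plane widget
#'
#' A plane widget is one facet of a clipping path: a plane through
#' `center` with unit `normal`, optionally bounded by a quadrilateral.
#' Its signed implicit value at a point `p` is `dot(normal, p - center)`:
#' negative inside, zero on the plane, positive outside.  The normal is
#' the orientation handle and points from the inside region toward the
#' outside region.
#'
#' @param center Numeric length-3 point on the plane (model units,
#'   typically mm).
#' @param normal Numeric length-3 direction; normalized internally, must
#'   be non-zero.
#' @param corners Optional 4 x 3 matrix of coplanar points bounding the
#'   widget quad.
#' @param id Integer index of the widget within its path (1-based).
#' @return An object of class `plane_widget`.
#' @examples
#' w <- plane_widget(c(0, 0, 0), c(0, 0, 1))
#' plane_value(w, c(0, 0, 3))   # +3, outside
#' @export
plane_widget <- function(center, normal, corners = NULL, id = 1L) {
  center <- as.numeric(center)
  normal <- as.numeric(normal)
  if (length(center) != 3L || !all(is.finite(center)))
    stop("widget center must be a finite 3D point")
  if (length(normal) != 3L || !all(is.finite(normal)))
    stop("widget normal must be a finite 3D vector")
  nn <- vnorm(normal)
  if (nn < 1e-12) stop("widget normal must be non-zero")
  normal <- normal / nn
  if (!is.null(corners)) {
    corners <- as.matrix(corners)
    if (!all(dim(corners) == c(4L, 3L)) || !all(is.finite(corners)))
      stop("corners must be a finite 4 x 3 matrix")
    d <- abs(as.numeric((corners - matrix(center, 4L, 3L, byrow = TRUE)) %*% normal))
    diag_len <- max(vnorm(corners[1L, ] - corners[3L, ]),
                    vnorm(corners[2L, ] - corners[4L, ]), 1)
    if (any(d > 1e-6 * diag_len))
      stop("corners do not lie on the widget plane")
  }
  structure(list(center = center, normal = normal, corners = corners,
                 id = as.integer(id)),
            class = "plane_widget")
}

is_plane_widget <- function(x) inherits(x, "plane_widget")

#' Signed plane value of points
#'
#' Evaluates the widget's implicit function `dot(normal, p - center)` at
#' one point or a matrix of points.  Negative values are inside (the side
#' the normal handle's initial point sits on), positive outside.
#'
#' @param widget A [plane_widget()].
#' @param points Length-3 point or n x 3 matrix.
#' @return Numeric vector of signed values.
#' @export
plane_value <- function(widget, points) {
  stopifnot(is_plane_widget(widget))
  p <- as_point_matrix(points)
  as.numeric((p - matrix(widget$center, nrow(p), 3L, byrow = TRUE)) %*% widget$normal)
}

#' Reverse a widget's orientation
#'
#' Returns a copy with the normal negated; every signed value flips sign,
#' so inside and outside swap.  Reversing twice restores the original.
#'
#' @param widget A [plane_widget()].
#' @return A `plane_widget` with negated normal.
#' @export
reverse_widget <- function(widget) {
  stopifnot(is_plane_widget(widget))
  widget$normal <- -widget$normal
  widget
}

#' @export
print.plane_widget <- function(x, ...) {
  cat(sprintf("<plane_widget a%d> center=(%s) normal=(%s)%s\n", x$id,
              paste(signif(x$center, 6), collapse = ", "),
              paste(signif(x$normal, 6), collapse = ", "),
              if (is.null(x$corners)) "" else " +corners"))
  invisible(x)
}
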