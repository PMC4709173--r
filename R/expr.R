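# Implicit expression trees.  Leaves are plane widgets; internal nodes
# combine children by Boolean union (pointwise minimum of the signed
# values) or Boolean intersection (pointwise maximum).  The result of
# either operation is again an implicit function, so trees compose.

#' Implicit expression constructors
#'
#' `imp_leaf()` wraps a single plane widget.  `imp_union()` and
#' `imp_intersection()` combine two sub-expressions: union takes the
#' pointwise minimum of the operand values (the inside regions merge),
#' intersection the pointwise maximum (only the common inside survives).
#'
#' @param widget A [plane_widget()].
#' @param left,right Implicit expressions.
#' @return An object of class `implicit_expr`.
#' @examples
#' a <- imp_leaf(plane_widget(c(0, 0, 0),  c(0, 0, 1), id = 1))
#' b <- imp_leaf(plane_widget(c(0, 0, -1), c(0, 0, 1), id = 2))
#' eval_expr(imp_union(a, b), c(0, 0, -0.5))        # min(-0.5, 0.5)
#' eval_expr(imp_intersection(a, b), c(0, 0, -0.5)) # max(-0.5, 0.5)
#' @export
imp_leaf <- function(widget) {
  stopifnot(is_plane_widget(widget))
  structure(list(op = "plane", widget = widget), class = "implicit_expr")
}

#' @rdname imp_leaf
#' @export
imp_union <- function(left, right) .imp_node("union", left, right)

#' @rdname imp_leaf
#' @export
imp_intersection <- function(left, right) .imp_node("intersection", left, right)

.imp_node <- function(op, left, right) {
  if (!is_implicit_expr(left) || !is_implicit_expr(right))
    stop("both children must be implicit expressions")
  structure(list(op = op, left = left, right = right), class = "implicit_expr")
}

#' @export
is_implicit_expr <- function(x) inherits(x, "implicit_expr")

#' Evaluate an implicit expression
#'
#' Recursively evaluates the signed scalar field: a leaf gives the plane
#' signed value; a union node the minimum of its children; an
#' intersection node the maximum.
#'
#' @param expr An implicit expression.
#' @param points Length-3 point or n x 3 matrix.
#' @return Numeric vector of signed values, one per point.
#' @export
eval_expr <- function(expr, points) {
  p <- as_point_matrix(points)
  .eval_expr_mat(expr, p)
}

.eval_expr_mat <- function(expr, p) {
  if (!is_implicit_expr(expr)) stop("malformed expression tree")
  switch(expr$op,
    plane = plane_value(expr$widget, p),
    union = pmin(.eval_expr_mat(expr$left, p), .eval_expr_mat(expr$right, p)),
    intersection = pmax(.eval_expr_mat(expr$left, p), .eval_expr_mat(expr$right, p)),
    stop("malformed expression tree: unknown op '", expr$op, "'"))
}

#' Classify points against an implicit expression
#'
#' Labels each point `"INSIDE"` (value below `-eps`), `"ON"` (absolute
#' value at most `eps`) or `"OUTSIDE"`.  The default tolerance scales
#' with the point magnitude so classification does not depend on the
#' model units.
#'
#' @param expr An implicit expression.
#' @param points Length-3 point or n x 3 matrix.
#' @param eps Positive tolerance for the ON band; default
#'   `1e-9 * (1 + |p|)` per point.
#' @return Character vector of region labels.
#' @export
classify <- function(expr, points, eps = NULL) {
  p <- as_point_matrix(points)
  if (is.null(eps)) eps <- 1e-9 * (1 + sqrt(rowSums(p * p)))
  if (any(eps <= 0)) stop("eps must be positive")
  v <- .eval_expr_mat(expr, p)
  ifelse(abs(v) <= eps, "ON", ifelse(v < 0, "INSIDE", "OUTSIDE"))
}

#' Structural accessors
#'
#' `expr_widgets()` collects the leaf widgets left to right;
#' `expr_n_leaves()` and `expr_n_nodes()` count leaves and internal
#' nodes (a well-formed tree over N leaves has N - 1 internal nodes);
#' `expr_depth()` is the maximum node depth (a single leaf has depth 1).
#'
#' @param expr An implicit expression.
#' @return See each function's description.
#' @export
expr_widgets <- function(expr) {
  if (expr$op == "plane") return(list(expr$widget))
  c(expr_widgets(expr$left), expr_widgets(expr$right))
}

#' @rdname expr_widgets
#' @export
expr_n_leaves <- function(expr) length(expr_widgets(expr))

#' @rdname expr_widgets
#' @export
expr_n_nodes <- function(expr) {
  if (expr$op == "plane") return(0L)
  1L + expr_n_nodes(expr$left) + expr_n_nodes(expr$right)
}

#' @rdname expr_widgets
#' @export
expr_depth <- function(expr) {
  if (expr$op == "plane") return(1L)
  1L + max(expr_depth(expr$left), expr_depth(expr$right))
}

#' Canonical text form of an expression
#'
#' Leaves print as `a<id>`; nodes as `(left OP right)` with the set
#' operators for union and intersection, e.g.
#' `(a1 \u222a (a2 \u2229 a3))` (union and intersection glyphs).
#'
#' @param expr An implicit expression.
#' @return A single string.
#' @export
expr_to_string <- function(expr) {
  if (expr$op == "plane") return(sprintf("a%d", expr$widget$id))
  op <- if (expr$op == "union") "\u222a" else "\u2229"
  sprintf("(%s %s %s)", expr_to_string(expr$left), op, expr_to_string(expr$right))
}

#' Nested-list / JSON form of an expression
#'
#' `expr_to_list()` gives the nested-list shape
#' `list("union", list("plane", 1), ...)`, which serializes with
#' jsonlite to `["union", ["plane", 1], ...]`.  `expr_from_list()`
#' rebuilds the tree; plane leaves are resolved against `widgets`, a
#' list of plane widgets indexed by id.
#'
#' @param expr An implicit expression.
#' @param x A nested list as produced by `expr_to_list()` (or parsed
#'   from its JSON form).
#' @param widgets List of [plane_widget()]s whose position matches the
#'   leaf ids.
#' @return `expr_to_list()`: a nested list; `expr_from_list()`: an
#'   implicit expression.
#' @export
expr_to_list <- function(expr) {
  if (expr$op == "plane") return(list("plane", expr$widget$id))
  list(expr$op, expr_to_list(expr$left), expr_to_list(expr$right))
}

#' @rdname expr_to_list
#' @export
expr_from_list <- function(x, widgets) {
  if (!is.list(x) || length(x) < 2L) stop("malformed expression list")
  op <- as.character(x[[1L]])
  if (op == "plane") {
    id <- as.integer(x[[2L]])
    if (id < 1L || id > length(widgets)) stop("leaf id out of range: ", id)
    w <- widgets[[id]]
    if (w$id != id) w$id <- id
    return(imp_leaf(w))
  }
  if (!op %in% c("union", "intersection") || length(x) != 3L)
    stop("malformed expression list: op '", op, "'")
  .imp_node(op, expr_from_list(x[[2L]], widgets), expr_from_list(x[[3L]], widgets))
}

#' @export
print.implicit_expr <- function(x, ...) {
  cat("<implicit_expr> ", expr_to_string(x), "\n", sep = "")
  invisible(x)
}
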