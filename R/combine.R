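# The recursive Boolean-combination algorithm.  A chain of widgets
# alpha_i..alpha_j with its transection polyline P_i..P_{j+1} is reduced
# by three subproblems: a single widget is returned as a leaf; two
# adjacent widgets are joined by intersection when P_{j+1} lies inside
# alpha_i and by union otherwise; a longer chain is split at an index k
# found by walking k down from j while the loop condition holds, then
# joined by intersection when P_{k+1} lies inside alpha_{k-1} and by
# union otherwise.
#
# Loop condition at index k (either test firing decrements k):
#   * line test, applicable for i+2 <= k <= j: the infinite line through
#     P_k P_{k+1} intersects the chain P'_i P_i P_{i+1} ... P_{k-1}
#     (head extension ray plus leading segments);
#   * ray test, applicable for i+2 <= k <= j-1: the ray from P_{k-1}
#     through P_k intersects the chain P_{k+1} ... P_{j+1} P'_{j+1}
#     (trailing segments plus tail extension ray).
#
# The instrumented cost counts 1 per base-case call, and 1 plus the
# number of loop iterations per composite call, reproducing the
# recursion-cost laws 2N-3 (best case) and (N+3)(N-2)/2 + 1 (worst
# case).

new_cost_counter <- function() {
  env <- new.env(parent = emptyenv())
  env$base_calls <- 0L
  env$composite_calls <- 0L
  env$loop_iters <- 0L
  env
}

counter_summary <- function(counter) {
  list(total = counter$base_calls + counter$composite_calls +
         counter$loop_iters,
       base_calls = counter$base_calls,
       composite_calls = counter$composite_calls,
       loop_iters = counter$loop_iters)
}

#' Recursive Boolean combination of a widget sub-chain
#'
#' Combines widgets `i..j` of an oriented path into one implicit
#' expression, guided by the transection polyline.  Callers normally use
#' [combine_path()]; this entry point exposes the recursion for
#' instrumentation and testing.
#'
#' @param path An oriented [clipping_path()] (see [orient_normals()]).
#' @param polyline The matching [transect()] polyline (inside
#'   directions consistent with the oriented path).
#' @param frame The [transection_frame()] used to build `polyline`.
#' @param i,j 1-based widget index range, `1 <= i <= j <= N`.
#' @param counter A cost counter environment from `new_cost_counter()`;
#'   created on the fly when omitted.
#' @return An implicit expression over widgets `i..j`.
#' @export
comb_imp_funs <- function(path, polyline, frame, i, j,
                          counter = new_cost_counter()) {
  n <- path_n_widgets(path)
  if (!(i >= 1L && i <= j && j <= n))
    stop("invalid index range [", i, ", ", j, "] for ", n, " widgets")
  pts3 <- frame_to_3d(frame, polyline$points)
  tol <- 1e-9 * polyline$scale
  .comb_rec(path, polyline, pts3, i, j, counter, tol)
}

.inside_widget <- function(path, pts3, widget_idx, point_idx, tol) {
  # strict sign test; values within tol of zero count as inside, so ties
  # break toward intersection
  plane_value(path$widgets[[widget_idx]], pts3[point_idx, ]) <= tol
}

.comb_rec <- function(path, polyline, pts3, i, j, counter, tol) {
  if (i == j) {
    counter$base_calls <- counter$base_calls + 1L
    return(imp_leaf(path$widgets[[i]]))
  }
  pts <- polyline$points
  if (j - i == 1L) {
    counter$base_calls <- counter$base_calls + 1L
    a <- imp_leaf(path$widgets[[i]])
    b <- imp_leaf(path$widgets[[j]])
    if (.inside_widget(path, pts3, i, j + 1L, tol))
      return(imp_intersection(a, b))
    return(imp_union(a, b))
  }

  counter$composite_calls <- counter$composite_calls + 1L
  k <- j
  repeat {
    line_fires <- FALSE
    ray_fires <- FALSE
    if (k >= i + 2L && k <= j) {
      # head chain P'_i P_i ... P_{k-1}
      head_pts <- pts[i:(k - 1L), , drop = FALSE]
      head_dir <- (pts[i, ] - pts[i + 1L, ]) /
        vnorm(pts[i, ] - pts[i + 1L, ])
      line_fires <- line_hits_polyline(pts[k, ], pts[k + 1L, ], "LINE",
                                       head_pts, head_ray_dir = head_dir,
                                       tol = tol)
    }
    if (!line_fires && k >= i + 2L && k <= j - 1L) {
      # tail chain P_{k+1} ... P_{j+1} P'_{j+1}
      tail_pts <- pts[(k + 1L):(j + 1L), , drop = FALSE]
      tail_dir <- (pts[j + 1L, ] - pts[j, ]) /
        vnorm(pts[j + 1L, ] - pts[j, ])
      ray_fires <- line_hits_polyline(pts[k - 1L, ], pts[k, ], "RAY",
                                      tail_pts, tail_ray_dir = tail_dir,
                                      tol = tol)
    }
    if (!line_fires && !ray_fires) break
    k <- k - 1L
    counter$loop_iters <- counter$loop_iters + 1L
  }

  left <- .comb_rec(path, polyline, pts3, i, k - 1L, counter, tol)
  right <- .comb_rec(path, polyline, pts3, k, j, counter, tol)
  if (.inside_widget(path, pts3, k - 1L, k + 1L, tol))
    imp_intersection(left, right)
  else
    imp_union(left, right)
}

#' Combine a whole clipping path into one implicit function
#'
#' Top-level driver: builds the transection frame, transects the path
#' into its 2D polyline, orients the widget normals consistently, and
#' runs the recursive Boolean combination over the full chain.  A path
#' with `reverse = TRUE` has every widget normal negated first, which
#' complements the clipped region.  Single-widget paths return the leaf
#' directly (instrumented cost 1) without any transection.
#'
#' @param path A [clipping_path()].
#' @return An object of class `path_combination`: a list with `expr`
#'   (the implicit expression), `cost` (list `total`, `base_calls`,
#'   `composite_calls`, `loop_iters`), `polyline`, `frame`, and `path`
#'   (the oriented path actually combined).
#' @examples
#' p <- gen_path("CONVEX", params = list(n = 4))
#' comb <- combine_path(p)
#' expr_to_string(comb$expr)
#' comb$cost$total   # 2 * 4 - 3
#' @export
combine_path <- function(path) {
  stopifnot(is_clipping_path(path))
  if (path$reverse) {
    path$widgets <- lapply(path$widgets, reverse_widget)
    path$reverse <- FALSE
  }
  counter <- new_cost_counter()
  n <- path_n_widgets(path)
  if (n == 1L) {
    counter$base_calls <- 1L
    res <- list(expr = imp_leaf(path$widgets[[1L]]),
                cost = counter_summary(counter), polyline = NULL,
                frame = NULL, path = path)
    class(res) <- "path_combination"
    return(res)
  }
  frame <- transection_frame(path)
  polyline <- transect(path, frame)
  path <- orient_normals(path, polyline)
  flipped <- attr(path, "flipped")
  if (length(flipped))
    polyline$inside_dirs[flipped, ] <- -polyline$inside_dirs[flipped, ,
                                                             drop = FALSE]
  expr <- comb_imp_funs(path, polyline, frame, 1L, n, counter)
  res <- list(expr = expr, cost = counter_summary(counter),
              polyline = polyline, frame = frame, path = path)
  class(res) <- "path_combination"
  res
}

#' @export
print.path_combination <- function(x, ...) {
  cat("<path_combination>\n  expr: ", expr_to_string(x$expr),
      "\n  cost: total=", x$cost$total, " (base=", x$cost$base_calls,
      ", composite=", x$cost$composite_calls, ", loop=",
      x$cost$loop_iters, ")\n", sep = "")
  invisible(x)
}
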