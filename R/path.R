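# Clipping paths: ordered chains of connected plane widgets.

#' Create a clipping path
#'
#' An ordered chain of plane widgets whose planes intersect pairwise in
#' hinge lines.  `closed = TRUE` marks enclosure-style paths whose last
#' widget hinges back onto the first (used to surround a target such as
#' a tumour).  `reverse = TRUE` asks for all normals to be negated
#' before combination, which complements the clipped region.
#'
#' @param widgets List of [plane_widget()]s (N >= 1); ids are rewritten
#'   to 1..N in order.
#' @param closed Logical; enclosure path.
#' @param reverse Logical; negate all normals before combining.
#' @param thickness Optional [plane_widget()] used as thickness plane.
#' @param reverse_thickness Logical; reverse the thickness plane.
#' @return An object of class `clipping_path`.
#' @export
clipping_path <- function(widgets, closed = FALSE, reverse = FALSE,
                          thickness = NULL, reverse_thickness = FALSE) {
  if (is_plane_widget(widgets)) widgets <- list(widgets)
  if (!length(widgets) || !all(vapply(widgets, is_plane_widget, TRUE)))
    stop("widgets must be a non-empty list of plane widgets")
  for (i in seq_along(widgets)) widgets[[i]]$id <- i
  n <- length(widgets)
  pairs <- if (n > 1L) cbind(seq_len(n - 1L), 2:n) else NULL
  if (isTRUE(closed) && n > 2L) pairs <- rbind(pairs, c(n, 1L))
  if (!is.null(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- widgets[[pairs[r, 1L]]]$normal
      b <- widgets[[pairs[r, 2L]]]$normal
      if (vnorm(cross3(a, b)) <= 1e-6)
        stop(degenerate_path_error(sprintf(
          "widgets %d and %d have (near-)parallel planes; no hinge line",
          pairs[r, 1L], pairs[r, 2L])))
    }
  }
  if (!is.null(thickness)) stopifnot(is_plane_widget(thickness))
  structure(list(widgets = widgets, closed = isTRUE(closed),
                 reverse = isTRUE(reverse), thickness = thickness,
                 reverse_thickness = isTRUE(reverse_thickness)),
            class = "clipping_path")
}

is_clipping_path <- function(x) inherits(x, "clipping_path")

path_n_widgets <- function(path) length(path$widgets)

#' @export
print.clipping_path <- function(x, ...) {
  cat(sprintf("<clipping_path> %d widget(s)%s%s%s\n", length(x$widgets),
              if (x$closed) ", closed" else "",
              if (x$reverse) ", reversed" else "",
              if (is.null(x$thickness)) "" else ", thickness plane"))
  invisible(x)
}

# Error classes used across the package (CLI maps them to exit codes).
degenerate_path_error <- function(msg)
  structure(class = c("pathclip_degenerate_path", "pathclip_error", "error",
                      "condition"),
            list(message = msg, call = sys.call(-1)))

transection_error <- function(msg)
  structure(class = c("pathclip_transection", "pathclip_error", "error",
                      "condition"),
            list(message = msg, call = sys.call(-1)))

orientation_error <- function(msg)
  structure(class = c("pathclip_orientation", "pathclip_error", "error",
                      "condition"),
            list(message = msg, call = sys.call(-1)))

io_error <- function(msg)
  structure(class = c("pathclip_io", "pathclip_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
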