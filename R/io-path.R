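# The JSON clipping-path schema (version 1) and fiducial-point input.
#
# {
#   "version": 1,
#   "widgets": [{"center": [x,y,z], "normal": [x,y,z],
#                "corners": [[..]x4]  (optional)}, ...],
#   "closed": false, "thickness_plane": {...} (optional),
#   "reverse_path": false, "reverse_thickness": false
# }

.widget_to_record <- function(w) {
  rec <- list(center = w$center, normal = w$normal)
  if (!is.null(w$corners))
    rec$corners <- lapply(seq_len(4L), function(i) w$corners[i, ])
  rec
}

.widget_from_record <- function(rec, idx, what = "widget") {
  err <- function(msg) stop(io_error(sprintf("%s %d: %s", what, idx, msg)))
  center <- suppressWarnings(as.numeric(unlist(rec$center)))
  normal <- suppressWarnings(as.numeric(unlist(rec$normal)))
  if (length(center) != 3L || any(!is.finite(center)))
    err("center must be 3 finite numbers")
  if (length(normal) != 3L || any(!is.finite(normal)) ||
      vnorm(normal) < 1e-12)
    err("normal must be a non-zero finite 3-vector")
  corners <- NULL
  if (!is.null(rec$corners)) {
    co <- rec$corners
    if (is.list(co)) co <- do.call(rbind, lapply(co, as.numeric))
    corners <- matrix(as.numeric(co), ncol = 3L)
    if (nrow(corners) != 4L || any(!is.finite(corners)))
      err("corners must be a 4 x 3 matrix of finite numbers")
  }
  tryCatch(plane_widget(center, normal, corners, id = idx),
           error = function(e) err(conditionMessage(e)))
}

#' Read and write clipping paths (JSON schema v1)
#'
#' The on-disk schema stores the widget list (center, normal, optional
#' quad corners), the closed flag, an optional thickness plane and the
#' two reverse flags.  Writing uses a canonical formatting, so
#' write-read-write round-trips are byte-identical; reading enforces
#' all clipping-path invariants and reports the first offending widget.
#'
#' @param file Path to the JSON file.
#' @param path A [clipping_path()].
#' @return `read_path()` returns a `clipping_path`; `write_path()`
#'   returns `file` invisibly.
#' @export
read_path <- function(file) {
  if (!file.exists(file)) stop(io_error(paste0("no such file: ", file)))
  doc <- tryCatch(jsonlite::fromJSON(file, simplifyVector = FALSE),
                  error = function(e)
                    stop(io_error(paste0("malformed JSON in ", file, ": ",
                                         conditionMessage(e)))))
  if (!identical(as.integer(doc$version %||% NA), 1L))
    stop(io_error("unsupported or missing path schema version (want 1)"))
  if (!length(doc$widgets)) stop(io_error("path has no widgets"))
  widgets <- lapply(seq_along(doc$widgets), function(i)
    .widget_from_record(doc$widgets[[i]], i))
  thickness <- if (!is.null(doc$thickness_plane))
    .widget_from_record(doc$thickness_plane, 0L, what = "thickness plane")
  tryCatch(
    clipping_path(widgets,
                  closed = isTRUE(doc$closed),
                  reverse = isTRUE(doc$reverse_path),
                  thickness = thickness,
                  reverse_thickness = isTRUE(doc$reverse_thickness)),
    error = function(e) {
      if (inherits(e, "pathclip_degenerate_path")) stop(e)  # geometry, not IO
      stop(io_error(paste0("invalid clipping path: ", conditionMessage(e))))
    })
}

#' @rdname read_path
#' @export
write_path <- function(path, file) {
  stopifnot(is_clipping_path(path))
  doc <- list(version = 1L,
              widgets = lapply(path$widgets, .widget_to_record),
              closed = path$closed,
              reverse_path = path$reverse,
              reverse_thickness = path$reverse_thickness)
  if (!is.null(path$thickness))
    doc$thickness_plane <- .widget_to_record(path$thickness)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, file)
  invisible(file)
}

#' Read fiducial points from CSV
#'
#' One `x,y,z` row per fiducial; `#` starts a comment line.  At least
#' two finite points are required.
#'
#' @param file CSV file path.
#' @return An n x 3 numeric matrix.
#' @export
read_fiducials <- function(file) {
  if (!file.exists(file)) stop(io_error(paste0("no such file: ", file)))
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop(io_error("need at least 2 fiducial points"))
  pts <- t(vapply(seq_along(lines), function(i) {
    x <- suppressWarnings(as.numeric(strsplit(lines[i], ",")[[1L]]))
    if (length(x) != 3L || any(!is.finite(x)))
      stop(io_error(sprintf("fiducial record %d is not x,y,z: '%s'",
                            i, lines[i])))
    x
  }, numeric(3L)))
  pts
}

#' Build a clipping path from fiducial points
#'
#' Widget `i` is the planar quad through fiducials `i` and `i+1`
#' extruded along `extrusion_dir` by `depth` on both sides; its normal
#' is the normalized cross product of the fiducial step and the
#' extrusion direction.  This is the headless analogue of placing a
#' widget chain on landmark points: the fiducials become the hinge
#' positions of the path.
#'
#' @param fiducials n x 3 matrix (n >= 2) of ordered landmark points.
#' @param extrusion_dir Length-3 direction, not parallel to any
#'   fiducial step.
#' @param depth Extrusion half-depth (model units).
#' @return A [clipping_path()] of `n - 1` widgets.
#' @export
path_from_fiducials <- function(fiducials, extrusion_dir = c(0, 0, 1),
                                depth = 10) {
  fid <- as.matrix(fiducials)
  if (ncol(fid) != 3L || nrow(fid) < 2L)
    stop("fiducials must be an n x 3 matrix with n >= 2")
  ex <- normalize(as.numeric(extrusion_dir))
  widgets <- vector("list", nrow(fid) - 1L)
  for (i in seq_len(nrow(fid) - 1L)) {
    a <- fid[i, ]; b <- fid[i + 1L, ]
    step <- b - a
    if (vnorm(step) < 1e-12)
      stop(degenerate_path_error(sprintf(
        "fiducials %d and %d coincide", i, i + 1L)))
    nrm <- cross3(step, ex)
    if (vnorm(nrm) < 1e-9 * vnorm(step))
      stop(degenerate_path_error(sprintf(
        "fiducial step %d is parallel to the extrusion direction", i)))
    corners <- rbind(a - depth * ex, b - depth * ex,
                     b + depth * ex, a + depth * ex)
    widgets[[i]] <- plane_widget(center = (a + b) / 2,
                                 normal = normalize(nrm),
                                 corners = corners, id = i)
  }
  clipping_path(widgets)
}
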