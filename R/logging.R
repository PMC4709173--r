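# Leveled logging to standard error.  Messages are deterministic so two
# identical runs produce identical logs apart from the timestamp column.

.log_state <- new.env(parent = emptyenv())
.log_state$level <- "INFO"

.log_levels <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, ERROR = 4L)

#' Set the logging threshold
#'
#' @param level One of `"DEBUG"`, `"INFO"`, `"WARN"`, `"ERROR"`.
#' @return The previous level, invisibly.
#' @export
set_log_level <- function(level) {
  level <- match.arg(toupper(level), names(.log_levels))
  old <- .log_state$level
  .log_state$level <- level
  invisible(old)
}

log_msg <- function(level, ...) {
  level <- match.arg(toupper(level), names(.log_levels))
  if (.log_levels[[level]] < .log_levels[[.log_state$level]]) return(invisible())
  stamp <- format(Sys.time(), "%H:%M:%OS3")
  message(sprintf("[%s] %-5s %s", stamp, level, paste0(..., collapse = "")))
  invisible()
}
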