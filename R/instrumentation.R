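## File-open instrumentation.
##
## The package promises that the large structures and references files
## are never opened unless a structure/reference getter is actually
## called, and are streamed rather than loaded.  To make that promise
## testable, every file open performed by the streaming readers (and by
## the bulk parser) is recorded in a session log.

.instr <- new.env(parent = emptyenv())
.instr$events <- character(0)

.instrLog <- function(kind, path) {
  .instr$events <- c(.instr$events, paste0(kind, ":", path))
  invisible(NULL)
}

#' File-open instrumentation log
#'
#' `resetFileOpenLog()` clears the log; `fileOpenLog()` returns the
#' files opened since, each entry of the form `"<logical name>:<path>"`.
#' Used to verify the laziness contract: reading scalar entity fields
#' never touches the structures or references files.
#'
#' @return `fileOpenLog()` returns a character vector of events, oldest
#'   first; `resetFileOpenLog()` returns (invisibly) the events it
#'   discarded.
#' @examples
#' resetFileOpenLog()
#' fileOpenLog()
#' @export
fileOpenLog <- function() .instr$events

#' @rdname fileOpenLog
#' @export
resetFileOpenLog <- function() {
  old <- .instr$events
  .instr$events <- character(0)
  invisible(old)
}
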