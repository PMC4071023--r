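# Run logging: every composing or CLI invocation records the operation,
# all argument values and every input file with its record count, so a
# finished image can always be traced back to how it was produced.

#' Capture an invocation for the run log
#'
#' @param operation Name of the invoked operation.
#' @param arguments Named list of every argument of the invocation (each
#'   parameter appears exactly once).
#' @param input_files Named list mapping input file paths (or track
#'   names) to their record counts.
#' @param timestamp Time of the invocation; defaults to now.
#' @return A list of class `run_log`.
#' @export
run_log <- function(operation, arguments = list(), input_files = list(),
                    timestamp = Sys.time()) {
  if (length(arguments) && anyDuplicated(names(arguments))) {
    stop("duplicate argument name in run log")
  }
  out <- list(operation = as.character(operation), arguments = arguments,
              input_files = input_files, timestamp = timestamp)
  class(out) <- "run_log"
  out
}

fmt_arg <- function(x) {
  if (is.null(x)) return("NULL")
  paste(format(x, scientific = FALSE, trim = TRUE), collapse = ",")
}

#' Write a run log file
#'
#' Human-readable listing of the operation, timestamp, every argument
#' name and value, and every input file with its record count. Two
#' identical invocations produce identical logs apart from the timestamp
#' line.
#'
#' @param log A [run_log()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_log <- function(log, path) {
  stopifnot(inherits(log, "run_log"))
  lines <- c(
    "# circosviz run log",
    paste0("timestamp: ",
           format(log$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"), "Z"),
    paste0("operation: ", log$operation),
    "arguments:")
  for (nm in names(log$arguments)) {
    lines <- c(lines, paste0("  ", nm, ": ", fmt_arg(log$arguments[[nm]])))
  }
  lines <- c(lines, "input files:")
  for (nm in names(log$input_files)) {
    lines <- c(lines, paste0("  ", nm, " (",
                             fmt_arg(log$input_files[[nm]]), " records)"))
  }
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}
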