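#' @keywords internal
"_PACKAGE"

## Condition classes used across the package. The CLI maps them to exit
## codes: validation/format -> 1, I/O -> 2.

abort_validation <- function(msg, ...) {
  stop(structure(
    class = c("fusionscreen_validation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

abort_format <- function(msg, ...) {
  stop(structure(
    class = c("fusionscreen_format_error",
              "fusionscreen_validation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

abort_io <- function(msg, ...) {
  stop(structure(
    class = c("fusionscreen_io_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

fus_log <- function(msg, ..., level = "INFO") {
  message(sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(msg, ...)))
}

check_file_readable <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    abort_io("cannot read file: %s", paste(path, collapse = ", "))
  invisible(path)
}

check_path_writable <- function(path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) abort_io("directory does not exist: %s", dir)
  invisible(path)
}
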