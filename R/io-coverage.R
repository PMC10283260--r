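#' Write / read a per-position coverage file
#'
#' The coverage file lists the number of aligned reads per genomic
#' position as dense tab-separated rows `position<TAB>count` with
#' 1-based positions, one row per reference position including zeros.
#' A leading `#seq_id=<id>` comment records the reference name so the
#' round-trip is exact; [read_coverage()] falls back to the file's base
#' name when the comment is absent.
#'
#' @param track A [coverage_track()].
#' @param path File path.
#' @return `read_coverage()` returns a [coverage_track()];
#'   `write_coverage()` returns `NULL` invisibly.
#' @export
write_coverage <- function(track, path) {
  check_path_writable(path)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#seq_id=%s", track$seq_id), con)
  if (track$length > 0L)
    writeLines(paste(seq_len(track$length), track$counts, sep = "\t"), con)
  invisible(NULL)
}

#' @rdname write_coverage
#' @export
read_coverage <- function(path) {
  check_file_readable(path)
  lines <- readLines(path, warn = FALSE)
  seq_id <- sub("\\.[^.]*$", "", basename(path))
  meta <- startsWith(lines, "#")
  if (any(meta)) {
    m <- grep("^#seq_id=", lines[meta], value = TRUE)
    if (length(m)) seq_id <- sub("^#seq_id=", "", m[1L])
  }
  body <- lines[!meta & nzchar(lines)]
  if (!length(body)) return(coverage_track(seq_id, integer(0)))
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    abort_format("coverage '%s': expected two tab-separated columns", path)
  pos <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 1L)))
  cnt_chr <- vapply(parts, `[[`, character(1), 2L)
  if (any(grepl("[^0-9]", cnt_chr)))
    abort_format("coverage '%s': non-integer count '%s'", path,
                 cnt_chr[grepl("[^0-9]", cnt_chr)][1L])
  cnt <- as.integer(cnt_chr)
  if (anyNA(pos) || !identical(pos, seq_along(pos)))
    abort_format("coverage '%s': positions must be dense 1..n", path)
  coverage_track(seq_id, cnt)
}
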