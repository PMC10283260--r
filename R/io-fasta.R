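#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that returns the
#' package's light-weight [seq_record()] list. Multi-line sequences are
#' concatenated; residues are upper-cased; record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Forced alphabet for all records, or `NULL` to guess
#'   per record from the residues.
#' @return List of [seq_record()] objects (possibly empty).
#' @export
read_fasta <- function(path, alphabet = NULL) {
  check_file_readable(path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && nzchar(first) && !startsWith(first, ">") &&
      !startsWith(first, ";"))
    abort_format("FASTA '%s': sequence data before any '>' header", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort_format(
                    "FASTA '%s': %s", path, conditionMessage(e)))
  if (!length(set)) return(list())
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    abort_format("FASTA '%s': duplicate record id '%s'", path,
                 ids[duplicated(ids)][1L])
  lapply(seq_along(set), function(i)
    seq_record(ids[i], as.character(set[[i]]), alphabet = alphabet))
}

#' Write a FASTA file
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x))` reproduces ids
#' and residues exactly.
#'
#' @param records List of [seq_record()] objects.
#' @param path Output path.
#' @param line_width Residues per sequence line (default 60).
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  check_path_writable(path)
  line_width <- as.integer(line_width)
  if (is.na(line_width) || line_width < 1L)
    abort_validation("write_fasta: line_width must be >= 1")
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    writeLines(paste0(">", rec$id), con)
    n <- nchar(rec$residues)
    starts <- seq.int(1L, n, by = line_width)
    writeLines(substring(rec$residues, starts,
                         pmin(starts + line_width - 1L, n)), con)
  }
  invisible(NULL)
}

#' Extract a subsequence from a genome record
#'
#' Returns the residues of `interval` with an id of the form
#' `"<seq_id>:<start1>-<end1>"` (1-based inclusive label, as printed by
#' common region-extraction tools).
#'
#' @param genome A nucleotide [seq_record()].
#' @param interval A [genomic_interval()] with `seq_id` matching
#'   `genome$id` and bounds within the sequence.
#' @return A [seq_record()] for the subsequence.
#' @export
extract_region <- function(genome, interval) {
  if (!identical(interval$seq_id, genome$id))
    abort_validation("extract_region: interval is on '%s', genome is '%s'",
                     interval$seq_id, genome$id)
  n <- record_length(genome)
  if (interval$end > n)
    abort_validation("extract_region: interval [%d,%d) exceeds length %d",
                     interval$start, interval$end, n)
  seq_record(sprintf("%s:%d-%d", genome$id, interval$start + 1L, interval$end),
             substr(genome$residues, interval$start + 1L, interval$end),
             alphabet = genome$alphabet)
}
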