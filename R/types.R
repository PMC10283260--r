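## Shared genomic data model.
##
## Internal coordinate convention: 0-based half-open [start, end) on the
## forward strand, everywhere. Conversion to/from the 1-based inclusive
## conventions of GFF3 and SAM happens only inside the readers/writers.

#' Construct a sequence record
#'
#' A minimal container for one named sequence, either nucleotide or
#' protein. Nucleotide residues are restricted to `A`, `C`, `G`, `T`, `N`;
#' residues are upper-cased on construction.
#'
#' @param id Character scalar, sequence identifier.
#' @param residues Character scalar, the sequence itself.
#' @param alphabet `"nucleotide"` or `"protein"`. If `NULL`, guessed from
#'   the residue composition (ACGTN-only implies nucleotide).
#' @return An object of class `seq_record` with fields `id`, `residues`
#'   and `alphabet`.
#' @export
seq_record <- function(id, residues, alphabet = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    abort_validation("seq_record: 'id' must be a non-empty string")
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues))
    abort_validation("seq_record '%s': residues must be non-empty", id)
  residues <- toupper(residues)
  if (is.null(alphabet)) {
    alphabet <- if (grepl("^[ACGTN]+$", residues)) "nucleotide" else "protein"
  }
  alphabet <- match.arg(alphabet, c("nucleotide", "protein"))
  if (alphabet == "nucleotide" && !grepl("^[ACGTN]+$", residues))
    abort_validation(
      "seq_record '%s': nucleotide residues must be drawn from {A,C,G,T,N}",
      id)
  structure(list(id = id, residues = residues, alphabet = alphabet),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  n <- nchar(x$residues)
  head <- substr(x$residues, 1L, 60L)
  cat(sprintf("<seq_record> %s [%s, %d residues]\n  %s%s\n",
              x$id, x$alphabet, n, head, if (n > 60L) "..." else ""))
  invisible(x)
}

record_length <- function(x) nchar(x$residues)

#' Construct a genomic interval
#'
#' Intervals are 0-based half-open `[start, end)` on a named sequence.
#'
#' @param seq_id Character scalar naming the reference sequence.
#' @param start,end Integer bounds, `0 <= start < end`.
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(seq_id, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    abort_validation("genomic_interval: need 0 <= start < end (got [%s, %s))",
                     start, end)
  structure(list(seq_id = seq_id, start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<interval> %s:[%d,%d)\n", x$seq_id, x$start, x$end))
  invisible(x)
}

interval_width <- function(x) x$end - x$start

#' Construct a gene model
#'
#' An annotated gene: ordered, non-overlapping exon intervals on one
#' reference sequence. Introns are derived as the gaps between
#' consecutive exons (see [gene_introns()]).
#'
#' @param gene_id Character scalar.
#' @param seq_id Reference sequence name; all exons must lie on it.
#' @param strand `"+"` or `"-"`. Carried for reporting/orientation only;
#'   coverage and junction evidence are computed unstranded.
#' @param exons List of [genomic_interval()] objects, or a two-column
#'   matrix/data.frame of 0-based half-open starts and ends.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, seq_id, strand, exons) {
  if (inherits(exons, "genomic_interval")) exons <- list(exons)
  if (is.matrix(exons) || is.data.frame(exons)) {
    exons <- lapply(seq_len(nrow(exons)), function(i)
      genomic_interval(seq_id, exons[i, 1L], exons[i, 2L]))
  }
  if (!length(exons)) abort_validation("gene_model '%s': needs >= 1 exon", gene_id)
  if (!strand %in% c("+", "-"))
    abort_validation("gene_model '%s': strand must be '+' or '-'", gene_id)
  starts <- vapply(exons, `[[`, integer(1), "start")
  ends <- vapply(exons, `[[`, integer(1), "end")
  ok_seq <- vapply(exons, function(e) identical(e$seq_id, seq_id), logical(1))
  if (!all(ok_seq))
    abort_validation("gene_model '%s': all exons must be on '%s'", gene_id, seq_id)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; exons <- exons[o]
  if (length(exons) > 1L && any(starts[-1L] < ends[-length(ends)]))
    abort_validation("gene_model '%s': exons overlap", gene_id)
  structure(list(gene_id = gene_id, seq_id = seq_id, strand = strand,
                 exons = exons),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  ex <- paste(vapply(x$exons, function(e)
    sprintf("[%d,%d)", e$start, e$end), character(1)), collapse = " ")
  cat(sprintf("<gene_model> %s on %s(%s): %d exon(s) %s\n",
              x$gene_id, x$seq_id, x$strand, length(x$exons), ex))
  invisible(x)
}

#' Derive the introns of a gene model
#'
#' @param gene A [gene_model()].
#' @return A list of [genomic_interval()]s, one per gap between
#'   consecutive exons (empty for single-exon genes).
#' @export
gene_introns <- function(gene) {
  n <- length(gene$exons)
  if (n < 2L) return(list())
  lapply(seq_len(n - 1L), function(i)
    genomic_interval(gene$seq_id, gene$exons[[i]]$end,
                     gene$exons[[i + 1L]]$start))
}

gene_span <- function(gene) {
  genomic_interval(gene$seq_id, gene$exons[[1L]]$start,
                   gene$exons[[length(gene$exons)]]$end)
}

#' Construct a spliced alignment
#'
#' One read alignment decomposed into reference-aligned blocks separated
#' by junction gaps (CIGAR `N` operations). Blocks are 0-based half-open
#' and strictly ascending; the gaps are exactly the space between
#' consecutive blocks.
#'
#' @param read_id,seq_id Identifiers.
#' @param block_start,block_end Integer vectors of equal length giving
#'   the aligned blocks.
#' @param aligned_length Number of query bases inside blocks.
#' @param read_length Full query length (soft/hard clips included).
#' @param identity Fraction in `[0,1]`; from the `NM` tag when available.
#' @return An object of class `spliced_alignment`.
#' @export
spliced_alignment <- function(read_id, seq_id, block_start, block_end,
                              aligned_length, read_length,
                              identity = 1.0) {
  block_start <- as.integer(block_start); block_end <- as.integer(block_end)
  n <- length(block_start)
  if (n == 0L || length(block_end) != n)
    abort_validation("spliced_alignment '%s': need >= 1 block", read_id)
  if (any(block_end <= block_start))
    abort_validation("spliced_alignment '%s': empty or inverted block", read_id)
  if (n > 1L && any(block_start[-1L] < block_end[-n]))
    abort_validation("spliced_alignment '%s': blocks overlap or are unsorted",
                     read_id)
  aligned_length <- as.integer(aligned_length)
  read_length <- as.integer(read_length)
  if (read_length <= 0L)
    abort_validation("spliced_alignment '%s': read_length must be > 0", read_id)
  if (aligned_length > read_length)
    abort_validation("spliced_alignment '%s': aligned_length > read_length",
                     read_id)
  if (is.na(identity) || identity < 0 || identity > 1)
    abort_validation("spliced_alignment '%s': identity outside [0,1]", read_id)
  structure(list(read_id = read_id, seq_id = seq_id,
                 block_start = block_start, block_end = block_end,
                 aligned_length = aligned_length,
                 read_length = read_length, identity = identity),
            class = "spliced_alignment")
}

#' Junction gaps of a spliced alignment
#'
#' @param aln A [spliced_alignment()].
#' @return Two-column integer matrix (`start`, `end`) of the N-gap
#'   intervals between consecutive blocks; zero rows if unspliced.
#' @export
alignment_gaps <- function(aln) {
  n <- length(aln$block_start)
  if (n < 2L)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  cbind(start = aln$block_end[-n], end = aln$block_start[-1L])
}

#' @export
print.spliced_alignment <- function(x, ...) {
  b <- paste(sprintf("[%d,%d)", x$block_start, x$block_end), collapse = " ")
  cat(sprintf("<spliced_alignment> %s on %s: %s id=%.3f len=%d/%d\n",
              x$read_id, x$seq_id, b, x$identity, x$aligned_length,
              x$read_length))
  invisible(x)
}

#' Construct a coverage track
#'
#' Per-position aligned-read counts for one reference sequence.
#'
#' @param seq_id Reference name.
#' @param counts Non-negative integer vector, one entry per reference
#'   position (position `p` 0-based is `counts[p + 1]`).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(seq_id, counts) {
  counts <- as.integer(counts)
  if (anyNA(counts) || any(counts < 0L))
    abort_validation("coverage_track '%s': counts must be non-negative", seq_id)
  structure(list(seq_id = seq_id, counts = counts,
                 length = length(counts)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s: %d positions, mean %.2f, max %d\n",
              x$seq_id, x$length,
              if (x$length) mean(x$counts) else 0,
              if (x$length) max(x$counts) else 0L))
  invisible(x)
}
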