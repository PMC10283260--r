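#' Exact k-mer matches between two sequences
#'
#' Enumerates every position pair `(i, j)` (0-based) where the k-mer of
#' sequence `a` starting at `i` equals the k-mer of `b` starting at `j`
#' — the computation behind a repeat dotplot. Matching is
#' case-insensitive; k-mers containing `N` never match (including
#' `N` vs `N`), so masked regions produce no spurious diagonals. With
#' `include_revcomp = TRUE`, matches of `a` k-mers against the reverse
#' complement of `b` are reported additionally, with `pos_b` giving the
#' 0-based start of the matching window on the forward strand of `b`.
#'
#' One sequence is hash-indexed and the other streamed, so runtime is
#' linear in sequence length plus output size.
#'
#' @param a,b [seq_record()]s (nucleotide when `include_revcomp`).
#' @param k K-mer size (default 31, a common choice resolving repeats
#'   while tolerant of unique sequence).
#' @param include_revcomp Also report reverse-complement matches.
#' @return Data.frame with columns `pos_a`, `pos_b` (0-based) and
#'   `orientation` (`"forward"`/`"revcomp"`), sorted by
#'   (`pos_a`, `pos_b`) within orientation, forward first.
#' @export
kmer_matches <- function(a, b, k = 31L, include_revcomp = FALSE) {
  k <- as.integer(k)
  if (k < 1L) abort_validation("kmer_matches: k must be >= 1")
  na <- record_length(a); nb <- record_length(b)
  if (k > na || k > nb)
    abort_validation("kmer_matches: k = %d exceeds a sequence length", k)
  if (include_revcomp && (a$alphabet != "nucleotide" ||
                          b$alphabet != "nucleotide"))
    abort_validation("kmer_matches: revcomp mode needs nucleotide sequences")

  match_one <- function(sa, sb, orientation) {
    ka <- substring(sa, seq_len(nchar(sa) - k + 1L),
                    seq_len(nchar(sa) - k + 1L) + k - 1L)
    kb <- substring(sb, seq_len(nchar(sb) - k + 1L),
                    seq_len(nchar(sb) - k + 1L) + k - 1L)
    ok_a <- !grepl("N", ka, fixed = TRUE)
    ok_b <- !grepl("N", kb, fixed = TRUE)
    ## hash-join: index b's k-mers, stream a's
    idx_b <- split(which(ok_b), kb[ok_b])
    ia <- which(ok_a)
    hits_b <- idx_b[ka[ia]]
    nhits <- lengths(hits_b)
    ## unmatched k-mers give NULL entries with length 0
    pos_a <- rep.int(ia, nhits) - 1L
    pos_b <- unlist(hits_b, use.names = FALSE) - 1L
    if (!length(pos_a))
      return(data.frame(pos_a = integer(0), pos_b = integer(0),
                        orientation = character(0)))
    data.frame(pos_a = pos_a, pos_b = as.integer(pos_b),
               orientation = orientation)
  }

  sa <- toupper(a$residues); sb <- toupper(b$residues)
  out <- match_one(sa, sb, "forward")
  if (include_revcomp) {
    rb <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(gsub("[^ACGTN]", "N", sb))))
    rc <- match_one(sa, rb, "revcomp")
    if (nrow(rc)) {
      ## map positions on revcomp(b) back to forward-strand starts on b
      rc$pos_b <- nb - (rc$pos_b + k)
      out <- rbind(out, rc)
    }
  }
  out <- out[order(match(out$orientation, c("forward", "revcomp")),
                   out$pos_a, out$pos_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a dotplot match table
#'
#' TSV with header `pos_a<TAB>pos_b<TAB>orientation` and 1-based
#' positions on output; [read_dotplot_table()] restores the 0-based
#' match data.frame.
#'
#' @param matches Data.frame as returned by [kmer_matches()].
#' @param path File path.
#' @export
dotplot_table <- function(matches, path) {
  check_path_writable(path)
  out <- data.frame(pos_a = matches$pos_a + 1L, pos_b = matches$pos_b + 1L,
                    orientation = matches$orientation)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(NULL)
}

#' @rdname dotplot_table
#' @return `read_dotplot_table()` returns the match data.frame (0-based).
#' @export
read_dotplot_table <- function(path) {
  check_file_readable(path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("integer", "integer", "character"))
  data.frame(pos_a = tab$pos_a - 1L, pos_b = tab$pos_b - 1L,
             orientation = tab$orientation)
}
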