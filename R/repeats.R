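## Protein-level domain screen: length filter, iterative local-alignment
## domain-copy counting, catalytic-triad conservation.

MASK_SYMBOL <- "#"
MASK_SCORE <- -1e6

#' Protein scoring scheme
#'
#' BLOSUM62 (taken from the Biostrings package) with affine gap
#' penalties mirroring common protein-BLAST defaults: gap open -11,
#' gap extend -1. The matrix is extended with the masking sentinel
#' `"#"`, which scores -1e6 against everything (itself included) so
#' that iterative repeat counting can never chain an alignment across a
#' previously recorded hit.
#'
#' @param substitution Square numeric matrix with identical row/column
#'   names, or `NULL` for BLOSUM62.
#' @param gap_open,gap_extend Negative integers;
#'   `gap_open <= gap_extend < 0`.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(substitution = NULL, gap_open = -11L,
                           gap_extend = -1L) {
  if (is.null(substitution)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    substitution <- e$BLOSUM62
  }
  if (!is.matrix(substitution) ||
      !identical(rownames(substitution), colnames(substitution)))
    abort_validation("scoring_scheme: substitution must be a named square matrix")
  if (!isTRUE(all.equal(substitution, t(substitution))))
    abort_validation("scoring_scheme: substitution matrix must be symmetric")
  if (!(gap_open <= gap_extend && gap_extend < 0))
    abort_validation("scoring_scheme: need gap_open <= gap_extend < 0")
  if (!MASK_SYMBOL %in% rownames(substitution)) {
    n <- nrow(substitution)
    substitution <- rbind(cbind(substitution, rep(MASK_SCORE, n)),
                          rep(MASK_SCORE, n + 1L))
    rownames(substitution)[n + 1L] <- MASK_SYMBOL
    colnames(substitution)[n + 1L] <- MASK_SYMBOL
  }
  structure(list(substitution = substitution,
                 gap_open = as.numeric(gap_open),
                 gap_extend = as.numeric(gap_extend)),
            class = "scoring_scheme")
}

encode_protein <- function(residues, scheme, what = "sequence") {
  symbols <- strsplit(toupper(residues), "", fixed = TRUE)[[1L]]
  codes <- match(symbols, rownames(scheme$substitution))
  if (anyNA(codes))
    abort_validation("%s contains symbol '%s' absent from the scoring scheme",
                     what, symbols[which(is.na(codes))[1L]])
  codes
}

#' Length screen for candidate fusion proteins
#'
#' Keeps proteins strictly longer than `min_len` residues — sequences
#' long enough to harbor more than one copy of a ~400-residue domain.
#'
#' @param proteins List of [seq_record()]s.
#' @param min_len Length threshold (default 500; strict `>`).
#' @return The surviving subset, order preserved.
#' @export
screen_by_length <- function(proteins, min_len = 500L) {
  if (!length(proteins)) return(proteins)
  proteins[vapply(proteins, record_length, integer(1)) > min_len]
}

#' Optimal local alignment of two proteins
#'
#' Smith-Waterman with affine gaps. Ties between equal-scoring optimal
#' alignments are broken towards the smallest subject start, then the
#' smallest query start.
#'
#' @param query,subject Protein [seq_record()]s.
#' @param scheme A [scoring_scheme()].
#' @return List with `score` and the 1-based inclusive hit coordinates
#'   `query_start`, `query_end`, `subject_start`, `subject_end` (all
#'   `NA` with `score = 0` when no positive-scoring alignment exists).
#' @export
local_align <- function(query, subject, scheme = scoring_scheme()) {
  qc <- encode_protein(query$residues, scheme, paste0("query '", query$id, "'"))
  sc <- encode_protein(subject$residues, scheme,
                       paste0("subject '", subject$id, "'"))
  .sw_align(qc, sc, scheme$substitution, scheme$gap_open, scheme$gap_extend)
}

self_score <- function(record, scheme) {
  codes <- encode_protein(record$residues, scheme, record$id)
  sum(scheme$substitution[cbind(codes, codes)])
}

#' Count domain copies in a protein by iterative local alignment
#'
#' Repeatedly aligns the single-domain reference against the protein;
#' each hit scoring at least `min_score_fraction` of the reference's
#' self-score is recorded and its subject interval masked with a
#' sentinel that cannot align, then the search repeats until no further
#' hit clears the threshold. The recorded hits are therefore
#' non-overlapping and `copy_count` is the number of domain copies —
#' 2 or 3 for the duplicated/triplicated fusion candidates.
#'
#' @param domain_ref Single-domain reference protein ([seq_record()]).
#' @param protein Protein to screen.
#' @param scheme A [scoring_scheme()].
#' @param min_score_fraction Acceptance threshold as a fraction of the
#'   reference self-score (default 0.3).
#' @return An object of class `repeat_scan`: list with `protein_id`,
#'   `copy_count`, `hits` (data.frame `subject_start`, `subject_end`,
#'   `score`, sorted by subject start, 1-based inclusive),
#'   `min_score_fraction` and `ref_self_score`.
#' @export
count_domain_copies <- function(domain_ref, protein,
                                scheme = scoring_scheme(),
                                min_score_fraction = 0.3) {
  if (min_score_fraction <= 0 || min_score_fraction > 1)
    abort_validation("count_domain_copies: min_score_fraction in (0,1]")
  ref_score <- self_score(domain_ref, scheme)
  threshold <- min_score_fraction * ref_score
  masked <- protein$residues
  hits <- list()
  repeat {
    subj <- seq_record(protein$id, masked, alphabet = "protein")
    hit <- local_align(domain_ref, subj, scheme)
    if (hit$score < threshold || is.na(hit$subject_start)) break
    hits[[length(hits) + 1L]] <- data.frame(
      subject_start = hit$subject_start, subject_end = hit$subject_end,
      score = hit$score)
    substr(masked, hit$subject_start, hit$subject_end) <-
      strrep(MASK_SYMBOL, hit$subject_end - hit$subject_start + 1L)
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(subject_start = integer(0), subject_end = integer(0),
               score = numeric(0))
  hits <- hits[order(hits$subject_start), , drop = FALSE]
  rownames(hits) <- NULL
  structure(list(protein_id = protein$id, copy_count = nrow(hits),
                 hits = hits, min_score_fraction = min_score_fraction,
                 ref_self_score = ref_score),
            class = "repeat_scan")
}

#' @export
print.repeat_scan <- function(x, ...) {
  cat(sprintf("<repeat_scan> %s: %d domain cop%s (threshold %.0f = %.2f x %0.f)\n",
              x$protein_id, x$copy_count,
              if (x$copy_count == 1L) "y" else "ies",
              x$min_score_fraction * x$ref_self_score,
              x$min_score_fraction, x$ref_self_score))
  if (nrow(x$hits))
    for (i in seq_len(nrow(x$hits)))
      cat(sprintf("  hit %d: subject %d-%d, score %.0f\n", i,
                  x$hits$subject_start[i], x$hits$subject_end[i],
                  x$hits$score[i]))
  invisible(x)
}

#' Check conservation of the catalytic Cys-His-Asn triad
#'
#' Globally aligns the reference (affine gaps, same scheme) against the
#' subject and maps each reference triad column to the subject. The
#' triad is conserved iff all three mapped positions exist (are not
#' gapped) and carry Cysteine, Histidine and Asparagine respectively.
#'
#' @param reference Protein [seq_record()] with C, H, N at
#'   `ref_triad_positions`.
#' @param ref_triad_positions Integer vector of three 1-based positions.
#' @param subject Protein [seq_record()] to check.
#' @param scheme A [scoring_scheme()].
#' @return An object of class `triad_result`: list with
#'   `positions_in_subject` (1-based, `NA` where gapped), `residues`
#'   (subject residues or `NA`) and `conserved` (logical).
#' @export
check_triad <- function(reference, ref_triad_positions, subject,
                        scheme = scoring_scheme()) {
  pos <- as.integer(ref_triad_positions)
  if (length(pos) != 3L || anyNA(pos) || any(pos < 1L) ||
      any(pos > record_length(reference)))
    abort_validation("check_triad: need three valid reference positions")
  ref_res <- strsplit(reference$residues, "")[[1L]][pos]
  if (!identical(ref_res, c("C", "H", "N")))
    abort_validation(
      "check_triad: reference residues at triad positions are %s, not C/H/N",
      paste(ref_res, collapse = ""))
  rc <- encode_protein(reference$residues, scheme, "reference")
  sc <- encode_protein(subject$residues, scheme, "subject")
  aln <- .nw_align(rc, sc, scheme$substitution, scheme$gap_open,
                   scheme$gap_extend)
  mapped <- aln$subject_map[pos]
  mapped[mapped == 0L] <- NA_integer_
  subj_res <- ifelse(is.na(mapped), NA_character_,
                     strsplit(subject$residues, "")[[1L]][mapped])
  conserved <- !anyNA(mapped) && identical(unname(subj_res), c("C", "H", "N"))
  structure(list(positions_in_subject = mapped, residues = subj_res,
                 conserved = conserved, score = aln$score),
            class = "triad_result")
}

#' @export
print.triad_result <- function(x, ...) {
  cat(sprintf("<triad_result> conserved=%s residues=%s at %s\n",
              x$conserved,
              paste(ifelse(is.na(x$residues), "-", x$residues), collapse = ""),
              paste(ifelse(is.na(x$positions_in_subject), "-",
                           x$positions_in_subject), collapse = ",")))
  invisible(x)
}
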