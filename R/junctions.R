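#' Junction-screening parameters
#'
#' Quantification of the qualitative curation criteria: a genuine intron
#' should be spanned by a number of split reads almost equivalent to the
#' coverage at the border of its flanking exons, while an artifactual
#' "intron" joining two tandem genes shows almost no connecting reads.
#'
#' @param theta_supported Link ratio at or above which an intron is
#'   `SUPPORTED` (default 0.5).
#' @param theta_unsupported Link ratio below which an intron is
#'   `UNSUPPORTED` (default 0.05).
#' @param min_edge_depth Minimal peak coverage both flanking exons must
#'   reach for the intron to be judged at all (default 10); below it the
#'   status is `NO_DATA`.
#' @param junction_slack Allowed bp deviation between an alignment gap
#'   and the annotated intron boundaries (default 0; real aligners may
#'   need 1-5).
#' @param edge_window Edge-window width passed to
#'   [exon_support_stats()] (default 10).
#' @param taper_terminal Taper ratio at or below which an exon end is
#'   recorded as "terminal-like" in the report notes (default 0.5).
#' @return An object of class `screen_params`.
#' @export
screen_params <- function(theta_supported = 0.5, theta_unsupported = 0.05,
                          min_edge_depth = 10L, junction_slack = 0L,
                          edge_window = 10L, taper_terminal = 0.5) {
  if (!(theta_unsupported >= 0 && theta_unsupported < theta_supported))
    abort_validation("screen_params: need 0 <= theta_unsupported < theta_supported")
  if (min_edge_depth < 1L)
    abort_validation("screen_params: min_edge_depth must be >= 1")
  structure(list(theta_supported = theta_supported,
                 theta_unsupported = theta_unsupported,
                 min_edge_depth = as.integer(min_edge_depth),
                 junction_slack = as.integer(junction_slack),
                 edge_window = as.integer(edge_window),
                 taper_terminal = taper_terminal),
            class = "screen_params")
}

#' Count reads spanning an annotated intron
#'
#' An alignment spans intron `i` when it contains a junction gap whose
#' boundaries match the intron's within `slack` bp and it has at least
#' one aligned base in a block on each side of that gap.
#'
#' @param gene A [gene_model()] with at least two exons.
#' @param intron_index 1-based ordinal of the intron (intron `i` lies
#'   between exons `i` and `i + 1`).
#' @param alignments List of [spliced_alignment()]s (subset to locus).
#' @param slack Allowed boundary deviation in bp.
#' @return Integer count of spanning reads.
#' @export
spanning_read_count <- function(gene, intron_index, alignments, slack = 0L) {
  introns <- gene_introns(gene)
  if (!length(introns))
    abort_validation("spanning_read_count: gene '%s' has < 2 exons",
                     gene$gene_id)
  if (intron_index < 1L || intron_index > length(introns))
    abort_validation("spanning_read_count: intron_index %d out of range",
                     intron_index)
  intr <- introns[[intron_index]]
  n <- 0L
  for (a in alignments) {
    if (!identical(a$seq_id, gene$seq_id)) next
    g <- alignment_gaps(a)
    if (!nrow(g)) next
    hit <- abs(g[, "start"] - intr$start) <= slack &
      abs(g[, "end"] - intr$end) <= slack
    ## a gap is always flanked by >= 1-base blocks by construction
    if (any(hit)) n <- n + 1L
  }
  n
}

#' Classify the introns of a gene model
#'
#' For each annotated intron the split-read support is compared with the
#' coverage at the borders of the flanking exons:
#' `link_ratio = spanning_reads / min(left_edge_cov, right_edge_cov)`
#' (0 when no read spans the intron). Status is `SUPPORTED` when the
#' ratio reaches `theta_supported`, `UNSUPPORTED` below
#' `theta_unsupported`, `WEAK` in between.
#'
#' Data adequacy is judged on the peak (maximum per-position) coverage
#' of the two flanking exons: when either peak is below
#' `min_edge_depth` the locus is too shallow to expect spanning reads
#' and the status is `NO_DATA`. The peak is used deliberately instead of
#' the edge windows: at a genuine gene boundary inside a fused model the
#' edge coverage tapers towards zero even at high depth, and an
#' edge-based guard would discard exactly the evidence that exposes the
#' fusion.
#'
#' @param gene A [gene_model()].
#' @param track Coverage computed from the same filtered alignments.
#' @param alignments The filtered, locus-subset alignments.
#' @param params A [screen_params()].
#' @return Data.frame with one row per intron: `intron_index`, `start`,
#'   `end`, `spanning_reads`, `left_edge_cov`, `right_edge_cov`,
#'   `flank_peak_cov`, `link_ratio`, `status`. Zero rows for single-exon
#'   genes.
#' @export
classify_introns <- function(gene, track, alignments,
                             params = screen_params()) {
  introns <- gene_introns(gene)
  if (!length(introns))
    return(data.frame(intron_index = integer(0), start = integer(0),
                      end = integer(0), spanning_reads = integer(0),
                      left_edge_cov = numeric(0), right_edge_cov = numeric(0),
                      flank_peak_cov = numeric(0), link_ratio = numeric(0),
                      status = character(0)))
  ex <- exon_support_stats(track, gene, edge_window = params$edge_window)
  rows <- lapply(seq_along(introns), function(i) {
    intr <- introns[[i]]
    left <- ex$right_edge_cov[i]        # right edge of upstream exon
    right <- ex$left_edge_cov[i + 1L]   # left edge of downstream exon
    peak <- min(ex$max_cov[i], ex$max_cov[i + 1L])
    span <- spanning_read_count(gene, i, alignments,
                                slack = params$junction_slack)
    if (peak < params$min_edge_depth) {
      status <- "NO_DATA"; ratio <- NA_real_
    } else {
      ratio <- if (span == 0L) 0 else span / min(left, right)
      status <- if (ratio >= params$theta_supported) "SUPPORTED"
      else if (ratio < params$theta_unsupported) "UNSUPPORTED"
      else "WEAK"
    }
    data.frame(intron_index = i, start = intr$start, end = intr$end,
               spanning_reads = span, left_edge_cov = left,
               right_edge_cov = right, flank_peak_cov = peak,
               link_ratio = ratio, status = status)
  })
  do.call(rbind, rows)
}

#' Screen a gene model for annotation fusion artifacts
#'
#' Issues a per-gene verdict from the intron classification:
#' `LIKELY_FUSION` when at least one intron is `UNSUPPORTED` (those
#' introns become the proposed split points), `INSUFFICIENT_DATA` when
#' every intron is `NO_DATA`, otherwise `CONSISTENT`. Single-exon genes
#' are trivially `CONSISTENT`. For each split intron the notes record
#' whether the flanking exon ends look terminal (taper at or below
#' `taper_terminal`), the corroborating signal of coverage continuously
#' dropping towards a gene end.
#'
#' @inheritParams classify_introns
#' @return An object of class `fusion_report`: list with `gene_id`,
#'   `verdict`, `intron_evidence` (see [classify_introns()]),
#'   `exon_evidence` (see [exon_support_stats()]), `split_introns`
#'   (integer ordinals) and `notes` (character).
#' @export
screen_gene <- function(gene, track, alignments, params = screen_params()) {
  if (!identical(gene$seq_id, track$seq_id))
    abort_validation("screen_gene: gene on '%s' but track is '%s'",
                     gene$seq_id, track$seq_id)
  bad <- vapply(alignments, function(a)
    !identical(a$seq_id, gene$seq_id), logical(1))
  if (length(alignments) && all(bad))
    abort_validation("screen_gene: no alignment is on '%s'", gene$seq_id)
  intron_ev <- classify_introns(gene, track, alignments, params)
  exon_ev <- exon_support_stats(track, gene, edge_window = params$edge_window)
  splits <- intron_ev$intron_index[intron_ev$status == "UNSUPPORTED"]
  verdict <- if (length(splits)) "LIKELY_FUSION"
  else if (nrow(intron_ev) > 0L && all(intron_ev$status == "NO_DATA"))
    "INSUFFICIENT_DATA"
  else "CONSISTENT"
  notes <- character(0)
  for (i in splits) {
    up_term <- exon_ev$right_taper[i] <= params$taper_terminal
    down_term <- exon_ev$left_taper[i + 1L] <= params$taper_terminal
    notes <- c(notes, sprintf(
      "intron %d: upstream exon end %s, downstream exon start %s (taper <= %.2f)",
      i,
      if (up_term) "terminal-like" else "not terminal-like",
      if (down_term) "terminal-like" else "not terminal-like",
      params$taper_terminal))
  }
  structure(list(gene_id = gene$gene_id, verdict = verdict,
                 intron_evidence = intron_ev, exon_evidence = exon_ev,
                 split_introns = as.integer(splits), notes = notes,
                 params = params),
            class = "fusion_report")
}

#' @export
print.fusion_report <- function(x, ...) {
  cat(sprintf("<fusion_report> %s: %s\n", x$gene_id, x$verdict))
  if (length(x$split_introns))
    cat("  proposed splits at intron(s):",
        paste(x$split_introns, collapse = ", "), "\n")
  if (nrow(x$intron_evidence)) {
    cat(sprintf("  introns: %s\n",
                paste(sprintf("%d:%s(n=%d)", x$intron_evidence$intron_index,
                              x$intron_evidence$status,
                              x$intron_evidence$spanning_reads),
                      collapse = " ")))
  }
  invisible(x)
}

#' Partition a flagged gene model at its split introns
#'
#' Cuts the exon list at every split intron of the report and emits one
#' gene model per segment, ids `"<gene_id>.split1"`, `"<gene_id>.split2"`,
#' ... with strand inherited. Without splits the original model is
#' returned unchanged as a single-element list.
#'
#' @param gene The screened [gene_model()].
#' @param report Its [screen_gene()] report.
#' @return List of [gene_model()]s.
#' @export
propose_splits <- function(gene, report) {
  if (!identical(report$gene_id, gene$gene_id))
    abort_validation("propose_splits: report is for '%s', gene is '%s'",
                     report$gene_id, gene$gene_id)
  splits <- sort(report$split_introns)
  if (!length(splits)) return(list(gene))
  n <- length(gene$exons)
  seg_start <- c(1L, splits + 1L)
  seg_end <- c(splits, n)
  lapply(seq_along(seg_start), function(s)
    gene_model(sprintf("%s.split%d", gene$gene_id, s), gene$seq_id,
               gene$strand, gene$exons[seg_start[s]:seg_end[s]]))
}
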