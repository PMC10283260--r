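#' Mapping-stringency filter parameters
#'
#' Defaults mirror the stringent spliced-mapping settings commonly used
#' for gene-model evaluation: minimal similarity 95% and minimal aligned
#' fraction 90% of the read length. Both bounds are inclusive.
#'
#' @param min_identity Minimal alignment identity, fraction in `[0,1]`.
#' @param min_aligned_fraction Minimal `aligned_length / read_length`,
#'   fraction in `[0,1]`.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(min_identity = 0.95, min_aligned_fraction = 0.90) {
  if (min_identity < 0 || min_identity > 1 ||
      min_aligned_fraction < 0 || min_aligned_fraction > 1)
    abort_validation("filter_params: thresholds must lie in [0,1]")
  structure(list(min_identity = min_identity,
                 min_aligned_fraction = min_aligned_fraction),
            class = "filter_params")
}

#' Filter alignments by identity and aligned fraction
#'
#' Keeps records with `identity >= min_identity` and
#' `aligned_length / read_length >= min_aligned_fraction` (inclusive
#' boundaries); input order is preserved.
#'
#' @param alignments List of [spliced_alignment()]s.
#' @param params A [filter_params()].
#' @return The surviving subset, order preserved.
#' @export
filter_alignments <- function(alignments, params = filter_params()) {
  if (!length(alignments)) return(alignments)
  rl <- vapply(alignments, `[[`, integer(1), "read_length")
  if (any(rl == 0L)) abort_validation("filter_alignments: read_length 0")
  keep <- vapply(alignments, function(a)
    a$identity >= params$min_identity &&
      a$aligned_length / a$read_length >= params$min_aligned_fraction,
    logical(1))
  alignments[keep]
}

#' Subset alignments to a locus of interest
#'
#' Keeps records whose aligned blocks overlap the interval by at least
#' one base — the in-memory analog of extracting all reads mapped to a
#' locus from each sample's alignment file and merging the subsets.
#'
#' @param alignments List of [spliced_alignment()]s.
#' @param interval A [genomic_interval()].
#' @return The overlapping subset (possibly empty), order preserved.
#' @export
subset_alignments <- function(alignments, interval) {
  if (!length(alignments)) return(alignments)
  keep <- vapply(alignments, function(a) {
    identical(a$seq_id, interval$seq_id) &&
      any(a$block_start < interval$end & a$block_end > interval$start)
  }, logical(1))
  alignments[keep]
}

#' Compute a per-position coverage track
#'
#' `counts[p]` is the number of alignments with position `p` inside one
#' of their blocks; junction gaps (`N`) contribute nothing. Each SAM
#' record counts once per covered position (reads, not fragments).
#'
#' @param alignments List of [spliced_alignment()]s, all on `seq_id`.
#' @param seq_id Reference sequence name.
#' @param seq_len Reference length (track length).
#' @return A [coverage_track()] of length `seq_len`.
#' @export
compute_coverage <- function(alignments, seq_id, seq_len) {
  seq_len <- as.integer(seq_len)
  ## difference-array accumulation: +1 at block starts, -1 at block ends
  delta <- integer(seq_len + 1L)
  for (a in alignments) {
    if (!identical(a$seq_id, seq_id))
      abort_validation("compute_coverage: read '%s' is on '%s', not '%s'",
                       a$read_id, a$seq_id, seq_id)
    if (max(a$block_end) > seq_len)
      abort_validation("compute_coverage: read '%s' extends past %d",
                       a$read_id, seq_len)
    for (j in seq_along(a$block_start)) {
      delta[a$block_start[j] + 1L] <- delta[a$block_start[j] + 1L] + 1L
      delta[a$block_end[j] + 1L] <- delta[a$block_end[j] + 1L] - 1L
    }
  }
  coverage_track(seq_id, cumsum(delta[seq_len(seq_len)]))
}

#' Per-exon coverage support statistics
#'
#' For each exon of a gene model: mean/median coverage, edge coverages
#' (mean over the outermost `min(edge_window, exon_length)` positions on
#' the 5'-most and 3'-most genomic side), taper ratios
#' `edge_cov / body_cov` (body = exon minus both edge windows; the whole
#' exon when shorter than `3 * edge_window`), the fraction of positions
#' with coverage >= 1, and the per-position maximum. A coasting gene end
#' shows a taper well below 1; an internal splice site keeps edge
#' coverage close to the body. Zero-coverage exons yield taper 0 with
#' `insufficient = TRUE` rather than an error.
#'
#' @param track A [coverage_track()].
#' @param gene A [gene_model()] on the track's sequence.
#' @param edge_window Width of the edge windows in bp (default 10).
#' @return A data.frame with one row per exon: `exon_index`, `start`,
#'   `end`, `mean_cov`, `median_cov`, `max_cov`, `left_edge_cov`,
#'   `right_edge_cov`, `left_taper`, `right_taper`, `supported_fraction`,
#'   `insufficient`.
#' @export
exon_support_stats <- function(track, gene, edge_window = 10L) {
  if (!identical(gene$seq_id, track$seq_id))
    abort_validation("exon_support_stats: gene on '%s', track is '%s'",
                     gene$seq_id, track$seq_id)
  edge_window <- as.integer(edge_window)
  if (edge_window < 1L)
    abort_validation("exon_support_stats: edge_window must be >= 1")
  rows <- lapply(seq_along(gene$exons), function(i) {
    e <- gene$exons[[i]]
    if (e$end > track$length)
      abort_validation("exon_support_stats: exon %d outside track", i)
    cov <- track$counts[(e$start + 1L):e$end]
    len <- length(cov)
    w <- min(edge_window, len)
    left <- mean(cov[seq_len(w)])
    right <- mean(cov[(len - w + 1L):len])
    body <- if (len < 3L * edge_window) cov else
      cov[(edge_window + 1L):(len - edge_window)]
    body_mean <- mean(body)
    taper <- function(edge) {
      if (body_mean == 0) 0 else edge / body_mean
    }
    data.frame(
      exon_index = i, start = e$start, end = e$end,
      mean_cov = mean(cov), median_cov = stats::median(cov),
      max_cov = max(cov),
      left_edge_cov = left, right_edge_cov = right,
      left_taper = taper(left), right_taper = taper(right),
      supported_fraction = mean(cov >= 1L),
      insufficient = body_mean == 0)
  })
  do.call(rbind, rows)
}
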