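#' Gene-model-focused coverage plot
#'
#' Draws the per-position aligned-read count around a gene of interest
#' (gene span plus `window` bp on each side, clipped to the track) with
#' the exon intervals as boxes under the curve — high coverage marks
#' exons, near-zero coverage marks introns, and a continuous drop
#' towards an exon end marks a gene boundary. The device is chosen from
#' the file extension (`.png`, `.svg` or `.pdf`). A machine-readable
#' sidecar TSV (`<path>.tsv`) records exactly the positions and counts
#' drawn, so the figure is testable without image comparison.
#'
#' @param track A [coverage_track()].
#' @param gene A [gene_model()] within the track.
#' @param window Flanking window in bp (default 500).
#' @param path Output figure path.
#' @return Invisibly, the data.frame written to the sidecar TSV.
#' @export
plot_gene_coverage <- function(track, gene, window = 500L, path) {
  if (!identical(gene$seq_id, track$seq_id))
    abort_validation("plot_gene_coverage: gene on '%s' but track is '%s'",
                     gene$seq_id, track$seq_id)
  span <- gene_span(gene)
  if (span$end > track$length)
    abort_validation("plot_gene_coverage: gene extends past the track")
  check_path_writable(path)
  from0 <- max(0L, span$start - as.integer(window))
  to0 <- min(track$length, span$end + as.integer(window))
  pos1 <- (from0 + 1L):to0
  dat <- data.frame(position = pos1, count = track$counts[pos1])

  ext <- tolower(sub(".*\\.", "", path))
  dev <- switch(ext,
                png = function(p) grDevices::png(p, width = 900, height = 420),
                svg = function(p) grDevices::svg(p, width = 9, height = 4.2),
                pdf = function(p) grDevices::pdf(p, width = 9, height = 4.2),
                abort_validation("plot_gene_coverage: unsupported extension '%s'",
                                 ext))
  dev(path)
  on.exit(grDevices::dev.off())
  ymax <- max(1L, dat$count)
  graphics::plot(dat$position, dat$count, type = "h", col = "grey70",
                 xlab = sprintf("position on %s", track$seq_id),
                 ylab = "aligned reads", ylim = c(-0.08 * ymax, ymax),
                 main = gene$gene_id, bty = "l")
  graphics::lines(dat$position, dat$count, col = "steelblue4")
  for (e in gene$exons)
    graphics::rect(e$start + 1L, -0.07 * ymax, e$end, -0.02 * ymax,
                   col = "black", border = "black")
  intr <- gene_introns(gene)
  for (i in intr)
    graphics::segments(i$start + 1L, -0.045 * ymax, i$end, -0.045 * ymax,
                       col = "black", lty = 3)
  utils::write.table(dat, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(dat)
}
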