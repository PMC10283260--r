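#' Read gene models from a GFF3 file
#'
#' Parsing is delegated to [rtracklayer::import()]; this function groups
#' `exon` (or, where a transcript has no exons, `CDS`) features to their
#' parent transcript and gene via the `ID`/`Parent` attributes and
#' converts the 1-based inclusive GFF3 coordinates to the package's
#' 0-based half-open convention.
#'
#' When a gene carries several transcripts, the transcript with the
#' largest summed exon length is taken and a warning is emitted. A gene
#' without any exon/CDS children contributes its own span as a single
#' exon (with a warning).
#'
#' @param path Path to a GFF3 file.
#' @return List of [gene_model()] objects, in file order of the genes.
#' @export
read_gff3 <- function(path) {
  check_file_readable(path)
  gr <- tryCatch(
    suppressWarnings(rtracklayer::import(path, format = "gff3")),
    error = function(e) abort_format("GFF3 '%s': %s", path,
                                     conditionMessage(e)))
  if (!length(gr)) return(list())

  type <- as.character(gr$type)
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_,
                                                           length(gr))
  parents <- if (!is.null(gr$Parent)) gr$Parent else
    S4Vectors::splitAsList(character(0), factor(integer(0),
                                                levels = seq_along(gr)))
  first_parent <- vapply(as.list(parents), function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1))

  starts0 <- GenomicRanges::start(gr) - 1L
  ends0 <- GenomicRanges::end(gr)
  seqs <- as.character(GenomicRanges::seqnames(gr))
  strands <- as.character(GenomicRanges::strand(gr))
  strands[!strands %in% c("+", "-")] <- "+"

  is_gene <- type == "gene"
  is_tx <- type %in% c("mRNA", "transcript")
  is_part <- type %in% c("exon", "CDS")

  gene_ids <- ids[is_gene]
  if (anyNA(gene_ids))
    abort_format("GFF3 '%s': gene feature without ID attribute", path)
  gene_idx <- which(is_gene)
  tx2gene <- stats::setNames(first_parent[is_tx], ids[is_tx])

  models <- vector("list", length(gene_idx))
  for (g in seq_along(gene_idx)) {
    gi <- gene_idx[g]
    gid <- ids[gi]
    tx_of_gene <- ids[is_tx][!is.na(tx2gene) & tx2gene == gid]
    exon_sets <- list()
    if (length(tx_of_gene)) {
      for (tx in tx_of_gene) {
        sel <- which(is_part & type == "exon" & first_parent == tx)
        if (!length(sel))
          sel <- which(is_part & type == "CDS" & first_parent == tx)
        if (length(sel)) exon_sets[[tx]] <- sel
      }
    }
    ## exons attached directly to the gene
    direct <- which(is_part & first_parent == gid & type == "exon")
    if (!length(direct))
      direct <- which(is_part & first_parent == gid & type == "CDS")
    if (length(direct)) exon_sets[[gid]] <- direct

    if (!length(exon_sets)) {
      warning(sprintf(
        "read_gff3: gene '%s' has no exon/CDS children; using gene span",
        gid))
      sel <- gi
    } else {
      if (length(exon_sets) > 1L) {
        warning(sprintf(
          "read_gff3: gene '%s' has %d transcripts; keeping the longest",
          gid, length(exon_sets)))
        totals <- vapply(exon_sets, function(s)
          sum(ends0[s] - starts0[s]), numeric(1))
        sel <- exon_sets[[which.max(totals)]]
      } else sel <- exon_sets[[1L]]
    }
    if (any(ends0[sel] <= starts0[sel]))
      abort_format("GFF3 '%s': feature with end < start for gene '%s'",
                   path, gid)
    models[[g]] <- gene_model(
      gid, seqs[gi], strands[gi],
      cbind(starts0[sel], ends0[sel]))
  }

  ## orphan exons: exon/CDS whose parent is neither a known tx nor gene
  orphan <- is_part & !is.na(first_parent) &
    !(first_parent %in% c(ids[is_tx], gene_ids))
  if (any(orphan))
    abort_format("GFF3 '%s': exon with unresolvable Parent '%s'",
                 path, first_parent[orphan][1L])
  models
}

#' Write gene models to a GFF3 file
#'
#' Emits `gene` + `mRNA` + `exon` rows with `ID`/`Parent` attributes,
#' converting back to 1-based inclusive coordinates. Inverse of
#' [read_gff3()] for single-transcript models.
#'
#' @param models List of [gene_model()] objects.
#' @param path Output path.
#' @export
write_gff3 <- function(models, path) {
  check_path_writable(path)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (m in models) {
    span <- gene_span(m)
    tx_id <- paste0(m$gene_id, ".t1")
    row <- function(type, start0, end0, attrs)
      paste(m$seq_id, "fusionscreen", type, start0 + 1L, end0, ".",
            m$strand, ".", attrs, sep = "\t")
    writeLines(row("gene", span$start, span$end,
                   sprintf("ID=%s", m$gene_id)), con)
    writeLines(row("mRNA", span$start, span$end,
                   sprintf("ID=%s;Parent=%s", tx_id, m$gene_id)), con)
    for (i in seq_along(m$exons)) {
      e <- m$exons[[i]]
      writeLines(row("exon", e$start, e$end,
                     sprintf("ID=%s.exon%d;Parent=%s", tx_id, i, tx_id)),
                 con)
    }
  }
  invisible(NULL)
}
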