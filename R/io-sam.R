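#' Read spliced alignments from a SAM text file
#'
#' Each mapped record is decomposed into reference-aligned blocks and
#' junction gaps using the CIGAR machinery of the GenomicAlignments
#' package: blocks are maximal runs of reference-consuming non-`N`
#' operations (`M`, `=`, `X`, `D`), split at every `N`; the `N`
#' operations become the gaps. Deletions (`D`) stay inside blocks — a
#' deleted base is still physically spanned by the read. Unmapped
#' records are skipped.
#'
#' Identity is `1 - NM / aligned_length` when the `NM:i:` tag is
#' present, else 1.0 (a notice reports how many records lacked the tag).
#'
#' @param path Path to a SAM file (text, with header).
#' @return List of [spliced_alignment()]s, with attribute `seq_lengths`
#'   (named integer vector from the `@SQ` header lines).
#' @export
read_sam <- function(path) {
  check_file_readable(path)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]

  sq <- hdr[startsWith(hdr, "@SQ")]
  seq_lengths <- integer(0)
  if (length(sq)) {
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    seq_lengths <- stats::setNames(ln, sn)
  }
  if (!length(body))
    return(structure(list(), seq_lengths = seq_lengths))

  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 11L)
  if (length(bad))
    abort_format("SAM '%s': record %d has fewer than 11 fields", path, bad[1L])

  qname <- vapply(fields, `[[`, character(1), 1L)
  flag <- as.integer(vapply(fields, `[[`, character(1), 2L))
  rname <- vapply(fields, `[[`, character(1), 3L)
  pos <- as.integer(vapply(fields, `[[`, character(1), 4L))
  cigar <- vapply(fields, `[[`, character(1), 6L)

  mapped <- !bitwAnd(flag, 4L) & rname != "*" & cigar != "*" & pos > 0L
  if (!any(mapped))
    return(structure(list(), seq_lengths = seq_lengths))

  keep <- which(mapped)
  cig <- cigar[keep]
  bad_op <- grepl("[^0-9MIDNSH=X]", cig)
  if (any(bad_op))
    abort_format("SAM '%s': unsupported CIGAR op in read '%s' (%s)",
                 path, qname[keep][which(bad_op)[1L]],
                 cig[which(bad_op)[1L]])
  malformed <- !grepl("^([0-9]+[MIDNSH=X])+$", cig)
  if (any(malformed))
    abort_format("SAM '%s': malformed CIGAR for read '%s' (%s)",
                 path, qname[keep][which(malformed)[1L]],
                 cig[which(malformed)[1L]])

  blocks <- GenomicAlignments::extractAlignmentRangesOnReference(
    cig, pos = pos[keep], drop.D.ranges = FALSE)
  alen <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cig, after.soft.clipping = TRUE)
  rlen <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cig, after.soft.clipping = FALSE)

  ## NM tag from the optional fields
  nm <- vapply(fields[keep], function(f) {
    if (length(f) > 11L) {
      hit <- grep("^NM:i:", f[12:length(f)], value = TRUE)
      if (length(hit)) return(as.integer(sub("^NM:i:", "", hit[1L])))
    }
    NA_integer_
  }, integer(1))
  n_missing <- sum(is.na(nm))
  if (n_missing)
    fus_log("read_sam: %d record(s) without NM tag; identity assumed 1.0",
            n_missing, level = "NOTE")

  out <- vector("list", length(keep))
  bl <- as.list(blocks)
  for (i in seq_along(keep)) {
    r <- bl[[i]]
    identity <- if (is.na(nm[i]) || alen[i] == 0L) 1.0 else
      max(0, 1 - nm[i] / alen[i])
    out[[i]] <- spliced_alignment(
      read_id = qname[keep[i]], seq_id = rname[keep[i]],
      block_start = IRanges::start(r) - 1L, block_end = IRanges::end(r),
      aligned_length = alen[i], read_length = rlen[i],
      identity = identity)
  }
  structure(out, seq_lengths = seq_lengths)
}

#' Write spliced alignments to a SAM text file
#'
#' Blocks and gaps are encoded as `M` and `N` CIGAR operations; any
#' unaligned remainder of the read (`read_length - aligned_length`) is
#' emitted as a trailing soft clip so that [read_sam()] round-trips
#' blocks, gaps, `aligned_length` and `read_length` exactly. The number
#' of mismatches implied by `identity` is written as an `NM:i:` tag.
#'
#' @param alignments List of [spliced_alignment()]s.
#' @param seq_lengths Named integer vector mapping every `seq_id` used to
#'   its reference length (becomes the `@SQ` header).
#' @param path Output path.
#' @export
write_sam <- function(alignments, seq_lengths, path) {
  check_path_writable(path)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (sn in names(seq_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", sn,
                       as.integer(seq_lengths[[sn]])), con)
  for (aln in alignments) {
    if (!aln$seq_id %in% names(seq_lengths))
      abort_validation("write_sam: unknown seq_id '%s' for read '%s'",
                       aln$seq_id, aln$read_id)
    if (max(aln$block_end) > seq_lengths[[aln$seq_id]])
      abort_validation("write_sam: read '%s' extends past end of '%s'",
                       aln$read_id, aln$seq_id)
    nb <- length(aln$block_start)
    widths <- aln$block_end - aln$block_start
    ops <- sprintf("%dM", widths)
    if (nb > 1L) {
      gaps <- aln$block_start[-1L] - aln$block_end[-nb]
      ops <- c(rbind(ops[-nb], sprintf("%dN", gaps)), ops[nb])
    }
    clip <- aln$read_length - aln$aligned_length
    cig <- paste0(paste(ops, collapse = ""),
                  if (clip > 0L) sprintf("%dS", clip) else "")
    nm <- as.integer(round((1 - aln$identity) * aln$aligned_length))
    writeLines(paste(aln$read_id, 0L, aln$seq_id,
                     aln$block_start[1L] + 1L, 255L, cig, "*", 0L, 0L,
                     "*", "*", sprintf("NM:i:%d", nm), sep = "\t"), con)
  }
  invisible(NULL)
}
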