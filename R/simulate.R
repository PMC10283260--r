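## Seeded simulator of a truth-known tandem gene array: the fixture that
## stands in for a real genome with a mis-annotated paralog cluster.

SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

#' Simulation configuration
#'
#' The stated world: a tandem array of `n_copies` paralogous two-exon
#' genes (the usual chalcone-synthase gene structure) with unequal
#' per-gene expression, annotated both correctly (separate genes) and as
#' one fused model, plus a genuine multi-exon control gene elsewhere on
#' the sequence. Reads span true introns but never the intergenic
#' spacers.
#'
#' @param n_copies Number of tandem gene copies (default 3).
#' @param exons_per_gene Exons per tandem gene (default 2).
#' @param exon_len Exon length in bp (default 200).
#' @param intron_len Intron length in bp (default 150).
#' @param spacer_len Intergenic spacer length in bp (default 500).
#' @param copy_divergence Per-position substitution rate between the
#'   ancestor and each copy, in `[0, 0.3]` (default 0.05).
#' @param depths Per-gene target mean exonic coverages (default
#'   `c(50, 10, 80)`, deliberately unequal).
#' @param read_len Read length in bp (default 100).
#' @param error_rate Per-base sequencing substitution rate (default 0).
#' @param seed Integer seed; every simulator output is bit-reproducible
#'   per seed.
#' @param control_depth Coverage of the control gene (default 50, a
#'   moderately expressed gene).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_copies = 3L, exons_per_gene = 2L, exon_len = 200L,
                       intron_len = 150L, spacer_len = 500L,
                       copy_divergence = 0.05, depths = c(50, 10, 80),
                       read_len = 100L, error_rate = 0, seed = 1L,
                       control_depth = 50) {
  cfg <- list(n_copies = as.integer(n_copies),
              exons_per_gene = as.integer(exons_per_gene),
              exon_len = as.integer(exon_len),
              intron_len = as.integer(intron_len),
              spacer_len = as.integer(spacer_len),
              copy_divergence = copy_divergence,
              depths = as.numeric(depths),
              read_len = as.integer(read_len),
              error_rate = error_rate,
              seed = as.integer(seed),
              control_depth = as.numeric(control_depth))
  if (cfg$n_copies < 1L || cfg$exons_per_gene < 1L || cfg$exon_len < 1L ||
      cfg$intron_len < 1L || cfg$spacer_len < 1L || cfg$read_len < 1L)
    abort_validation("sim_config: all counts/lengths must be >= 1")
  if (length(cfg$depths) != cfg$n_copies)
    abort_validation("sim_config: depths must have one entry per copy")
  if (cfg$copy_divergence < 0 || cfg$copy_divergence > 0.3)
    abort_validation("sim_config: copy_divergence must lie in [0, 0.3]")
  if (cfg$error_rate < 0 || cfg$error_rate > 1)
    abort_validation("sim_config: error_rate must lie in [0, 1]")
  if (cfg$read_len > cfg$exons_per_gene * cfg$exon_len)
    abort_validation("sim_config: read_len exceeds the mature mRNA length")
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

## positions (1-based, within the spliced mRNA) of the triad codons
triad_codon_positions <- function(n_codons) {
  aa <- unique(pmax(1L, pmin(n_codons, round(c(0.30, 0.60, 0.85) * n_codons))))
  if (length(aa) != 3L)
    abort_validation("sim: mRNA too short to place a distinct triad")
  aa
}

#' Build a truth-known tandem gene locus
#'
#' Deterministic under `config$seed`. An ancestor two-exon gene is drawn
#' with exonic sequence assembled from sense codons (no in-frame stops)
#' and a Cys/His/Asn catalytic triad written at three fixed codon
#' positions; introns get canonical `GT..AG` ends. Each tandem copy is
#' the ancestor mutated at `copy_divergence` (substitutions only; triad
#' codons are exempt and substitutions that would create an in-frame
#' stop are redrawn, mimicking purifying selection). The genome is
#' `spacer + copy1 + spacer + ... + copyN + spacer + control + spacer`.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_truth`: list with `genome`
#'   ([seq_record()]), `true_models`, `fused_model`, `control_model`
#'   ([gene_model()]s), `junction_read_tally` (zero-initialised
#'   data.frame `gene_id`/`intron_index`/`count`), `proteins` (translated
#'   single-domain paralogs plus the concatenated fusion decoy),
#'   `domain_ref` (translated ancestor, the bundled synthetic
#'   single-domain reference), `triad_positions` (1-based residue
#'   positions) and `config`.
#' @export
build_tandem_locus <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  E <- config$exons_per_gene; el <- config$exon_len; il <- config$intron_len

  mrna_len <- E * el
  n_codons <- mrna_len %/% 3L
  leftover <- mrna_len - 3L * n_codons
  triad_aa <- triad_codon_positions(n_codons)
  codons <- sample(SENSE_CODONS, n_codons, replace = TRUE)
  codons[triad_aa] <- c("TGC", "CAC", "AAC")  # Cys, His, Asn
  anc_mrna <- paste0(paste(codons, collapse = ""),
                     if (leftover) random_dna(leftover) else "")
  ## triad nucleotide positions within the mRNA (1-based)
  triad_nt <- as.vector(vapply(triad_aa, function(a)
    (3L * (a - 1L) + 1L):(3L * a), integer(3)))

  make_intron <- function() {
    if (il >= 4L) paste0("GT", random_dna(il - 4L), "AG") else random_dna(il)
  }
  anc_introns <- vapply(seq_len(max(E - 1L, 0L)), function(i) make_intron(),
                        character(1))

  ## assemble ancestor gene; record, per genomic position within the
  ## gene, the corresponding mRNA position (NA inside introns)
  gene_parts <- character(0)
  mrna_of_pos <- integer(0)
  off <- 0L
  for (e in seq_len(E)) {
    gene_parts <- c(gene_parts, substr(anc_mrna, off + 1L, off + el))
    mrna_of_pos <- c(mrna_of_pos, (off + 1L):(off + el))
    off <- off + el
    if (e < E) {
      gene_parts <- c(gene_parts, anc_introns[e])
      mrna_of_pos <- c(mrna_of_pos, rep(NA_integer_, il))
    }
  }
  anc_gene <- paste(gene_parts, collapse = "")
  gene_len <- nchar(anc_gene)

  mutate_copy <- function() {
    chars <- strsplit(anc_gene, "")[[1L]]
    hit <- which(stats::runif(gene_len) < config$copy_divergence)
    for (p in hit) {
      mp <- mrna_of_pos[p]
      if (!is.na(mp) && mp %in% triad_nt) next  # triad conserved
      alts <- setdiff(c("A", "C", "G", "T"), chars[p])
      if (!is.na(mp) && mp <= 3L * n_codons) {
        ## avoid creating an in-frame stop codon
        cod_i <- (mp - 1L) %/% 3L
        cod_pos <- cod_i * 3L + c(1L, 2L, 3L)
        within <- mp - cod_i * 3L
        ok <- vapply(alts, function(b) {
          cod <- chars[match(cod_pos, mrna_of_pos)]
          cod[within] <- b
          !paste(cod, collapse = "") %in% c("TAA", "TAG", "TGA")
        }, logical(1))
        alts <- alts[ok]
        if (!length(alts)) next
      }
      chars[p] <- sample(alts, 1L)
    }
    paste(chars, collapse = "")
  }

  copies <- vapply(seq_len(config$n_copies), function(i) mutate_copy(),
                   character(1))

  ## control gene: genuine 3-exon gene elsewhere on the sequence
  ctrl_exons <- 3L
  ctrl_gene <- paste(vapply(seq_len(2L * ctrl_exons - 1L), function(i)
    if (i %% 2L == 1L) random_dna(el) else make_intron(),
    character(1)), collapse = "")

  spacers <- vapply(seq_len(config$n_copies + 2L), function(i)
    random_dna(config$spacer_len), character(1))

  seq_id <- "sim_locus"
  pieces <- character(0); cursor <- 0L
  gene_starts <- integer(config$n_copies)
  for (i in seq_len(config$n_copies)) {
    pieces <- c(pieces, spacers[i]); cursor <- cursor + config$spacer_len
    gene_starts[i] <- cursor
    pieces <- c(pieces, copies[i]); cursor <- cursor + gene_len
  }
  pieces <- c(pieces, spacers[config$n_copies + 1L])
  cursor <- cursor + config$spacer_len
  ctrl_start <- cursor
  pieces <- c(pieces, ctrl_gene); cursor <- cursor + nchar(ctrl_gene)
  pieces <- c(pieces, spacers[config$n_copies + 2L])
  genome <- seq_record(seq_id, paste(pieces, collapse = ""),
                       alphabet = "nucleotide")

  exon_coords <- function(start0, n_ex) {
    t(vapply(seq_len(n_ex), function(e) {
      s <- start0 + (e - 1L) * (el + il)
      c(s, s + el)
    }, integer(2)))
  }
  true_models <- lapply(seq_len(config$n_copies), function(i)
    gene_model(sprintf("gene%d", i), seq_id, "+",
               exon_coords(gene_starts[i], E)))
  fused_exons <- do.call(rbind, lapply(true_models, function(m)
    t(vapply(m$exons, function(e) c(e$start, e$end), integer(2)))))
  fused_model <- gene_model("fused_gene", seq_id, "+", fused_exons)
  control_model <- gene_model("control_gene", seq_id, "+",
                              exon_coords(ctrl_start, ctrl_exons))

  translate_mrna <- function(dna, n_codons) {
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(dna, 1L, 3L * n_codons))))
  }
  copy_mrna <- vapply(copies, function(g)
    paste(substring(g, which(!is.na(mrna_of_pos)),
                    which(!is.na(mrna_of_pos))), collapse = ""),
    character(1), USE.NAMES = FALSE)
  copy_prot <- vapply(copy_mrna, translate_mrna, character(1),
                      n_codons = n_codons, USE.NAMES = FALSE)
  proteins <- c(
    lapply(seq_len(config$n_copies), function(i)
      seq_record(sprintf("gene%d_protein", i), copy_prot[i],
                 alphabet = "protein")),
    list(seq_record(sprintf("decoy_fusion_protein_x%d", config$n_copies),
                    paste(copy_prot, collapse = ""),
                    alphabet = "protein")))
  domain_ref <- seq_record("ancestor_domain_synthetic",
                           translate_mrna(anc_mrna, n_codons),
                           alphabet = "protein")

  all_models <- c(true_models, list(control_model))
  tally <- do.call(rbind, lapply(all_models, function(m) {
    n_int <- length(m$exons) - 1L
    if (n_int < 1L) return(NULL)
    data.frame(gene_id = m$gene_id, intron_index = seq_len(n_int),
               count = 0L)
  }))

  structure(list(genome = genome, true_models = true_models,
                 fused_model = fused_model, control_model = control_model,
                 junction_read_tally = tally, proteins = proteins,
                 domain_ref = domain_ref, triad_positions = triad_aa,
                 config = config),
            class = "sim_truth")
}

#' Simulate spliced RNA-seq alignments for a tandem locus
#'
#' For each true gene with target depth `d`,
#' `N = ceiling(d * mRNA_len / read_len)` single-end reads are drawn at
#' uniform start positions on the mature mRNA and mapped back to genomic
#' blocks, with junction gaps exactly at the true introns; reads never
#' join two genes. Substitution errors at `error_rate` lower the
#' identity accordingly. The control gene is sequenced at
#' `control_depth`. Reads are emitted directly as alignments so the
#' toolkit is testable without an external aligner.
#'
#' @param truth A [build_tandem_locus()] result.
#' @param config The same [sim_config()] (defaults to `truth$config`).
#' @return An object of class `sim_reads`: list with `alignments` (list
#'   of [spliced_alignment()]s) and `junction_read_tally` (the truth
#'   tally updated with the per-intron counts of emitted spanning reads).
#' @export
simulate_reads <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed((config$seed + 1L) %% .Machine$integer.max)
  rl <- config$read_len
  genes <- c(truth$true_models, list(truth$control_model))
  depths <- c(config$depths, config$control_depth)
  tally <- truth$junction_read_tally
  alignments <- list()

  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    widths <- vapply(g$exons, interval_width, integer(1))
    mlen <- sum(widths)
    if (rl > mlen)
      abort_validation("simulate_reads: read_len %d > mRNA length %d of '%s'",
                       rl, mlen, g$gene_id)
    offsets <- cumsum(c(0L, widths[-length(widths)]))  # mRNA offset per exon
    boundaries <- cumsum(widths)[-length(widths)]      # mRNA pos of intron
    n_reads <- as.integer(ceiling(depths[gi] * mlen / rl))
    starts <- sample.int(mlen - rl + 1L, n_reads, replace = TRUE) - 1L
    nerr <- if (config$error_rate > 0)
      stats::rbinom(n_reads, rl, config$error_rate) else integer(n_reads)

    exon_starts <- vapply(g$exons, `[[`, integer(1), "start")
    gene_alns <- vector("list", n_reads)
    ids <- sprintf("%s_r%05d", g$gene_id, seq_len(n_reads))
    for (r in seq_len(n_reads)) {
      s <- starts[r]; e <- s + rl
      hit <- which(offsets < e & offsets + widths > s)
      ms <- pmax(s, offsets[hit]); me <- pmin(e, offsets[hit] + widths[hit])
      ## records are valid by construction; bypass the checking constructor
      gene_alns[[r]] <- structure(
        list(read_id = ids[r], seq_id = g$seq_id,
             block_start = exon_starts[hit] + (ms - offsets[hit]),
             block_end = exon_starts[hit] + (me - offsets[hit]),
             aligned_length = rl, read_length = rl,
             identity = 1 - nerr[r] / rl),
        class = "spliced_alignment")
    }
    alignments <- c(alignments, gene_alns)
    ## junction tally: reads with >= 1 base on each side of the boundary
    for (j in seq_along(boundaries)) {
      n_span <- sum(starts < boundaries[j] & starts + rl > boundaries[j])
      sel <- tally$gene_id == g$gene_id & tally$intron_index == j
      tally$count[sel] <- tally$count[sel] + n_span
    }
  }
  structure(list(alignments = alignments, junction_read_tally = tally),
            class = "sim_reads")
}

#' Write simulated reads as FASTQ
#'
#' Optional convenience for users who want to run a real spliced
#' aligner: reconstructs each read's sequence from the genome (errors
#' are not re-applied; qualities are constant).
#'
#' @param alignments List of [spliced_alignment()]s.
#' @param genome The genome [seq_record()].
#' @param path Output path.
#' @export
write_fastq <- function(alignments, genome, path) {
  check_path_writable(path)
  con <- file(path, "w")
  on.exit(close(con))
  for (a in alignments) {
    seq <- paste(substring(genome$residues, a$block_start + 1L, a$block_end),
                 collapse = "")
    writeLines(c(paste0("@", a$read_id), seq, "+",
                 strrep("I", nchar(seq))), con)
  }
  invisible(NULL)
}
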