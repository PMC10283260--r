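## Independent oracles and fixture generators. Each oracle takes the
## dumbest correct route (full matrices, per-position membership,
## all-vs-all substring comparison) so it shares no code path with the
## implementation it checks.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

random_dna_str <- function(n, with_n = FALSE) {
  alpha <- c("A", "C", "G", "T", if (with_n) "N")
  paste(sample(alpha, n, replace = TRUE,
               prob = if (with_n) c(rep(0.24, 4), 0.04) else NULL),
        collapse = "")
}

random_protein_str <- function(n) paste(sample(AA20, n, TRUE), collapse = "")

## O(n*m) substring-comparison dotplot oracle
oracle_kmer_matches <- function(a, b, k) {
  sa <- toupper(a$residues); sb <- toupper(b$residues)
  ka <- substring(sa, seq_len(nchar(sa) - k + 1L),
                  seq_len(nchar(sa) - k + 1L) + k - 1L)
  kb <- substring(sb, seq_len(nchar(sb) - k + 1L),
                  seq_len(nchar(sb) - k + 1L) + k - 1L)
  ok_b <- !grepl("N", kb, fixed = TRUE)
  pos_a <- integer(0); pos_b <- integer(0)
  for (i in seq_along(ka)) {           # all-vs-all string comparison
    if (grepl("N", ka[i], fixed = TRUE)) next
    j <- which(ok_b & kb == ka[i])
    if (length(j)) {
      pos_a <- c(pos_a, rep.int(i - 1L, length(j)))
      pos_b <- c(pos_b, j - 1L)
    }
  }
  data.frame(pos_a = pos_a, pos_b = pos_b)
}

## per-position membership coverage oracle
oracle_coverage <- function(alignments, seq_id, seq_length) {
  bs <- integer(0); be <- integer(0)
  for (a in alignments) {
    if (!identical(a$seq_id, seq_id)) next
    bs <- c(bs, a$block_start); be <- c(be, a$block_end)
  }
  counts <- integer(seq_length)
  for (p in seq_len(seq_length) - 1L)
    counts[p + 1L] <- sum(bs <= p & p < be)
  counts
}

## naive full-matrix affine-gap Smith-Waterman score oracle
oracle_sw_score <- function(q_res, s_res, scheme) {
  sub <- scheme$substitution
  qc <- match(strsplit(q_res, "")[[1L]], rownames(sub))
  sc <- match(strsplit(s_res, "")[[1L]], rownames(sub))
  n <- length(qc); m <- length(sc)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)
  F <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  go <- scheme$gap_open; ge <- scheme$gap_extend
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      E[i, j] <- max(H[i, j - 1L] + go, E[i, j - 1L] + ge)
      F[i, j] <- max(H[i - 1L, j] + go, F[i - 1L, j] + ge)
      h <- max(0, H[i - 1L, j - 1L] + sub[qc[i - 1L], sc[j - 1L]],
               E[i, j], F[i, j])
      H[i, j] <- h
      if (h > best) best <- h
    }
  }
  best
}

## quick alignment-record builder for hand-made fixtures
make_aln <- function(read_id, seq_id, blocks, read_length = NULL,
                     aligned_length = NULL, identity = 1.0) {
  bs <- vapply(blocks, `[[`, numeric(1), 1L)
  be <- vapply(blocks, `[[`, numeric(1), 2L)
  if (is.null(aligned_length)) aligned_length <- sum(be - bs)
  if (is.null(read_length)) read_length <- aligned_length
  spliced_alignment(read_id, seq_id, bs, be, aligned_length, read_length,
                    identity)
}

exon_matrix <- function(model) {
  t(vapply(model$exons, function(e) c(e$start, e$end), integer(2)))
}

## normalize a match table for set comparison
match_key <- function(df) sort(paste(df$pos_a, df$pos_b, sep = ":"))
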