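## hand-built locus: two exons [0,100) and [200,300) on "c"
two_exon_gene <- gene_model("g", "c", "+",
                            matrix(c(0L, 100L, 200L, 300L), 2L, byrow = TRUE))

spanning_aln <- function(id, shift = 0L) {
  make_aln(id, "c", list(c(50L, 100L + shift), c(200L + shift, 250L)))
}

uniform_track <- function(exon1, exon2) {
  coverage_track("c", c(rep(exon1, 100L), integer(100L), rep(exon2, 100L)))
}

test_that("spanning_read_count matches gaps within slack with anchors", {
  exact <- spanning_aln("exact")
  expect_equal(spanning_read_count(two_exon_gene, 1L, list(exact), 0L), 1L)

  shifted <- make_aln("sh", "c", list(c(50L, 101L), c(201L, 250L)))
  expect_equal(spanning_read_count(two_exon_gene, 1L, list(shifted), 0L), 0L)
  expect_equal(spanning_read_count(two_exon_gene, 1L, list(shifted), 1L), 1L)

  unspliced <- make_aln("u", "c", list(c(20L, 120L)))
  expect_equal(spanning_read_count(two_exon_gene, 1L, list(unspliced), 0L), 0L)

  single <- gene_model("s", "c", "+", matrix(c(0L, 100L), 1L))
  expect_error(spanning_read_count(single, 1L, list(exact)),
               class = "fusionscreen_validation_error")
})

test_that("classify_introns applies the threshold rules", {
  spanning <- lapply(seq_len(45L), function(i) spanning_aln(paste0("s", i)))

  cls <- classify_introns(two_exon_gene, uniform_track(50L, 50L), spanning)
  expect_equal(cls$spanning_reads, 45L)
  expect_equal(cls$link_ratio, 0.9)
  expect_equal(cls$status, "SUPPORTED")

  cls0 <- classify_introns(two_exon_gene, uniform_track(50L, 80L), list())
  expect_equal(cls0$link_ratio, 0)
  expect_equal(cls0$status, "UNSUPPORTED")

  ## shallow flank: exon uniformly at 4x -> peak below min_edge_depth
  cls_nd <- classify_introns(two_exon_gene, uniform_track(4L, 50L), spanning)
  expect_equal(cls_nd$status, "NO_DATA")
  expect_true(is.na(cls_nd$link_ratio))
})

test_that("status is monotone in added spanning reads", {
  track <- uniform_track(50L, 50L)
  rank <- c(UNSUPPORTED = 1L, WEAK = 2L, SUPPORTED = 3L)
  prev <- 0L
  for (n in c(0L, 1L, 3L, 10L, 26L, 60L)) {
    alns <- lapply(seq_len(max(n, 0L)), function(i) spanning_aln(paste0("a", i)))
    st <- classify_introns(two_exon_gene, track, alns)$status
    expect_true(rank[[st]] >= prev)
    prev <- rank[[st]]
  }
})

test_that("screen_gene verdict rules and degenerate inputs", {
  spanning <- lapply(seq_len(40L), function(i) spanning_aln(paste0("s", i)))
  rep_ok <- screen_gene(two_exon_gene, uniform_track(50L, 50L), spanning)
  expect_equal(rep_ok$verdict, "CONSISTENT")
  expect_length(rep_ok$split_introns, 0L)

  rep_empty <- screen_gene(two_exon_gene, coverage_track("c", integer(300L)),
                           list())
  expect_equal(rep_empty$verdict, "INSUFFICIENT_DATA")

  single <- gene_model("s", "c", "+", matrix(c(0L, 100L), 1L))
  expect_equal(screen_gene(single, coverage_track("c", integer(300L)),
                           list())$verdict, "CONSISTENT")

  expect_error(screen_gene(two_exon_gene, coverage_track("other",
                                                         integer(300L)),
                           list()),
               class = "fusionscreen_validation_error")
})

test_that("propose_splits partitions exons at unsupported introns", {
  ex6 <- matrix(c(0L, 10L, 20L, 30L, 40L, 50L, 60L, 70L, 80L, 90L,
                  100L, 110L), 6L, 2L, byrow = TRUE)
  g6 <- gene_model("big", "c", "-", ex6)
  fake_report <- structure(list(gene_id = "big", verdict = "LIKELY_FUSION",
                                split_introns = c(2L, 4L)),
                           class = "fusion_report")
  parts <- propose_splits(g6, fake_report)
  expect_length(parts, 3L)
  expect_equal(lapply(parts, exon_matrix),
               list(ex6[1:2, ], ex6[3:4, ], ex6[5:6, ]))
  expect_equal(vapply(parts, `[[`, character(1), "gene_id"),
               c("big.split1", "big.split2", "big.split3"))
  expect_equal(vapply(parts, `[[`, character(1), "strand"), rep("-", 3L))

  no_split <- structure(list(gene_id = "big", verdict = "CONSISTENT",
                             split_introns = integer(0)),
                        class = "fusion_report")
  expect_equal(propose_splits(g6, no_split), list(g6))
})

test_that("parameter recovery and split/merge consistency at >= 20x depth", {
  for (seed in 1:5) {
    cfg <- sim_config(seed = seed, depths = c(50, 20, 80))
    truth <- build_tandem_locus(cfg)
    sim <- simulate_reads(truth, cfg)
    alns <- filter_alignments(sim$alignments)
    track <- compute_coverage(alns, truth$genome$id,
                              nchar(truth$genome$residues))
    rep_fused <- screen_gene(truth$fused_model, track, alns)
    expect_equal(rep_fused$verdict, "LIKELY_FUSION")
    expect_equal(rep_fused$split_introns, c(2L, 4L))

    ## splits re-screened never come back as fusions
    for (m in propose_splits(truth$fused_model, rep_fused)) {
      v <- screen_gene(m, track, alns)$verdict
      expect_true(v %in% c("CONSISTENT", "INSUFFICIENT_DATA"))
    }
    for (m in c(truth$true_models, list(truth$control_model)))
      expect_equal(screen_gene(m, track, alns)$verdict, "CONSISTENT")
  }
})
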