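test_that("locus layout follows the analytic length formula", {
  cfg <- sim_config(seed = 5L)
  truth <- build_tandem_locus(cfg)
  gene_len <- cfg$exons_per_gene * cfg$exon_len +
    (cfg$exons_per_gene - 1L) * cfg$intron_len
  ctrl_len <- 3L * cfg$exon_len + 2L * cfg$intron_len
  expected <- (cfg$n_copies + 2L) * cfg$spacer_len +
    cfg$n_copies * gene_len + ctrl_len
  expect_equal(nchar(truth$genome$residues), expected)

  ## fused model = union of the true models' exons
  expect_equal(do.call(rbind, lapply(truth$true_models, exon_matrix)),
               exon_matrix(truth$fused_model))

  ## genome residues at exon positions translate back to the proteins
  expect_length(truth$proteins, cfg$n_copies + 1L)
  decoy <- truth$proteins[[cfg$n_copies + 1L]]
  expect_equal(decoy$residues,
               paste(vapply(truth$proteins[seq_len(cfg$n_copies)],
                            `[[`, character(1), "residues"), collapse = ""))
})

test_that("single-copy config degenerates to no fusion artifact", {
  truth <- build_tandem_locus(sim_config(n_copies = 1L, depths = 50,
                                         seed = 2L))
  expect_equal(exon_matrix(truth$fused_model),
               exon_matrix(truth$true_models[[1L]]))
})

test_that("different seeds change residues but never coordinates", {
  t1 <- build_tandem_locus(sim_config(seed = 101L))
  t2 <- build_tandem_locus(sim_config(seed = 202L))
  expect_false(identical(t1$genome$residues, t2$genome$residues))
  expect_equal(lapply(t1$true_models, exon_matrix),
               lapply(t2$true_models, exon_matrix))
  expect_equal(exon_matrix(t1$control_model), exon_matrix(t2$control_model))
  ## same seed is bit-reproducible
  t1b <- build_tandem_locus(sim_config(seed = 101L))
  expect_identical(t1$genome$residues, t1b$genome$residues)
})

test_that("read counts follow ceil(depth * mRNA / read_len)", {
  cfg <- sim_config(seed = 3L)
  truth <- build_tandem_locus(cfg)
  sim <- simulate_reads(truth, cfg)
  ids <- vapply(sim$alignments, `[[`, character(1), "read_id")
  per_gene <- table(sub("_r[0-9]+$", "", ids))
  expect_equal(unname(per_gene[["gene1"]]), ceiling(50 * 400 / 100))
  expect_equal(unname(per_gene[["gene2"]]), ceiling(10 * 400 / 100))
  expect_equal(unname(per_gene[["gene3"]]), ceiling(80 * 400 / 100))
  expect_equal(unname(per_gene[["control_gene"]]), ceiling(50 * 600 / 100))
})

test_that("error-free reads all pass the default filter", {
  cfg <- sim_config(seed = 9L)
  sim <- simulate_reads(build_tandem_locus(cfg), cfg)
  expect_true(all(vapply(sim$alignments, `[[`, numeric(1), "identity") == 1))
  expect_length(filter_alignments(sim$alignments), length(sim$alignments))
})

test_that("sequencing errors lower identities accordingly", {
  cfg <- sim_config(seed = 12L, error_rate = 0.04)
  sim <- simulate_reads(build_tandem_locus(cfg), cfg)
  ids <- vapply(sim$alignments, `[[`, numeric(1), "identity")
  expect_true(any(ids < 1))
  expect_true(all(ids >= 0.8))
  expect_equal(mean(1 - ids), 0.04, tolerance = 0.25)
})

test_that("mean exonic coverage per gene is close to its target depth", {
  devs <- sapply(1:5, function(seed) {
    cfg <- sim_config(seed = seed)
    truth <- build_tandem_locus(cfg)
    sim <- simulate_reads(truth, cfg)
    track <- compute_coverage(sim$alignments, truth$genome$id,
                              nchar(truth$genome$residues))
    vapply(seq_along(truth$true_models), function(i) {
      m <- truth$true_models[[i]]
      cov <- unlist(lapply(m$exons, function(e)
        track$counts[(e$start + 1L):e$end]))
      mean(cov) / cfg$depths[i]
    }, numeric(1))
  })
  expect_true(all(abs(devs - 1) <= 0.15))
})

test_that("the junction tally equals observed spanning reads", {
  cfg <- sim_config(seed = 4L)
  truth <- build_tandem_locus(cfg)
  sim <- simulate_reads(truth, cfg)
  for (m in c(truth$true_models, list(truth$control_model))) {
    for (j in seq_len(length(m$exons) - 1L)) {
      counted <- spanning_read_count(m, j, sim$alignments, 0L)
      sel <- sim$junction_read_tally$gene_id == m$gene_id &
        sim$junction_read_tally$intron_index == j
      expect_equal(counted, sim$junction_read_tally$count[sel])
    }
  }
  ## no simulated read ever joins two genes: every gap is a true intron
  true_introns <- do.call(rbind, lapply(
    c(truth$true_models, list(truth$control_model)), function(m)
      t(vapply(gene_introns(m), function(i) c(i$start, i$end), integer(2)))))
  for (a in sim$alignments) {
    g <- alignment_gaps(a)
    if (!nrow(g)) next
    for (r in seq_len(nrow(g)))
      expect_true(any(true_introns[, 1L] == g[r, "start"] &
                        true_introns[, 2L] == g[r, "end"]))
  }
})

test_that("simulated proteins carry the conserved triad", {
  cfg <- sim_config(seed = 6L)
  truth <- build_tandem_locus(cfg)
  scheme <- scoring_scheme()
  expect_equal(count_domain_copies(truth$domain_ref,
                                   truth$proteins[[4L]],
                                   scheme)$copy_count, 3L)
  for (i in 1:3) {
    tri <- check_triad(truth$domain_ref, truth$triad_positions,
                       truth$proteins[[i]], scheme)
    expect_true(tri$conserved)
  }
})

test_that("write_fastq reconstructs read sequences from the genome", {
  cfg <- sim_config(seed = 8L, depths = c(2, 2, 2))
  truth <- build_tandem_locus(cfg)
  sim <- simulate_reads(truth, cfg)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim$alignments[1:5], truth$genome, path)
  lines <- readLines(path)
  expect_length(lines, 20L)
  expect_true(all(startsWith(lines[seq(1L, 20L, 4L)], "@")))
  expect_equal(unique(nchar(lines[seq(2L, 20L, 4L)])), 100L)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(depths = c(10, 20)),
               class = "fusionscreen_validation_error")
  expect_error(sim_config(read_len = 500L),
               class = "fusionscreen_validation_error")
  expect_error(sim_config(copy_divergence = 0.5),
               class = "fusionscreen_validation_error")
})
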