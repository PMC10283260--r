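scheme <- scoring_scheme()

mutate_protein <- function(res, rate, protect = integer(0)) {
  chars <- strsplit(res, "")[[1L]]
  hit <- setdiff(which(runif(length(chars)) < rate), protect)
  for (p in hit) chars[p] <- sample(setdiff(AA20, chars[p]), 1L)
  paste(chars, collapse = "")
}

test_that("screen_by_length is strict at the threshold", {
  p500 <- seq_record("p500", random_protein_str(500))
  p501 <- seq_record("p501", random_protein_str(501))
  kept <- screen_by_length(list(p500, p501))
  expect_equal(vapply(kept, `[[`, character(1), "id"), "p501")
  expect_length(screen_by_length(list()), 0L)

  set.seed(2)
  lens <- c(120L, 499L, 500L, 501L, 777L, 1200L)
  fix <- lapply(seq_along(lens), function(i)
    seq_record(paste0("f", i), random_protein_str(lens[i])))
  expect_equal(vapply(screen_by_length(fix), `[[`, character(1), "id"),
               c("f4", "f5", "f6"))
})

test_that("local_align: identity, floor and oracle equivalence", {
  set.seed(8)
  p <- seq_record("p", random_protein_str(40))
  hit <- local_align(p, p, scheme)
  codes <- match(strsplit(p$residues, "")[[1L]], rownames(scheme$substitution))
  expect_equal(hit$score, sum(scheme$substitution[cbind(codes, codes)]))
  expect_equal(hit$subject_start, 1L)
  expect_equal(hit$subject_end, 40L)

  polyA <- seq_record("a", strrep("A", 15L))
  polyW <- seq_record("w", strrep("W", 15L))
  miss <- local_align(polyA, polyW, scheme)
  expect_equal(miss$score, 0)
  expect_true(is.na(miss$subject_start))

  q <- seq_record("q", random_protein_str(20))
  s <- seq_record("s", paste0(random_protein_str(20), substr(q$residues, 3, 18),
                              random_protein_str(24)))
  expect_equal(local_align(q, s, scheme)$score,
               oracle_sw_score(q$residues, s$residues, scheme))

  bad <- seq_record("bad", "MKLO1", alphabet = "protein")
  expect_error(local_align(bad, p, scheme),
               class = "fusionscreen_validation_error")
})

test_that("count_domain_copies recovers k copies and masks soundly", {
  set.seed(77)
  domain <- seq_record("dom", random_protein_str(120))
  for (k in 1:3) {
    for (div in c(0, 0.10)) {
      copies <- vapply(seq_len(k), function(i)
        mutate_protein(domain$residues, div), character(1))
      linkers <- c(replicate(k, random_protein_str(10)))
      prot <- seq_record(sprintf("k%d_div%g", k, div),
                         paste0(paste0(linkers, copies, collapse = ""),
                                random_protein_str(10)))
      scan <- count_domain_copies(domain, prot, scheme)
      expect_equal(scan$copy_count, k)
      ## masking soundness: hits never overlap
      if (nrow(scan$hits) > 1L) {
        h <- scan$hits[order(scan$hits$subject_start), ]
        expect_true(all(h$subject_start[-1L] > h$subject_end[-nrow(h)]))
      }
    }
  }
  unrelated <- seq_record("rand", random_protein_str(360))
  expect_equal(count_domain_copies(domain, unrelated, scheme)$copy_count, 0L)
})

test_that("copy counting is invariant to copy order", {
  set.seed(5)
  domain <- seq_record("dom", random_protein_str(100))
  c1 <- mutate_protein(domain$residues, 0.05)
  c2 <- mutate_protein(domain$residues, 0.05)
  fwd <- seq_record("fwd", paste0(c1, random_protein_str(8), c2))
  rev <- seq_record("rev", paste0(c2, random_protein_str(8), c1))
  expect_equal(count_domain_copies(domain, fwd, scheme)$copy_count, 2L)
  expect_equal(count_domain_copies(domain, rev, scheme)$copy_count, 2L)
})

test_that("check_triad maps the catalytic residues through gaps", {
  set.seed(19)
  base <- strsplit(random_protein_str(80), "")[[1L]]
  base[c(20L, 45L, 60L)] <- c("C", "H", "N")
  ref <- seq_record("ref", paste(base, collapse = ""))

  same <- check_triad(ref, c(20L, 45L, 60L), ref, scheme)
  expect_true(same$conserved)
  expect_equal(same$positions_in_subject, c(20L, 45L, 60L))

  mut <- base; mut[20L] <- "S"
  res_mut <- check_triad(ref, c(20L, 45L, 60L),
                         seq_record("mut", paste(mut, collapse = "")), scheme)
  expect_false(res_mut$conserved)
  expect_equal(unname(res_mut$residues), c("S", "H", "N"))

  ins <- seq_record("ins", paste0(paste(base[1:10], collapse = ""),
                                  "GGGGG",
                                  paste(base[11:80], collapse = "")))
  res_ins <- check_triad(ref, c(20L, 45L, 60L), ins, scheme)
  expect_true(res_ins$conserved)
  expect_equal(res_ins$positions_in_subject, c(25L, 50L, 65L))

  expect_error(check_triad(ref, c(1L, 45L, 60L), ref, scheme),
               class = "fusionscreen_validation_error")
})

test_that("scoring scheme invariants are enforced", {
  expect_error(scoring_scheme(gap_open = -1L, gap_extend = -11L),
               class = "fusionscreen_validation_error")
  asym <- matrix(c(1, 2, 3, 1), 2L, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(scoring_scheme(substitution = asym),
               class = "fusionscreen_validation_error")
  expect_true("#" %in% rownames(scheme$substitution))
  expect_equal(scheme$substitution["#", "A"], -1e6)
})
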