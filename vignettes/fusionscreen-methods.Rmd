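---
title: "Detecting artificially fused gene models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting artificially fused gene models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Tandem arrays of near-identical paralogs are a known trap for automatic
gene annotation: a pipeline may bridge adjacent copies and emit one gene
model whose predicted protein carries two or three copies of a domain
that is biologically single-copy. Chalcone synthase — a two-exon gene in
most plants, with a catalytic Cys/His/Asn triad in its single domain —
is the motivating example: several plant genome annotations contain
apparent CHS domain triplications that transcriptome evidence
contradicts.

RNA-seq read mapping exposes such artifacts because mature mRNAs do not
extend across intergenic spacers. Three signals distinguish a genuine
intron from a mis-annotated spacer:

1. **Split-read support.** A real intron is spanned by approximately as
   many gapped reads as cover the borders of its flanking exons. A
   spacer joining two genes has essentially no spanning reads.
2. **Coverage shape.** At a splice site the exonic coverage drops
   abruptly to near zero. At a true gene end the coverage declines
   continuously over roughly a read length ("taper").
3. **Expression heterogeneity.** Tandem copies are often expressed at
   very different levels; a single gene cannot have a highly covered
   5' exon, an almost uncovered middle exon pair, and a highly covered
   3' end.

`fusionscreen` quantifies signal 1 as the decision rule, records signal
2 as corroboration, and exposes signal 3 through per-exon statistics.

## The classifier

All coordinates are internally 0-based half-open; GFF3 and SAM
conversions happen only at file boundaries. Alignments are first
filtered at minimal identity 0.95 and minimal aligned read fraction 0.90
(inclusive bounds), the stringency customarily used for gene-model
evaluation with spliced aligners.

For intron *i* of a gene model, with an edge window of `edge_window`
positions (default 10 bp):

* `left_edge_cov` / `right_edge_cov` — mean coverage over the inner edge
  windows of the flanking exons;
* `spanning_reads` — alignments containing a junction gap matching the
  intron boundaries within `junction_slack` bp (default 0) and anchored
  by at least one aligned base on each side;
* `link_ratio = spanning_reads / min(left_edge_cov, right_edge_cov)`,
  defined as 0 when `spanning_reads` is 0.

Status: `SUPPORTED` when `link_ratio >= theta_supported` (0.5, so
"almost equivalent" support passes), `UNSUPPORTED` when
`link_ratio < theta_unsupported` (0.05, "almost no connecting reads"),
`WEAK` between. Verdicts: `LIKELY_FUSION` iff at least one intron is
`UNSUPPORTED` (those ordinals become the proposed split points);
`INSUFFICIENT_DATA` iff every intron is `NO_DATA`; otherwise
`CONSISTENT`. Single-exon genes are trivially consistent.
`propose_splits()` cuts the exon list at each `UNSUPPORTED` intron.

### Why the data-adequacy guard uses peak exon coverage

An intron can only be judged when the locus is expressed and sequenced
deeply enough that spanning reads would be expected were the intron
real. The natural first idea — require the *edge* coverages themselves
to reach `min_edge_depth` (default 10×) — turns out to be
self-defeating: at a genuine gene boundary *inside* a fused model, the
upstream gene's coverage tapers toward zero over the last read length,
so the edge window sits at a few reads even when the gene body is at
50–80×. An edge-based guard therefore classifies exactly the artifact
introns as `NO_DATA` and the screen can never fire. We verified this
arithmetically and empirically: at 50× depth with 100 bp reads on a
400 bp mRNA the terminal 10 bp window averages about 3.6×, and in
simulation the intergenic edge coverages come out at 0–6× while the
flanking exons peak at 20–130×.

The guard therefore asks whether the *peak* per-position coverage of
both flanking exons reaches `min_edge_depth`. Peak coverage measures
sequencing depth of the transcript without being confounded by boundary
taper, is robust at low depth (the maximum over ~200 positions
concentrates well above the mean), and leaves the `link_ratio`
denominator — the border coverage the decision rule is phrased in —
untouched. With this guard a 10× gene is still judged (its real intron
has edge coverage ≈ 13× and a ratio near 1) while a zero-coverage gene
is reported `INSUFFICIENT_DATA` rather than guessed at.

### Taper as corroboration only

For each proposed split intron the report notes whether the upstream
exon's right taper and the downstream exon's left taper fall at or below
`taper_terminal` (default 0.5) — a "terminal-like" shape. Taper is not
required for the verdict: the decisive signal at adequate depth is the
absence of spanning reads, and taper estimates are noisy on short or
shallow exons (taper is `edge/body` with body = exon minus both edge
windows, the whole exon when shorter than three windows; 0/0 yields 0
plus an `insufficient` flag rather than an error).

## Parameters at a glance

| parameter | default | unit | role |
|---|---|---|---|
| `min_identity` | 0.95 | fraction | alignment filter, inclusive |
| `min_aligned_fraction` | 0.90 | fraction | alignment filter, inclusive |
| `theta_supported` | 0.5 | ratio | `SUPPORTED` threshold |
| `theta_unsupported` | 0.05 | ratio | `UNSUPPORTED` threshold |
| `min_edge_depth` | 10 | reads | adequacy guard on flank peak coverage |
| `junction_slack` | 0 | bp | gap/intron boundary tolerance |
| `edge_window` | 10 | bp | edge coverage window |
| `taper_terminal` | 0.5 | ratio | "terminal-like" annotation in notes |
| `k` | 31 | bp | dotplot k-mer size |
| `min_score_fraction` | 0.3 | fraction | domain-hit acceptance threshold |

`junction_slack` is 0 because the bundled simulator writes exact
junction coordinates; real aligners can exhibit a few bp of wobble, so
the flag exists and is echoed, like every other threshold, into the
JSON report for provenance.

## The simulator: what it emulates, what it does not

`build_tandem_locus()` + `simulate_reads()` generate the stated world
the screen is validated against: `n_copies = 3` two-exon genes
(exon 200 bp, intron 150 bp), separated by 500 bp spacers, with a
genuine 3-exon control gene further along the sequence, per-gene depths
50×/10×/80× (deliberately unequal, mimicking the expression
heterogeneity seen at real mis-annotated loci), 100 bp single-end
reads, no sequencing error by default. Reads are drawn uniformly on the
mature mRNA, mapped back to genomic blocks with gaps exactly at true
introns, and never join two genes. The control gene is sequenced at
50×, a moderately expressed gene; it exists so that every screening run
also contains a true multi-intron negative.

Design choices a user should know:

* **Reads are emitted as alignments**, not FASTQ through an external
  aligner, so tests are hermetic. A `write_fastq()` is provided for
  users who want to exercise a real spliced aligner.
* **Single-end only.** Pairing adds no information to per-position
  coverage or junction counts as defined here; real libraries are
  usually paired. This is a documented divergence from typical data.
* **Exonic sequence is drawn from sense codons**, substitutions between
  copies that would create an in-frame stop are redrawn, and the three
  triad codons are exempt from divergence — a crude model of purifying
  selection that keeps the translated paralogs alignable and the triad
  checkable. The default exon length (200 bp) makes the 400 bp mRNA one
  base short of a whole codon count; translation simply uses the first
  133 codons.
* **Copy divergence is substitution-only** (default 5%), so coordinates
  are identical across seeds and frames never shift; real tandem arrays
  also differ by indels.
* Coverage is uniform on the mRNA apart from end taper; real libraries
  have positional biases. A green simulation test therefore establishes
  the *logic* of the classifier, not its calibration on any particular
  library chemistry.

All randomness flows from a single integer seed (`simulate_reads` uses
`seed + 1` so that locus construction and read sampling are
independently reproducible); every output is bit-reproducible per seed.

## Sequence-level screens

The **dotplot** computes the exact set of k-mer matches between two
sequences (hash-index one, stream the other). Matching is
case-insensitive; any k-mer containing `N` is dead (it matches nothing,
including itself), so masked regions cannot paint spurious diagonals.
The self-comparison main diagonal is reported, not suppressed — a
renderer may grey it out, but the computation stays honest.

The **domain-copy screen** replaces a database-annotation count with an
explicit alignment procedure: iterative Smith–Waterman (BLOSUM62 from
Biostrings; affine gaps −11/−1, the customary protein-BLAST values) of
a single-domain reference against the protein, masking each accepted
hit with a sentinel residue that scores −10⁶ against everything, so
hits cannot chain across masked regions and termination is guaranteed.
A hit is accepted at `min_score_fraction` (0.3) of the reference
self-score, low enough to catch diverged copies (a 10%-diverged copy
scores ≈ 0.8 of self) and far above random local-alignment scores for
domain-length references. Ties between equal-scoring optimal local
alignments are broken deterministically toward the smallest subject
start, then query start. The triad check runs a global (end-gap
penalized) alignment and maps the three reference triad columns to the
subject; "conserved" requires all three to be aligned (not gapped) and
to read C, H, N. Discriminating CHS from the closely related stilbene
synthase (two further diagnostic residues) is out of scope.

The protein length screen keeps sequences strictly longer than 500
residues — the length at which a protein can plausibly harbor more than
one copy of this ~400-residue domain family; the spec's wording
("longer than") makes the bound exclusive, and a boundary test pins
that.

## Numerical and I/O conventions

* Coverage files are dense 1-based `position<TAB>count` rows. The
  original convention is ambiguous between 0- and 1-based; we
  standardize on 1-based and additionally write a `#seq_id=` comment so
  the reader/writer round-trip is exact.
* SAM: blocks are maximal runs of reference-consuming non-`N` CIGAR
  operations (deletions stay inside blocks — a deleted base is still
  physically spanned by the read); identity is `1 − NM/aligned_length`
  when the tag is present and 1.0 with a logged notice otherwise, so
  filtering behavior is explicit.
* Multiple transcripts per gene: the transcript with the largest summed
  exon length wins, with a warning.
* Alignment strand is ignored throughout (unstranded libraries
  assumed); gene strand is carried for reporting only.
* Every figure is accompanied by a sidecar TSV of exactly what was
  drawn, so plots are tested by data comparison, not image comparison.

## Known limitations

* A spanning read needs only one aligned base per side; no minimum
  anchor length is enforced beyond that, which slightly inflates
  spanning counts for error-prone real data (the simulator's exact
  junctions are unaffected).
* Multi-mapping reads are not modeled; every SAM record counts once.
* The screen cannot distinguish a fused annotation from a genuine
  read-through transcript if the transcriptome truly contains spanning
  reads; it reports evidence, and the final call on unusual loci
  remains with the curator.
* BAM/CRAM are not parsed (SAM text only); convert externally if
  needed.
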