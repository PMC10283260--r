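# fusionscreen

Quality control for gene annotations in repetitive regions.

Automatic annotation pipelines occasionally merge a tandem array of
paralogous genes into a single gene model. The classic symptom is a
predicted protein with an implausible duplication or triplication of a
well-known single-copy domain — chalcone synthase (CHS), whose gene
normally has two coding exons, is a documented example across several
plant genomes. `fusionscreen` detects such artificial fusions from
spliced RNA-seq alignment evidence and proposes the corrected gene
models, without requiring any external database or aligner.

## What it computes

For a gene model with exons `e_1..e_n` and introns `i_1..i_{n-1}`, and a
set of spliced alignments filtered at a minimal identity of 0.95 and a
minimal aligned read fraction of 0.90:

* **Coverage track** — `cov[p]`, the number of alignments whose aligned
  blocks contain genomic position `p` (junction gaps contribute
  nothing). Exons of an expressed gene show high coverage, introns show
  next to none.
* **Junction support** — for each intron, the number of reads whose
  alignment gap matches the intron boundaries (within a configurable
  slack) with at least one aligned base on each side, compared with the
  coverage at the borders of the flanking exons:

  ```
  link_ratio(i) = spanning_reads(i) / min(left_edge_cov(i), right_edge_cov(i))
  ```

  A genuine intron is spanned by almost as many reads as cover the
  flanking exon borders (`link_ratio ≈ 1`, status `SUPPORTED`); an
  intergenic spacer mis-annotated as an intron has essentially no
  connecting reads (`link_ratio ≈ 0`, status `UNSUPPORTED`). Introns
  whose flanking exons never reach a peak coverage of `min_edge_depth`
  are `NO_DATA`.
* **Verdict** — `LIKELY_FUSION` if any intron is `UNSUPPORTED` (those
  introns become split points), `INSUFFICIENT_DATA` if all introns are
  `NO_DATA`, else `CONSISTENT`. Exon-end coverage taper (a continuous
  drop towards a gene end, as opposed to the abrupt drop at a splice
  site) is recorded as corroborating evidence.
* **Locus self-similarity** — exact k-mer matches (default k = 31)
  between two sequences for repeat dotplots; tandem copies appear as
  off-diagonals.
* **Domain-copy counting** — iterative Smith–Waterman (BLOSUM62, affine
  gaps −11/−1) of a single-domain reference against a protein, masking
  each accepted hit, until no hit reaches `min_score_fraction` (0.3) of
  the reference self-score; plus a check that the catalytic
  Cys/His/Asn triad is conserved in each copy via global alignment.
* **Simulator** — a seeded generator of a truth-known tandem locus
  (3 two-exon paralogs at unequal depths 50×/10×/80×, a fused decoy
  annotation, a genuine 3-exon control gene, translated paralog
  proteins and a concatenated decoy protein) emitting reads directly as
  spliced alignments, so the whole pipeline is verifiable offline.

## Worked example

```sh
fusionscreen simulate --seed 7 --out-dir demo/
fusionscreen screen --gff3 demo/fused_model.gff3 --sam demo/alignments.sam \
    --out-dir demo/screen
```

(The `fusionscreen` script lives in `inst/cli/`; equivalently call
`fusionscreen_cli(c("simulate", ...))` from R.) The run prints

```
[INFO] simulate: wrote 860 reads and truth files to demo
[INFO] filter: kept 860 / 860 alignments
[INFO] screen: 2 gene(s) screened; reports in demo/screen
```

and `demo/screen/summary.tsv` contains

```
gene_id       verdict        n_introns  n_unsupported  split_coordinates    n_proposed_models
fused_gene    LIKELY_FUSION  5          2              1051-1550;2101-2600  3
control_gene  CONSISTENT     2          0                                   1
```

Read: the fused decoy spans six exons; its five annotated introns
include two (coordinates shown 1-based) with zero spanning reads despite
well-covered flanking exons — exactly the two intergenic spacers — so
the model is flagged and split into three two-exon genes, which match
the simulated truth. The genuine control gene passes. Per-intron
evidence (spanning reads, edge coverages, link ratios, taper notes) is
in `demo/screen/report.json`.

The same library calls in R:

```r
library(fusionscreen)
cfg   <- sim_config(seed = 7)
truth <- build_tandem_locus(cfg)
sim   <- simulate_reads(truth, cfg)
alns  <- filter_alignments(sim$alignments)
track <- compute_coverage(alns, truth$genome$id, nchar(truth$genome$residues))
screen_gene(truth$fused_model, track, alns)
#> <fusion_report> fused_gene: LIKELY_FUSION
#>   proposed splits at intron(s): 2, 4
#>   introns: 1:SUPPORTED(n=55) 2:UNSUPPORTED(n=0) 3:SUPPORTED(n=8)
#>            4:UNSUPPORTED(n=0) 5:SUPPORTED(n=126)
```

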