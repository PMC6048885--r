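# lncprofiler

Identification and genomic characterization of tissue-specific long
noncoding RNAs (lncRNAs) and mRNAs from multi-tissue expression profiles.

Profiling studies of the mammalian testis repeatedly find that it expresses
more tissue-specific lncRNAs than any other organ, and that many of them
are long intergenic ncRNAs (lincRNAs) sitting near protein-coding genes —
candidates for *cis*-regulation during spermatogenesis. `lncprofiler`
implements that analysis as a reusable, fully tested pipeline for any
normalized transcripts × samples intensity matrix with per-tissue
replicates (the classic design is 5 tissues × 3 replicates), plus
strand-aware transcript annotations.

## What it computes

**Tissue specificity.** Each cell of the matrix receives a
present/marginal/absent (P/M/A) detection flag from a log2 background
model: with background mean μ and SD σ, a cell is P when
x ≥ μ + k_P·σ, M when μ + k_M·σ ≤ x < μ + k_P·σ, else A
(defaults k_P = 3, k_M = 2; vendor flags can be supplied instead). A
transcript is *specific* to tissue *t* iff

1. it is P or M in **every** replicate of *t* and A in **every** replicate
   of every other tissue,
2. its fold-change FC(t) = mean(t) / max over t′≠t of mean(t′) ≥ 5
   (linear scale, minimum pairwise ratio — the strictest reading of
   "relative to the others"), and
3. a two-sided equal-variance Student's t-test of log2 intensities,
   replicates of *t* versus all other samples pooled, gives p ≤ 0.05.

Criterion 1 alone guarantees no transcript is specific to two tissues.

**Positional classification.** Every lncRNA gets exactly one of six
subtypes relative to the mRNA annotation, by precedence: `exonic_sense` /
`exonic_antisense` (≥ 1 bp overlap with a gene exon), `intronic_sense` /
`intronic_antisense` (≥ 1 bp overlap with an intron, no exon overlap),
`bidirectional` (no overlap, nearest gene < 1 kb, strand ignored), and
`intergenic` (lincRNA, ≥ 1 kb from every gene). Coordinates are 0-based
half-open throughout; distances count bases strictly between loci.

**Downstream characterization.** A 10-kb window search pairs each lincRNA
with candidate *cis*-target genes; per-chromosome ratios of specific to
expressed transcripts expose chromosomal enrichment; Venn partitions of
cell-line sets, first-detection-day staging across the first wave of
spermatogenesis, wild-type vs. germ-cell-deficient (W/Wv) presence calls,
and 2^-ΔΔCt relative quantification round out the reporting.

**Synthetic data.** `generate_genome()` and `generate_expression()` plant
subtype geometries and tissue-specific transcripts with serialized ground
truth, so every stage is testable offline and recovery is measurable.

## Worked example

```r
library(lncprofiler)

gg <- generate_genome(1, n_genes = 30, n_lncs = 60)   # planted geometries
ge <- generate_expression(1, n_transcripts = 2000,    # 5 tissues x 3 reps
                          planted = c(testis = 0.025), fold = 20)

m     <- compute_flags(ge$matrix, background_model(6, 1))
calls <- call_specific(m, fc_threshold = 5, p_threshold = 0.05)
specific_counts(calls)
#> # A tibble: 5 x 2
#>   tissue n_specific
#>   <chr>       <int>
#> 1 brain           0
#> 2 heart           0
#> 3 kidney          0
#> 4 liver           0
#> 5 testis         50

lncs  <- subset(gg$annotations, biotype == "lncRNA")
genes <- subset(gg$annotations, biotype == "mRNA")
labels <- classify_lncrnas(lncs, genes)
subtype_proportions(labels)
#> # A tibble: 6 x 3
#>   subtype                n   pct
#>   <chr>              <int> <dbl>
#> 1 exonic_sense          10  16.7
#> 2 exonic_antisense      10  16.7
#> 3 intronic_sense        10  16.7
#> 4 intronic_antisense    10  16.7
#> 5 bidirectional         10  16.7
#> 6 intergenic            10  16.7

lincs <- subset(lncs, transcript_id %in%
                  labels$transcript_id[labels$subtype == "intergenic"])
cis_summary(find_nearby_genes(lincs, genes), n_lincs = nrow(lincs))
#> $n_pairs
#> [1] 2
#> $n_lincs_with_partner
#> [1] 2
#> $n_partner_genes
#> [1] 2
#> $pct_colocalized
#> [1] 20
```

All 50 planted testis-specific transcripts are recovered with no false
positives, the 60 planted subtype labels are recovered exactly, and the
cis pairs found are exactly the planted ones. `run_pipeline(list(generate
= TRUE, seed = 1, out = "out/"))` performs the same steps end to end and
writes TSV tables plus a JSON report.

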