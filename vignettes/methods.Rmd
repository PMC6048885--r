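---
title: "Methods: tissue-specific lncRNA profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-specific lncRNA profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncprofiler)
```

This vignette documents the models, conventions, and design choices behind
`lncprofiler`, in the order the pipeline runs them: detection flags,
tissue-specificity calling, positional classification, the cis-target
window search, reporting operations, and the synthetic-data generator used
to validate all of the above.

## Detection flags

Microarray-style expression profiling classifies each (transcript, sample)
cell as present (P), marginal (M), or absent (A) relative to background.
Vendor pipelines derive these flags from probe-level statistics that are
not reproducible from a normalized matrix, so `lncprofiler` defines a
transparent stand-in: a log2-scale background model with mean $\mu$ and
standard deviation $\sigma$, under which a cell with log2 intensity $x$ is

* **P** when $x \ge \mu + k_P\,\sigma$,
* **M** when $\mu + k_M\,\sigma \le x < \mu + k_P\,\sigma$,
* **A** otherwise,

with defaults $k_P = 3$, $k_M = 2$ (units: background SDs). The rule is
deterministic, idempotent, and monotone in intensity; both thresholds are
inclusive at their lower edge. Precomputed flags can be supplied alongside
the matrix to bypass the model entirely, which is the recommended path
when vendor calls exist. Intensities are assumed already normalized; an
optional per-sample median scaling (`median_scale()`) is provided but
never applied implicitly, because the upstream normalization method is a
property of the data, not of this pipeline.

## The composite specificity rule

A transcript is specific to tissue $t$ iff three criteria hold jointly:

1. **Replicate-consistent flags** — P or M in every replicate of $t$, A in
   every replicate of every other tissue. This alone implies a transcript
   can be specific to at most one tissue, an invariant asserted on every
   run.
2. **Fold-change $\ge 5$** — computed on the *linear* scale as the
   minimum ratio of the target tissue mean over each other tissue's mean.
   "Relative to the others" admits several readings (per-tissue minimum,
   pooled mean, maximum); the minimum-pairwise reading is the strictest —
   it guarantees at least five-fold enrichment against *every* tissue —
   and is the default, with the pooled-mean variant available via
   `fc_method = "pooled"`.
3. **Student's t-test $p \le 0.05$** — two-sided, *equal-variance*
   (pooled) two-sample t on log2 intensities, the target tissue's
   replicates versus all other-tissue replicates pooled (3 vs. 12 in the
   five-tissue design). Pooling yields the single p-value per candidate
   that the rule calls for; per-pair testing would produce four. The
   equal-variance form is used because the named test is Student's, not
   Welch's. Fold-change on linear intensities and testing on log2
   intensities is standard microarray practice.

Both thresholds are inclusive, as printed ("$\ge 5$", "$\le 0.05$"). No
multiple-testing correction is applied by default — the rule is a filter,
not an inference procedure — but `p_adjust = "BH"` is available.

Degenerate variance is handled by convention: when the pooled variance is
zero, $p = 1$ if the group means are equal and $p = 0$ otherwise. This
keeps noise-free synthetic data well-defined.

## Positional classification

Each lncRNA receives exactly one of six labels relative to the
protein-coding annotation, evaluated in precedence order: exon overlap
($\ge 1$ bp), then intron overlap, then proximity, then intergenic. The
field's verbal definitions leave three choices open, resolved as follows:

* **Precedence** exonic > intronic > bidirectional > intergenic: exon
  overlap is the strongest structural relation and the common annotation
  practice when several hold at once.
* **Locus representation**: overlap is evaluated against the lncRNA's
  full transcript span (the conservative reading of "the lncRNA
  overlapped..."); `region = "exon_union"` switches to the exon union.
* **Distance convention**: the gap between loci counts bases strictly
  between them, so "less than 1 kb" means `gap_bp < 1000` and a gap of
  exactly 1000 bp is intergenic. Boundary-to-boundary distance is used
  (not TSS-anchored); "regardless of its direction" applies to the
  bidirectional class only.

Sense/antisense compares the lncRNA strand with a deterministically
chosen partner gene: largest overlap, then smallest gap, then smallest
gene id. Classification is strand-flip covariant (flipping every lncRNA
strand swaps sense and antisense labels only) and translation invariant;
both properties are exercised in the test suite, and the classifier is
checked for exact agreement against an exhaustive brute-force oracle on
random genomes.

Internally all coordinates are 0-based half-open (BED-native); GTF input
is converted on read, and writers convert back, so files round-trip
bit-exactly. lncRNA records shorter than 200 nt are rejected at load
time, following the standard length definition of a lncRNA.

## Cis-target search

Intergenic lncRNAs are paired with every gene whose span intersects the
half-open window `[start − w, end + w)` with `w` = 10 kb by default: a
gene edge exactly `w` away is excluded, `w − 1` included. Distances are
edge-to-edge gaps, signed negative when the gene lies upstream of the
lincRNA's 5′ end relative to its strand. Because lincRNAs are by
definition $\ge 1$ kb from every gene, every reported distance has
magnitude $\ge 1000$; this is asserted. Non-intergenic input is an error
(or dropped with a warning under `lenient = TRUE`), since the window
semantics only make sense for lincRNAs.

## Reporting operations

* **Percentages** round half-up (`proportion()`), matching how published
  count tables are conventionally rounded; R's banker's rounding would
  disagree on exact halves.
* **Chromosomal enrichment** is the ratio of specific to expressed
  transcripts per chromosome and biotype; zero denominators yield ratio 0
  with an explicit degenerate flag rather than NaN.
* **Set overlaps** partition the union of named id sets into exclusive
  Venn regions; region counts provably sum to the union size. Published
  Venn figures typically print per-set totals, the union, and the full
  intersection but not the pairwise regions, so validation instantiates
  one consistent completion of those marginals — a synthetic membership
  assignment, documented as such where used.
* **Developmental staging** maps a transcript's first detection day
  during the synchronized first spermatogenic wave to the earliest stage
  that can express it. The timeline landmarks — meiosis from about day
  10, pachytene enrichment by day 14, round spermatids from day 18 — are
  codified as inclusive day cutoffs 10/14/16: day ≤ 10
  `mitotic_or_earlier`, 11–14 `early_spermatocyte`, 15–16
  `pachytene_spermatocyte`, later days `round_spermatid` (so a first
  detection at day 21 is assigned to round spermatids, which appear at
  day 18). The cutoffs are configurable because they codify a narrative
  timeline, not a printed table; the mapping is monotone by construction.
* **Germ-cell specificity** is presence in wild-type testis AND absence
  in the germ-cell-deficient W/Wv mutant testis.
* **2^-ΔΔCt** implements the standard relative quantification identity
  $2^{-[(Ct_{target,s} - Ct_{ref,s}) - (Ct_{target,c} - Ct_{ref,c})]}$,
  with `ddct(a, b, a, b) = 1` for all inputs.

## The synthetic-data generator

The generator defines the validation conditions; it is configuration, not
a tuning knob.

**Genome.** Genes (1–5 exons of 300 bp, introns of 4 kb) are laid out one
per 100-kb slot, 20 kb into the slot, so neighboring geometries cannot
interact. Each planted lncRNA instantiates exactly one subtype
definition: exonic lncRNAs overlap a host exon; intronic lncRNAs sit
strictly inside an intron with ≥ 200 bp margins; bidirectional lncRNAs
start 1–999 bp past the host gene; intergenic lncRNAs 2–30 kb past it —
the 2-kb floor (not 1 kb) keeps planted labels unambiguous under any
boundary convention. Intergenic placements within 10 kb of the host are
recorded as planted cis pairs; slot isolation guarantees no other gene
can enter the window.

**Expression.** Five tissues × 3 replicates by default, log-normal
intensities: background cells draw log2 intensity at $\mu$, a planted
specific transcript draws $\mu + \log_2(\text{fold})$ in its target
tissue, and a ubiquitous fraction (default 0.3, mirroring the existence
of ubiquitously expressed control lncRNAs) draws well above the present
threshold everywhere. Replicate noise is additive Gaussian on log2 with
SD `noise_sd`. Planting the target at $\mu + \log_2(\text{fold})$ makes
the *expected observed* linear fold-change equal the planted fold
exactly, so a planted fold of 3 demonstrably fails the $\ge 5$ criterion
and a planted fold of 20 passes it — the property the recovery tests
rely on. Defaults are $\mu = 6$, $\sigma = 1$ (log2 units), fold 20,
noise 0.3, 2000 transcripts with 2.5% planted testis-specific (~50
transcripts), chosen once as a realistic microarray-like regime where
background cells sit ≥ 6 noise-SDs below the absent threshold.

**Determinism.** Every generator call is wrapped in a seed context; the
same seed reproduces outputs bit for bit, and truth serializes to JSON
losslessly.

**What it does not emulate.** No probe effects, batch effects, intensity-
dependent variance, cross-hybridization, or sequence content; transcripts
are independent, and planted geometries are deliberately unambiguous
rather than borderline. Passing recovery tests therefore demonstrates
correctness of the *rules*, not robustness to real microarray artifacts —
real data should arrive already normalized, ideally with vendor flags.

## Problem sizes used in validation

The test suite and acceptance script run at desk scale, chosen to
exercise every code path with comfortable margins: planted-genome
recovery at 60 lncRNAs over 30 genes; classifier-versus-oracle agreement
on 100 random genomes of ~32 features; specificity recovery on 2000
transcripts × 15 samples over ten seeds (sensitivity and false-positive
rate against planted truth, with noise 0.3 and in the noise-free limit);
and the printed worked ratios recomputed exactly from their census
counts. Genome-scale counts from the original microarray study (tens of
thousands of probes) are inputs to the ratio operations, not targets the
synthetic pipeline is meant to regenerate.

## Known limitations

* The P/M/A background model is a documented stand-in for vendor flags;
  absolute flag counts on real data will depend on how $\mu$ and $\sigma$
  are estimated.
* The fold-change and t-test groupings ("versus each other tissue" vs.
  "versus pooled") are both supported but only one can be default; results
  near the thresholds can differ between readings.
* Classification uses the transcript span by default; exon-union mode can
  demote span-exonic lncRNAs whose exons avoid the gene.
* The cis-target search reports proximity only; it deliberately computes
  no expression correlation and no enrichment statistics.
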