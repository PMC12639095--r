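---
title: "Quantifying 3' tag mRNA-seq and seasonal re-regulation with tagseq3p"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3' tag mRNA-seq and seasonal re-regulation with tagseq3p}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagseq3p)
library(dplyr)
```

## The problem

3' tag mRNA-seq (QuantSeq-style) libraries sequence a single short fragment
at the polyadenylated 3' end of each transcript. Read counts are then
proportional to transcript abundance without gene-length normalization, which
makes the protocol attractive for large field experiments — for example
profiling storage roots of several cassava (*Manihot esculenta*) genotypes
across rainy-to-dry-to-rainy season transitions with three biological
replicates per genotype and time point. The price is that standard
exon-union counting is a poor fit: reads pile up in narrow stacks near
annotated (or mis-annotated) 3' ends, and genuine transcript ends have to be
told apart from scattered mismapped reads.

`tagseq3p` implements a complete, tested quantification and analysis chain
for such data, downstream of a splice-aware aligner:

1. post-alignment quality filtering of single-end tag reads,
2. overlap clustering of read hits into candidate 3'-end sites,
3. detection of soft-clipped polyA tails as transcript-end evidence,
4. validation of clusters across biological replicates,
5. strand-aware assignment of validated clusters to annotated genes,
6. normalization, QC (PCA, sample correlation), negative-binomial
   differential expression between consecutive time points, and
   classification of *re-regulated* genes — genes whose stress response is
   undone when the stress is removed.

A synthetic-data module generates ground-truthed annotation, tag alignments
and count experiments, so every stage is testable without any external
download.

## Alignment filtering

Reads arrive as SAM/BAM (`read_alignments()`, via Rsamtools). Internally all
intervals are 0-based half-open; SAM's 1-based inclusive `POS` is converted
on input. Four per-record criteria define a usable tag
(`passes_filters()`, thresholds in `filter_policy()`):

* **matched fraction** — the aligned (M/=/X) length must exceed
  `min_match_frac` (default 0.5) of the read length. The read length is
  always recomputed from the CIGAR, never assumed, because tag protocols mix
  nominal read lengths (75 bp reads from 76 bp cycles are common).
* **mismatches** — strictly fewer than `max_mismatches` (default 4, from the
  NM tag).
* **alignment score** — the aligner's AS tag must exceed `min_score_frac`
  (default 0.66) of the read length; STAR-style scores are on a read-length
  scale, which is what the default assumes.
* **unique mapping** — NH must equal 1 (`unique_only = TRUE`). Multi-mapper
  counting is undefined for stacked tag reads, so they are dropped by
  default.

All comparisons are strict, so a 37-of-75 nt match fails the 50% rule
(37 < 37.5) and exactly 4 mismatches fail the "fewer than 4" rule. A record
missing one of the tags has that criterion skipped with a counted warning —
never silently passed or failed. Records whose reference name is absent from
the header cannot reach the filter: the underlying htslib parser demotes
them to unmapped, and unmapped records are skipped on input.

## Clusters, polyA evidence, and the replicate rule

Within one sample, the aligned spans of filtered reads are grouped per
(reference, strand) into the connected components of the interval-overlap
relation (`build_clusters()`): a cluster is a maximal set of reads linked by
a chain of pairwise overlaps, its interval is the union span, and its read
count is the expression signal. The merge gap defaults to 0, i.e. strict
overlap — book-ended reads touching at a coordinate do not merge — because a
3'-end stack is by nature contiguous; `gap` is exposed for noisier data.
Clustering is a single sort-and-sweep, so its output is independent of input
record order; the test suite checks it against a brute-force union-find over
all read pairs.

A genuine transcript end announces itself through untemplated polyA: the
aligner soft-clips the tail, so the stored sequence retains it. For a
`+`-strand alignment the tail is the *trailing* clip and is A-rich; for a
`-`-strand alignment the stored read is the reverse complement, so the tail
is the *leading* clip and T-rich (`detect_polya()`). A clip counts as polyA
evidence when it is at least `min_tail = 5` nt long with base purity at
least `min_purity = 0.9`. These two thresholds are this package's choice:
5 nt rejects the 1-2 nt adventitious clips aligners routinely emit, and 0.9
tolerates one sequencing error in tails of 10 nt or longer. Both are
configurable; no positional constraint (clip at the downstream cluster edge)
is applied.

Per biological-replicate group (genotype × time point), per-sample clusters
are merged across samples by the same transitive-overlap rule into
*meta-clusters* (`group_replicates()`). A meta-cluster is **validated** when
at least one of its member clusters individually contains at least
`min_polya_reads = 2` polyA-tailed reads (`validate_metacluster()`). The
alternative reading — at least 2 polyA reads summed over replicates — is
available as `validation_mode = "pooled"`; the two modes differ exactly on
meta-clusters whose evidence is split 1+1 across replicates, and the
per-replicate form is the default because concentrated evidence in a single
library is a stronger indication of a real 3' end than coincident
singletons.

Validated meta-clusters are assigned to the strand-matched annotated gene
with the largest overlap (ties broken alphabetically by gene id); the gene
feature span from the GFF3 is used as the gene extent, since tag clusters
fall inside gene bodies and UTR-specific repair is out of scope. A gene's
count in a sample is the sum of member-cluster read counts for that sample;
validated clusters overlapping no gene are reported as a BED6 intergenic
table rather than silently dropped, and read totals are conserved:
assigned + intergenic + rejected = filtered input reads, per sample.

## Normalization and QC

`filter_low_expression()` keeps genes with at least `min_count = 5` reads in
at least `min_samples = 3` samples — the conventional noise filter for
three-replicate designs. `estimate_size_factors()` implements
median-of-ratios: per gene expressed in all samples, the ratio of each
sample's count to the gene's geometric mean; the per-sample median ratio is
the size factor. The estimator is exact on matrices built as a base profile
times per-sample factors (recovered proportionally to numerical precision)
and agrees with DESeq2's implementation, which the test suite uses as an
independent cross-check.

`vst_transform()` is deliberately simple: `log2(count / size_factor + 1)`.
It is a pseudocount log transform, monotone in counts and log2-like at high
expression, and it is labelled as such (`attr(, "transform")`) in every
output. A fitted mean-dispersion variance-stabilizing transform is *not*
re-implemented here; for the unsupervised QC the transform feeds (PCA,
correlation heatmaps) the difference is immaterial, and an unspecified
internal fit would be harder to test than it is worth.

`run_pca()` treats samples as observations and genes as variables, with
centering and unit-variance scaling on by default; zero-variance genes are
dropped (with a message) before scaling, where they would be undefined.
Explained-variance fractions come from the squared singular values, so they
are non-increasing and sum to at most 1, and a rank-1 matrix yields a PC1
fraction of exactly 1. `sample_correlation()` computes all pairwise Pearson
correlations on the transformed matrix and orders samples by average-linkage
hierarchical clustering on the `1 - r` distance; a zero-variance sample is a
named fatal error rather than a row of `NA`s.

## Differential expression

The DE engine (`nb_wald_test()`) is fully specified and intentionally
compact — a testable negative-binomial Wald test, not a re-implementation of
any larger framework:

* normalized counts `n = count / size_factor`;
* `log2FC = log2((mean_b + c) / (mean_a + c))` with pseudocount `c = 0.5`,
  which bounds the fold change on genes with an all-zero group;
* per-gene dispersion by method of moments from the pooled within-group
  variance, `alpha = max(0, (var - mean) / mean^2)`;
* **dispersion moderation**: the raw `alpha` is shrunk towards the
  experiment-wide trimmed-mean dispersion with `prior_df = 10` prior degrees
  of freedom. With 2-4 replicates the per-gene method-of-moments dispersion
  is so noisy that an unmoderated Wald test is badly anticonservative
  (measured at ~12% rejection at p < 0.05 on null simulations), while a
  small-sample t reference fixes calibration only by destroying power. The
  empirical-Bayes compromise — the same idea that underlies limma and
  edgeR — keeps the null rejection rate at 5-7% across independent null
  simulations while retaining power at two-fold changes. `prior_df = 0`
  restores the unmoderated estimator.
* the Wald statistic `log2FC / se`, with the delta-method standard error
  under NB variance `mean + alpha * mean^2`, is referred to the standard
  normal, two-sided.

FDR control is Benjamini-Hochberg (`bh_adjust()`, a thin wrapper over
`p.adjust`, verified against an exhaustive step-up oracle). A gene is a
significant DEG when `|log2FC| > 0.5` *strictly* and `FDR < 0.05` strictly
(`classify_sig()`); both thresholds are arguments, since reasonable analyses
also use inclusive or slightly different cutoffs. Contrast orientation is
always second condition over first (D1 over R1 for the label "R1-D1").

Across genotypes, `shared_deg_sets()` decomposes the union of per-genotype
DEG sets into the disjoint membership regions of an UpSet plot; the
all-genotype intersection is the *shared DEG* set. Intersection is
direction-agnostic by default (a gene up in one genotype and down in another
still intersects); the per-gene direction is retained in the DE tables for
stricter downstream filtering.

For two consecutive transitions (rainy→dry, dry→rainy),
`classify_reregulation()` labels each shared gene `sig_in_one` (significant
in exactly one transition), `reversed` (significant in both with opposite
direction), or `none`; the first two are *re-regulated* — the signature of
transcriptional resetting when the stress is removed.

## The synthetic-data generator

`simulate_annotation()` places non-overlapping genes (default 20 genes of
500-2000 nt, at least 300 nt apart so clusters can never bridge genes) on
one reference, on both strands. `simulate_tag_reads()` emits 75 nt
single-end alignments whose 3' ends fall within a 50 nt window inside each
gene's 3' terminus. The window is deliberately smaller than the minimum
aligned length (63 nt with the longest simulated tail), so one gene's reads
always form a single overlap cluster — the noise-free regime in which exact
count recovery is a meaningful test. Truth counts are log-normal
(median 30 reads/gene/sample) floored at 2, emulating detectably expressed
genes whose 3' sites carry at least the two reads the validation rule
requires. A configurable fraction of reads (default 1) receives a 6-12 nt
polyA clip, placed strand-appropriately so both orientations of
`detect_polya()` are exercised. NM/AS/NH tags are written to pass the
default filters; optional decoy reads violate exactly one criterion each and
are labelled in the ground truth. Reads are emitted directly as SAM —
the package's scope starts downstream of the aligner, so simulating FASTQ
would only re-test the aligner.

`simulate_count_experiment()` generates the statistical layer: NB counts
(default dispersion 0.1, the typical magnitude for biological replicates of
this kind) for one or more genotypes over the time course R1→D1→R2 with 3
replicates, log-normal baseline means centred at 100 counts, optional
per-sample depth factors, a planted fraction of persistent DE genes, and a
planted set of 26 re-regulated genes (|log2FC| = 2 at baseline mean 200 in
the first transition, half reverting and half staying — so both
re-regulation criteria are represented). The count of 26 mirrors the scale
on which such resetting is typically observed in shared DEG sets; it is a
fixture design choice, not an empirical claim.

What the simulations do **not** emulate: positional biases and internal
priming on genomic A-tracts, sequencing-error profiles in tails, overlapping
or nested gene models, unannotated 3' UTR extensions, and multi-mapping
structure. Passing tests therefore demonstrate algorithmic correctness under
the stated model, not robustness to every artifact of real libraries.

## Numerical and interface choices

* Coordinates: 0-based half-open everywhere internally; SAM and GFF3
  (1-based inclusive) converted at the boundary.
* Strict inequalities in every quoted threshold (matched fraction,
  mismatches, score, log2FC, FDR).
* Ties in gene assignment and overlap listing broken lexicographically by
  gene id, making outputs order-independent and reproducible.
* Degenerate inputs: empty SAM → empty stream; empty sample → all-zero
  column with a warning; a gene with `se = 0` in the Wald test gets p = 1;
  an all-zero contrast group is fatal.
* Determinism: every generator takes a seed; `run_pipeline()` seeds once
  from the config and writes a manifest with md5 checksums of all outputs,
  so identical configurations produce identical manifests.
* Problem sizes in the test and acceptance runs (20-gene read-level
  fixtures, 800-3000 gene count simulations, 100 random clustering
  instances up to 1000 intervals) were chosen to exercise every code path
  at desk scale while keeping the full suite under a few minutes.

## Command line

The installed `exec/tag3p` script exposes
`simulate | quantify | normalize | qc | de | reregulate | run-all` over a
single YAML configuration (schema in `?validate_config`); every subcommand
is a thin wrapper over `run_pipeline()`. Exit codes: 0 success, 2
configuration or input error (with the offending key named), 1 internal
error.

## Known limitations

* The log2 pseudocount transform is not a variance-stabilizing transform in
  the strict sense; very low-count genes retain above-average variance on
  the transformed scale.
* The DE engine tests one two-group contrast at a time; it fits no
  time-course model and applies no fold-change shrinkage, so ranking genes
  by raw log2FC at low counts is noisier than shrinkage-based rankings.
* Cluster-to-gene assignment is winner-takes-all by overlap; a meta-cluster
  genuinely spanning two genes contributes all its reads to one of them.
* The replicate validation rule is applied per genotype × time point group;
  evidence is never pooled across conditions.
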