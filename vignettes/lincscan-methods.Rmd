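---
title: "Methods: lincRNA discovery and spatiotemporal expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lincRNA discovery and spatiotemporal expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lincscan)
```

# The problem

Long intergenic noncoding RNAs (lincRNAs) are transcripts of at least
200 nt that do not overlap annotated protein-coding genes and carry no
protein-coding capacity. Catalogues of lincRNAs are typically built from
RNA-seq assemblies by (i) classifying assembled transcript models against a
reference annotation, (ii) filtering by structure, expression reliability
and genomic distance, and (iii) removing transcripts with coding potential.
Downstream, lincRNAs are characterised by where (tissue panel) and when
(time course) they are expressed, and by co-expression with their genomic
neighbours. `lincscan` implements this full chain, together with a
synthetic-data generator that plants known truth into every analysis layer,
so the pipeline's behaviour can be verified end to end.

# Discovery model

## Positional classification

`classify_vs_reference()` assigns each candidate one of four positional
classes by interval arithmetic on 1-based inclusive coordinates (the GTF
convention, used throughout):

* **overlap** — any candidate exon shares ≥ 1 bp with any reference exon,
  on either strand. Strand is deliberately ignored: "intergenic" is a
  positional property, and a transcript overlapping a coding exon in
  antisense is still not intergenic.
* **intronic** — the candidate span lies wholly inside a reference gene
  span without exon overlap.
* **near** — no overlap, but the gap to the nearest gene span is < 500 bp.
* **u** (intergenic) — everything else; by construction the gap is ≥ 500 bp.

Distances are span-to-span gaps in base pairs (0 for touching/overlapping
spans). A candidate on a chromosome absent from the reference is classed
`u` with infinite distance and a warning, rather than an error, because
scaffold-only candidates are common in draft genomes.

## Filter cascade

`apply_filter_cascade()` applies, in order: class `u`; exon count ≥ 2;
expression reliability; distance ≥ 500 bp; spliced length ≥ 200 bp;
coding-potential consensus. All thresholds use *inclusive survival*
(a transcript at exactly 500 bp or exactly 200 bp survives). Expression
reliability defaults to "max FPKM over samples ≥ 0.5" (`fpkm_mode = "max"`);
the stricter per-sample variant (`"all"`) is provided because pipelines
that filter each per-sample assembly before merging effectively apply the
cut per sample, and the two interpretations differ. Each stage is recorded
in an audit table whose counts chain (`n_out[k] = n_in[k+1]`); the audit is
order-dependent but the final catalogue is not — the cascade is a pure
intersection, which the test suite verifies by permuting stages.

## Coding-potential consensus

Three independent scorers stand in for the external classifiers a
production pipeline would call, preserving the decisive property:
*intersection consensus* — a transcript is kept only when all three
scorers label it noncoding.

* **ORF scorer**: longest ATG→in-frame-stop ORF over the three forward
  frames (assembled transcripts are stranded, so reverse frames are not
  scanned); coding at ORF ≥ 300 nt or coverage ≥ 0.5. The 300-nt cut is
  the classical "100-codon" convention for distinguishing noncoding RNA.
* **Fickett TESTCODE**: the published position-asymmetry/composition
  statistic with its published lookup tables and weights; coding at the
  published cut of 0.95. The statistic is refused below 50 nt, where its
  position parameters are meaningless.
* **Hexamer log-likelihood ratio**: mean over all overlapping hexamer
  windows of log2(coding/noncoding frequency) under tables trained with
  `train_hexamer_table()` (pseudocount 1 over all 4096 hexamers; windows
  containing `N` are skipped); coding when positive.

The consensus is monotone (making any score more coding-like can never turn
a coding call into noncoding), a property the tests check over random score
draws. An alternative rule — discard only transcripts called coding by
*all three* scorers — is available (`rule = "not_all_coding"`); the two
rules differ exactly on transcripts with mixed votes, and the stricter
keep-iff-all-noncoding default reflects how per-tool catalogues are usually
intersected into a consensus set.

# Expression analysis

All expression is handled as FPKM (fragments per kilobase of transcript per
million mapped reads); `compute_fpkm()` provides the closed form for raw
counts. Heatmap-style transforms go through `log_z_transform()`:
log(FPKM + 1) followed by Z-scoring per column group. Both log2 and log10
are supported because tissue-panel displays conventionally use log2 while
time-course clustering uses log10; the temporal functions default to log10
and the transform base is a parameter everywhere.

* **Tissue specificity**: a feature is "expressed" in a tissue when its
  tissue-mean FPKM is ≥ 0.5 (the same reliability cut as discovery, kept
  for consistency; configurable). The label is the tissue name iff exactly
  one tissue is expressed.
* **HF enrichment**: hair-follicle mean ≥ 20× the mean of the pooled other
  tissue means *and* ≥ 2.5× every individual tissue mean. The sentence
  defining such rules names both a collective and a per-tissue comparison,
  so both are enforced; each sub-rule is its own parameter. Zero
  denominators pass (provided the HF mean is positive), since a fold
  against zero is unbounded.
* **Neighbour pairs**: lincRNA–coding gene pairs within a 10-kb
  boundary-inclusive span gap; coding–coding pairs within the same gap are
  the matched comparison class, and seeded random lincRNA–coding pairs the
  null. Correlation is Pearson over tissue-mean vectors (tissue-level, not
  per-sample, because panel designs often have one library per tissue).
  Distributions are compared by the two-sample, two-sided, asymptotic
  Kolmogorov–Smirnov test. Pairs with a zero-variance member are dropped
  with a warning (their correlation is undefined).

# Temporal analysis

The design is five time points (May, Jun, Aug, Sep, Oct) × 3 replicates,
split by the seasonal transition into an early (May–Jun) and late
(Aug–Oct) block.

* **Differential expression** (`pairwise_de()`): for each of the 10
  time-point pairs, log2FC = log2((mean_B + ε)/(mean_A + ε)) with
  ε = 0.1 FPKM stabilising fold changes at zero expression; the p-value is
  a two-sample t-test on log2(FPKM + 1); BH correction per comparison;
  significant iff |log2FC| ≥ 1 and q ≤ 0.05. The t-test uses the
  **pooled-variance** form by default: at n = 3 per group the
  Welch–Satterthwaite approximation is measurably conservative (its true
  size at α = 0.05 is ≈ 0.035 in simulation), whereas the pooled test is
  exact under the balanced, shared-noise design this package models; Welch
  remains available (`var_equal = FALSE`) for unequal-variance settings.
  When a group has zero variance (the noise-free limit), the p-value is
  defined as 1 for equal means and 0 otherwise, the limit of the statistic.
* **Time-specific genes**: significant in ≥ 1 comparison; the *transition
  subset* contains features significant **only** in cross-block
  comparisons.
* **PCA** (`pca_samples()`): features centred on log10(FPKM + 1); constant
  features are excluded; explained-variance fractions sum to 1.
* **Clustering** (`hierarchical_cluster()`): profiles are per-time-point
  means of log10(FPKM + 1); distance 1 − Pearson r; complete linkage; the
  tree is cut at exactly k = 5 (the number of distinct seasonal patterns
  the package's generator plants, and a common choice for one-cycle time
  courses). Cluster ids are relabelled by descending size with ties broken
  by the lexicographically smallest member, making labels deterministic.
  Zero-variance profiles are dropped with a warning.
* **Enrichment** (`hypergeometric_enrichment()`): standard
  over-representation, p = P(X ≥ overlap) from the hypergeometric
  distribution with BH across terms. Because the statistic is discrete the
  p-values are *super-uniform* rather than uniform under the null; the test
  suite therefore checks calibration with the randomised probability
  integral transform (P(X > x) + U·P(X = x), exactly uniform under the
  null) plus an explicit super-uniformity bound, rather than a naive KS
  test against the uniform, which any discrete p-value would fail at large
  sample sizes.

A note on PCA and k-means: sample clustering on PCA scores is sometimes
conflated with PCA itself. The package keeps them separate — `pca_samples()`
returns scores and explained variance only, and users who want sample
clusters can run `stats::kmeans()` on the scores.

# qPCR

`delta_delta_ct()` implements 2^−ΔΔCt with multi-reference normalisation:
technical replicates are averaged first (arithmetic mean of Ct), then
ΔCt = Ct_target − mean(Ct_references) — the arithmetic mean over reference
Cts equals normalising by the geometric mean of the reference quantities,
the standard multi-reference convention. Amplification efficiency defaults
to perfect doubling (base 2) and is exposed as a parameter. The alternative
convention (ΔCt per reference, averaged afterwards) coincides with the
default at efficiency 2, which is why only the former is implemented.
`rnaseq_concordance()` converts both the qPCR relative quantities and the
RNA-seq FPKM series to log2 ratios against the reference time point (Oct)
and reports the per-assay Pearson correlation; zeros in the RNA-seq series
are stabilised with ε = 0.1 and flagged.

The simulated qPCR (`generate_qpcr()`) uses Ct = 30 − log2(FPKM), i.e.
abundance is FPKM itself with non-positive values capped at Ct 40 and
flagged. This convention makes the noise-free round trip exact:
2^−ΔΔCt returns precisely the FPKM ratio, so concordance r is exactly 1 —
the invariant the test suite asserts.

# The synthetic study

`sim_config()` fixes the study conditions; the defaults are the conditions
under which all tests and the acceptance script run:

| parameter | default | meaning |
|---|---|---|
| tissues | 10 tissues + HF | one library per tissue |
| time points | May, Jun, Aug, Sep, Oct × 3 replicates | seasonal course |
| class mix | 55% intergenic-far, 9% each near/overlap/intronic/single-exon/short | candidate classes |
| `prop_coding_like` | 0.15 of far | long-ORF, GC-biased codons |
| `prop_low_expr` | 0.10 of far | flat FPKM < 0.5 |
| `n_tissue_specific` / `n_hf_high` | 15 / 8 | planted panel structure |
| `n_de` / `n_de_coding` | 23 / 40 | planted DE features |
| `de_log2fc` | 2 | cross-block shift (fold change 4) |
| `n_corr_pairs` / `target_r` | 12 / 0.9 | planted neighbour pairs at 1 kb |
| `n_spatiotemporal` / `spatiotemporal_r` | 2 / 0.95 | HF-high + up-regulated pair lincRNAs |
| `noise_sd` | 0.2 | Gaussian SD on log2(FPKM+1) |

Geometry is deterministic: coding genes (3 × 200 bp exons, 400 bp introns)
occupy 40-kb slots; each candidate's class is realised *by construction*
(near at a 200-bp gap, pairs at a 1000-bp gap, all other intergenic
candidates > 10 kb from any gene so that the only ≤ 10-kb lincRNA–coding
pairs are the planted ones). An independent brute-force geometric verifier
in the test suite re-derives every class label.

Planted expression: baselines are log-normal (2^N(log2 15, 0.8)); noise is
Gaussian on log2(FPKM + 1), back-transformed and clamped at zero — so at
`noise_sd = 0` every planted property holds *exactly*, which is what makes
the end-to-end identity test meaningful. The five cluster templates are
block-up, block-down, and single-time-point peaks at Aug, Oct and May;
templates 1–2 are the cross-block shifts, so only their members belong to
the expected transition subset. Planted neighbour pairs use an exact-sample
construction (the partner profile is an affine combination of the
standardised lincRNA profile and an orthogonalised residual), so the sample
Pearson correlation equals the target exactly at zero noise, on the FPKM
scale the analysis actually uses. The two spatiotemporal pair lincRNAs are
additionally HF-high and follow template 1; their coding partners co-vary
with them (deterministic residual direction) and are therefore themselves
differentially expressed — the truth table marks them so.

**What the generator does not emulate**: read-level artefacts (alignment
bias, positional coverage), library-size and length biases inside FPKM,
batch effects, overdispersed counts, correlated noise between features, and
partial class labels (every candidate's class is unambiguous). Passing the
end-to-end tests therefore demonstrates the *logic* of the pipeline —
thresholds, boundary semantics, audit bookkeeping, statistical calibration
under the stated noise model — not robustness to real-data pathologies.

# Numerical and design notes

* Boundary semantics everywhere are inclusive-survival: gap ≥ 500, length
  ≥ 200, FPKM ≥ 0.5, pair gap ≤ 10 kb.
* The BLAST homology filter applies its four bounds as strict inequalities
  (mismatches < 3, identity > 98, gap opens < 6, length > 200); "length"
  defaults to the alignment length, with a `length_on = "transcript"`
  switch because the criterion can also be read against the query
  transcript length.
* Merging (`merge_transcripts()`) collapses identical intron chains
  (identical exon intervals for mono-exon models), extends terminal exons
  to the outermost observed boundaries, and groups transcripts into genes
  by same-strand exonic overlap via union-find; ids are reassigned in
  (chromosome, start, end) order so merges are deterministic.
* Tests that need an independent cluster-agreement measure cross-check the
  package's adjusted Rand index against `mclust::adjustedRandIndex`.
* Problem sizes in the test suite and acceptance script (160 candidates;
  2000 null features; 500 power features; 200 clustering features; 200
  neighbour pairs per side) were chosen as the smallest sizes at which the
  planted effects and the binomial tolerance bands are statistically
  meaningful.

# Known limitations

* The discovery stage assumes stranded transcript models; unstranded
  assemblies would need reverse-frame ORF scanning.
* `classify_vs_reference()` implements the four positional classes a
  lincRNA pipeline needs, not the full assembler class-code vocabulary.
* FPKM is taken as given; no within-pipeline normalisation across samples
  is attempted beyond the FPKM definition itself.
* The deposited catalogue audits (`audit_lincrna_gtf()`,
  `audit_hf_table()`) are I/O-level checks; the published catalogue files
  themselves are third-party data and are not redistributed with the
  package.
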