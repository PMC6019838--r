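# lincscan

Genome-wide discovery of long intergenic noncoding RNAs (lincRNAs) and
analysis of their spatiotemporal expression, packaged as a tested, reusable R
pipeline. The intended users are transcriptomics analysts who have assembled
transcript models (GTF), transcript sequences (FASTA) and FPKM expression
matrices across a tissue panel and/or a time course, and who want a
reproducible route from "assembled transcripts" to "lincRNA catalogue with
tissue-specific, hair-follicle-enriched, time-specific and co-expression
annotations". A synthetic-data module generates all of these inputs with
planted ground truth, so every stage of the pipeline is verifiable without
any external download.

## What it computes

**Discovery.** Candidate transcripts are classified against the reference
annotation by interval geometry (intergenic `u`, intronic, near, overlap;
distance to the nearest coding gene span) and passed through an auditable
filter cascade: class `u` → multi-exon → reliably expressed (max FPKM ≥ 0.5)
→ ≥ 500 bp from coding genes → spliced length ≥ 200 bp → consensus
noncoding. The coding-potential consensus combines three independent
scorers, and a transcript survives only if **all three** call it noncoding:

* ORF scorer: longest ATG→stop open reading frame across the three forward
  frames; coding if ORF ≥ 300 nt or ORF coverage ≥ 0.5;
* Fickett TESTCODE statistic (published position/composition lookup tables);
  coding at the classical cut of 0.95;
* hexamer log-likelihood ratio, mean over step-1 hexamer windows of
  log2(coding/noncoding frequency) under trained hexamer tables; coding if
  positive.

**Expression analysis.** Tissue-specificity (expressed, mean FPKM ≥ 0.5, in
exactly one tissue), hair-follicle enrichment (HF mean ≥ 20× the pooled mean
of the other tissues **and** ≥ 2.5× each individual tissue), neighbour-pair
co-expression (lincRNA–coding gene pairs within 10 kb, Pearson correlation
over tissue means, Kolmogorov–Smirnov comparison against coding–coding and
random pairs), pairwise time-point differential expression (log2 fold change
with ε = 0.1, pooled two-sample t on log2(FPKM+1), Benjamini–Hochberg; a
feature is significant at |log2FC| ≥ 1 and q ≤ 0.05), time-specific and
seasonal-transition calls, sample PCA, complete-linkage hierarchical
clustering with 1 − Pearson r distance cut at k = 5, hypergeometric set
enrichment, and RT-qPCR concordance via the 2^−ΔΔCt method with
multi-reference normalisation.

## Worked example

A complete noise-free synthetic study, discovery run and downstream
analysis:

```r
library(lincscan)

cfg <- sim_config(seed = 1, noise_sd = 0)     # 160 candidates, 60 coding genes
sim <- simulate_study(cfg)
res <- discover_lincrnas(sim$reference, sim$candidates, sim$expression,
                         sim$sequences, sim$hexamer_table)
res$audit
#>                 stage n_in n_removed n_out
#> 1             class_u  160        44   116
#> 2          multi_exon  116        14   102
#> 3           expressed  102         9    93
#> 4            distance   93         0    93
#> 5              length   93        14    79
#> 6 noncoding_consensus   79        13    66
```

Each audit row is one filter stage: 44 candidates were intronic, near or
exon-overlapping; 14 were single-exon; 9 never reached FPKM 0.5; 14 were
shorter than 200 bp; 13 were called coding by at least one scorer. The 66
survivors are exactly the planted lincRNAs (precision = recall = 1 on the
generator's truth labels).

```r
feature_stats(res$lincrnas)
#> Catalogue: 66 transcripts in 66 genes
#>   mean exons/gene (distinct intervals): 2.00
#>   mean exons/transcript:                2.00
#>   mean transcripts/gene:                1.00
#>   mean spliced transcript length:       402.0 bp

hf  <- detect_hf_high(sim$expression, sim$metadata)        # 8 HF-high lincRNAs
de  <- pairwise_de(sim$expression, sim$metadata)
tsg <- time_specific_genes(de)
length(tsg$time_specific); length(tsg$transition)
#> [1] 65
#> [1] 38

cl <- hierarchical_cluster(sim$expression[tsg$time_specific, ], sim$metadata, k = 5)
pairs <- find_neighbor_pairs(res$lincrnas, sim$reference)
spatiotemporal_overlap(names(hf)[hf], tsg$time_specific, cl, pairs,
                       sim$expression, sim$metadata)$neighbors
#>    linc_id coding_id  gap cluster pearson_r    p_value
#> 1 CAND0001    CG0001 1000       1      0.95 0.01332001
#> 2 CAND0007    CG0002 1000       1      0.95 0.01332001
```

The last table is the spatiotemporal report: lincRNAs that are both HF-high
and differentially expressed, with their ≤ 10 kb coding neighbours and the
Pearson correlation of the two genes' time-course profiles — here the two
planted neighbour pairs at their planted r = 0.95, both in the up-regulated
cluster 1.

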