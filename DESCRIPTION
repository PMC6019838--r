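Package: lincscan
Title: Discovery and Spatiotemporal Expression Analysis of Long Intergenic Noncoding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for genome-wide discovery of long
    intergenic noncoding RNAs (lincRNAs) from assembled transcript models and
    for their downstream spatiotemporal expression analysis. Candidate
    transcripts are classified against a reference annotation by interval
    geometry, passed through an auditable filter cascade (intergenic class,
    multi-exon, expression reliability, distance to coding genes, length) and
    a three-scorer coding-potential consensus (longest open reading frame,
    Fickett TESTCODE statistic, hexamer log-likelihood ratio). Expression
    utilities call tissue-specific and hair-follicle-highly-expressed
    lincRNAs, analyse neighbour co-expression against proximal protein-coding
    genes, run time-course differential expression with Benjamini-Hochberg
    control, hierarchical co-expression clustering and hypergeometric set
    enrichment, and check RT-qPCR concordance via the 2^-ddCt method. A
    synthetic-data module generates toy annotations, transcript sequences,
    expression matrices and Ct tables with planted ground truth so that every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
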