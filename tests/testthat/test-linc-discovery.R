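ref_one_gene <- function() {
  # gene span 1000-10000 with exons 1000-1200, 5000-5200, 9800-10000
  annotation_set(ex_rows("r1.1", "G1", "chr1", "+",
                         1000, 1200, 5000, 5200, 9800, 10000))
}

test_that("positional classification follows the exon/span/gap rules", {
  ref <- ref_one_gene()
  cands <- annotation_set(rbind(
    ex_rows("ov", "ov", "chr1", "-", 1150, 1250),        # shares 51 bp with exon
    ex_rows("intr", "intr", "chr1", "+", 2000, 2100),    # inside span, no exon overlap
    ex_rows("near", "near", "chr1", "+", 10101, 10200),  # gap 100
    ex_rows("u500", "u500", "chr1", "+", 10501, 10700),  # gap exactly 500
    ex_rows("off", "off", "chrZ", "+", 1, 100)))         # chromosome absent
  expect_warning(cls <- classify_vs_reference(cands, ref), "absent")
  got <- stats::setNames(cls$class, cls$transcript_id)
  expect_equal(got[["ov"]], "overlap")
  expect_equal(cls$distance[cls$transcript_id == "ov"], 0)
  expect_equal(got[["intr"]], "intronic")
  expect_equal(got[["near"]], "near")
  expect_equal(cls$distance[cls$transcript_id == "near"], 100)
  expect_equal(got[["u500"]], "u")
  expect_equal(cls$distance[cls$transcript_id == "u500"], 500)
  expect_equal(got[["off"]], "u")
  expect_true(is.infinite(cls$distance[cls$transcript_id == "off"]))
  # class invariants
  expect_true(all(cls$distance[cls$class == "u"] >= 500))
  expect_true(all(cls$distance[cls$class == "overlap"] == 0))
})

test_that("classification agrees with a brute-force all-pairs interval scan", {
  ref <- random_annotation(60, seed = 101)
  cands <- random_annotation(200, seed = 202)
  cls <- suppressWarnings(classify_vs_reference(cands, ref))
  spans <- ref$transcripts
  gene_spans <- do.call(rbind, lapply(split(spans, spans$gene_id), function(d) {
    data.frame(chrom = d$chrom[1], start = min(d$start), end = max(d$end))
  }))
  for (i in seq_len(nrow(cls))) {
    tid <- cls$transcript_id[i]
    ce <- cands$exons[cands$exons$transcript_id == tid, ]
    overlap <- FALSE
    for (k in seq_len(nrow(ce))) {
      re <- ref$exons[ref$exons$chrom == ce$chrom[k], ]
      if (any(pmax(re$start, ce$start[k]) <= pmin(re$end, ce$end[k]))) overlap <- TRUE
    }
    cs <- min(ce$start); cend <- max(ce$end)
    gs <- gene_spans[gene_spans$chrom == ce$chrom[1], ]
    contained <- any(gs$start <= cs & cend <= gs$end)
    gaps <- ifelse(pmax(gs$start, cs) <= pmin(gs$end, cend), 0,
                   ifelse(cend < gs$start, gs$start - cend - 1, cs - gs$end - 1))
    mind <- if (nrow(gs)) min(gaps) else Inf
    expected <- if (overlap) "overlap" else if (contained) "intronic" else
      if (mind < 500) "near" else "u"
    expect_equal(cls$class[i], expected, label = tid)
    if (!overlap) expect_equal(cls$distance[i], mind, label = tid)
  }
})

test_that("merging collapses intron chains and groups same-strand overlaps", {
  s1 <- annotation_set(ex_rows("tA", "gA", "chr1", "+", 100, 200, 400, 500))
  s2 <- annotation_set(ex_rows("tB", "gB", "chr1", "+", 80, 200, 400, 520))
  s3 <- annotation_set(ex_rows("tC", "gC", "chr1", "+", 100, 200, 400, 500))
  m <- merge_transcripts(list(s1, s2, s3))
  # identical intron chain (201-399) -> one transcript, terminal exons extended
  expect_equal(length(m), 1L)
  expect_equal(m$transcripts$start, 80L)
  expect_equal(m$transcripts$end, 520L)

  # overlapping exons, different intron chains -> one gene, two transcripts
  a <- annotation_set(ex_rows("t1", "g1", "chr1", "+", 100, 300, 500, 700))
  b <- annotation_set(ex_rows("t2", "g2", "chr1", "+", 250, 320, 600, 700))
  m2 <- merge_transcripts(list(a, b))
  expect_equal(length(m2), 2L)
  expect_equal(length(unique(m2$transcripts$gene_id)), 1L)

  # opposite strands never share a gene
  c1 <- annotation_set(ex_rows("t1", "g1", "chr1", "+", 100, 300))
  c2 <- annotation_set(ex_rows("t2", "g2", "chr1", "-", 150, 350))
  m3 <- merge_transcripts(list(c1, c2))
  expect_equal(length(unique(m3$transcripts$gene_id)), 2L)

  # counts are monotone: genes <= transcripts <= input transcripts
  sets <- lapply(1:3, function(i) random_annotation(40, seed = 300 + i))
  mm <- merge_transcripts(sets)
  expect_lte(length(unique(mm$transcripts$gene_id)), length(mm))
  expect_lte(length(mm), sum(vapply(sets, length, integer(1))))
  # merging is deterministic
  mm2 <- merge_transcripts(sets)
  expect_identical(mm$exons, mm2$exons)
})

test_that("filter cascade retains the intended survivors and audits every stage", {
  ref <- ref_one_gene()
  cands <- annotation_set(rbind(
    ex_rows("keep", "keep", "chr1", "+", 20000, 20150, 20400, 20550),
    ex_rows("mono", "mono", "chr1", "+", 30000, 30400),
    ex_rows("dim", "dim", "chr1", "+", 40000, 40150, 40400, 40550),
    ex_rows("tiny", "tiny", "chr1", "+", 50000, 50080, 50400, 50480),
    ex_rows("close", "close", "chr1", "+", 10301, 10450, 10700, 10850)))
  cls <- classify_vs_reference(cands, ref)
  expr <- matrix(1, nrow = 5, ncol = 2,
                 dimnames = list(c("keep", "mono", "dim", "tiny", "close"),
                                 c("s1", "s2")))
  expr["dim", ] <- c(0.4, 0.3)
  report <- data.frame(transcript_id = rownames(expr),
                       consensus_noncoding = TRUE, stringsAsFactors = FALSE)
  res <- apply_filter_cascade(cands, cls, expr, report)
  expect_equal(res$lincrnas$transcripts$transcript_id, "keep")
  expect_equal(res$lincrnas$transcripts$biotype, "lincRNA")
  aud <- res$audit
  expect_equal(aud$stage, c("class_u", "multi_exon", "expressed", "distance",
                            "length", "noncoding_consensus"))
  expect_true(all(aud$n_out == aud$n_in - aud$n_removed))
  expect_equal(aud$n_in[-1], aud$n_out[-nrow(aud)])  # stages chain
  expect_equal(aud$n_removed, c(1, 1, 1, 0, 1, 0))
  # per-sample FPKM mode is stricter
  expr["keep", 2] <- 0.4
  res_all <- apply_filter_cascade(cands, cls, expr, report, fpkm_mode = "all")
  expect_equal(length(res_all$lincrnas), 0L)
  # missing expression row names the transcript
  expect_error(apply_filter_cascade(cands, cls, expr[-1, , drop = FALSE], report),
               "keep")
})

test_that("the final catalogue is order-invariant even though audits are not", {
  sim <- noise_free_study()
  res <- discover_lincrnas(sim$reference, sim$candidates, sim$expression,
                           sim$sequences, sim$hexamer_table)
  # re-apply with a permuted stage order by filtering manually in reverse
  cls <- res$classification
  tx <- sim$candidates$transcripts
  lens <- spliced_lengths(sim$candidates)
  keep <- tx$transcript_id
  keep <- keep[res$coding_report$consensus_noncoding[
    match(keep, res$coding_report$transcript_id)]]
  keep <- keep[lens[keep] >= 200]
  keep <- keep[cls$distance[match(keep, cls$transcript_id)] >= 500]
  keep <- keep[apply(sim$expression[keep, , drop = FALSE], 1, max) >= 0.5]
  keep <- keep[tx$n_exons[match(keep, tx$transcript_id)] >= 2]
  keep <- keep[cls$class[match(keep, cls$transcript_id)] == "u"]
  expect_setequal(keep, res$lincrnas$transcripts$transcript_id)
})

test_that("audit stage removals equal the planted construction counts", {
  sim <- noise_free_study()
  res <- discover_lincrnas(sim$reference, sim$candidates, sim$expression,
                           sim$sequences, sim$hexamer_table)
  truth <- sim$truth$candidates
  aud <- res$audit
  removed <- stats::setNames(aud$n_removed, aud$stage)
  expect_equal(removed[["class_u"]],
               sum(truth$class %in% c("intergenic_near", "exon_overlap", "intronic")))
  expect_equal(removed[["multi_exon"]], sum(truth$class == "single_exon"))
  expect_equal(removed[["expressed"]], sum(truth$low_expr))
  expect_equal(removed[["length"]], sum(truth$class == "short"))
  expect_equal(removed[["noncoding_consensus"]], sum(truth$coding_like))
})

test_that("feature statistics summarise exon/transcript/length structure", {
  one <- annotation_set(ex_rows("t1", "g1", "chr1", "+",
                                1, 100, 201, 300, 401, 500))
  st <- feature_stats(one)
  expect_equal(st$mean_exons_per_gene, 3)
  expect_equal(st$mean_transcripts_per_gene, 1)
  expect_equal(st$mean_transcript_length, 300)
  two <- annotation_set(rbind(
    ex_rows("t1", "g1", "chr1", "+", 1, 100, 201, 300),
    ex_rows("t2", "g1", "chr1", "+", 1, 100, 401, 500)))
  st2 <- feature_stats(two)
  expect_equal(st2$mean_transcripts_per_gene, 2)
  # distinct exonic intervals of the gene: {1-100, 201-300, 401-500}
  expect_equal(st2$mean_exons_per_gene, 3)
  expect_error(feature_stats(annotation_set(NULL)), "empty")
})

test_that("catalogue audits run on GTF files and expression tables", {
  ann <- random_annotation(40, seed = 11)
  p <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, p)
  audit <- audit_lincrna_gtf(p)
  expect_equal(audit$n_transcripts, 40L)
  expect_equal(audit$n_genes, 40L)
  expect_equal(audit$stats$mean_transcript_length,
               mean(spliced_lengths(ann)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(gene = paste0("l", 1:7), HF = runif(7), skin = runif(7))
  utils::write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(audit_hf_table(tsv)$n_features, 7L)
})
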