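# Independent geometric verifier: brute-force overlap/distance scan of a
# candidate against every reference exon and gene span.
verify_class <- function(cand_ann, tid, ref_ann) {
  ce <- cand_ann$exons[cand_ann$exons$transcript_id == tid, ]
  re <- ref_ann$exons
  spans <- do.call(rbind, lapply(split(ref_ann$transcripts, ref_ann$transcripts$gene_id),
                                 function(d) data.frame(chrom = d$chrom[1],
                                                        start = min(d$start),
                                                        end = max(d$end))))
  exon_overlap <- FALSE
  for (i in seq_len(nrow(ce))) {
    same <- re[re$chrom == ce$chrom[i], ]
    if (any(pmax(same$start, ce$start[i]) <= pmin(same$end, ce$end[i]))) {
      exon_overlap <- TRUE
    }
  }
  cs <- min(ce$start); cend <- max(ce$end)
  gs <- spans[spans$chrom == ce$chrom[1], ]
  contained <- any(gs$start <= cs & cend <= gs$end)
  gaps <- ifelse(pmax(gs$start, cs) <= pmin(gs$end, cend), 0,
                 ifelse(cend < gs$start, gs$start - cend - 1, cs - gs$end - 1))
  min_gap <- if (nrow(gs)) min(gaps) else Inf
  if (exon_overlap) return(list(class = "exon_overlap", gap = 0))
  if (contained) return(list(class = "intronic", gap = min_gap))
  if (min_gap < 500) return(list(class = "intergenic_near", gap = min_gap))
  list(class = "intergenic_far", gap = min_gap)
}

test_that("every generated candidate realises its class label exactly", {
  sim <- noise_free_study()
  truth <- sim$truth$candidates
  for (i in seq_len(nrow(truth))) {
    v <- verify_class(sim$candidates, truth$transcript_id[i], sim$reference)
    expected <- switch(truth$class[i],
                       single_exon = "intergenic_far",
                       short = "intergenic_far",
                       truth$class[i])
    expect_equal(v$class, expected, label = truth$transcript_id[i])
    if (expected == "intergenic_far") expect_gte(v$gap, 500)
  }
  # geometry subclasses hold too
  n_ex <- sim$candidates$transcripts$n_exons
  names(n_ex) <- sim$candidates$transcripts$transcript_id
  expect_true(all(n_ex[truth$transcript_id[truth$class == "single_exon"]] == 1L))
  lens <- spliced_lengths(sim$candidates)
  expect_true(all(lens[truth$transcript_id[truth$class == "short"]] < 200))
  expect_true(all(lens[truth$transcript_id[truth$class == "intergenic_far"]] >= 200))
})

test_that("a pure intergenic_far mix yields only far candidates at >= 500 bp", {
  cfg <- sim_config(seed = 3, n_candidates = 20,
                    class_mix = c(intergenic_far = 1, intergenic_near = 0,
                                  exon_overlap = 0, intronic = 0,
                                  single_exon = 0, short = 0),
                    prop_coding_like = 0, prop_low_expr = 0,
                    n_corr_pairs = 5, n_cc_pairs = 2,
                    n_tissue_specific = 2, n_hf_high = 2, n_de = 5,
                    n_de_coding = 5, n_spatiotemporal = 1)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann$truth$candidates), 20L)
  expect_true(all(ann$truth$candidates$class == "intergenic_far"))
  for (tid in ann$truth$candidates$transcript_id) {
    expect_gte(verify_class(ann$candidates, tid, ann$reference)$gap, 500)
  }
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- tiny_config()
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$candidates$exons, b$candidates$exons)
  expect_identical(a$reference$exons, b$reference$exons)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$expression, b$expression)
  expect_identical(a$truth$features, b$truth$features)
  # byte-identical serialisation
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_gtf(a$candidates, p1); write_gtf(b$candidates, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("degenerate configurations behave: no candidates, infeasible genome", {
  cfg0 <- sim_config(seed = 1, n_candidates = 0, n_corr_pairs = 0,
                     n_cc_pairs = 2, n_tissue_specific = 0, n_hf_high = 0,
                     n_de = 0, n_de_coding = 2, n_spatiotemporal = 0,
                     n_coding_genes = 10)
  ann0 <- generate_annotation(cfg0)
  expect_equal(length(ann0$candidates), 0L)
  tiny_genome <- data.frame(chrom = "chr1", length = 1e5)
  cfg_bad <- sim_config(seed = 1, genome = tiny_genome)
  expect_error(generate_annotation(cfg_bad), "genome too small")
  expect_error(sim_config(class_mix = c(intergenic_far = 1)), "class_mix")
})

test_that("noise-free expression realises the planted structure exactly", {
  sim <- noise_free_study()
  feat <- sim$truth$features
  mat <- sim$expression
  meta <- sim$metadata
  tiss_cols <- meta$sample[!is.na(meta$tissue)]
  # tissue-specific: positive in exactly the planted tissue, 0 elsewhere
  ts <- feat[!is.na(feat$tissue), ]
  for (i in seq_len(nrow(ts))) {
    own <- paste0("tissue_", ts$tissue[i])
    expect_gt(mat[ts$feature_id[i], own], 0)
    expect_true(all(mat[ts$feature_id[i], setdiff(tiss_cols, own)] == 0))
  }
  # block-up DE features: Aug/Sep/Oct means exactly 2^lfc times May/Jun
  tpm <- time_point_means(mat, meta)
  up <- feat$feature_id[feat$de & !feat$spatio_partner & !is.na(feat$template) &
                          feat$template == 1L]
  for (f in up) {
    expect_equal(unname(tpm[f, "Aug"] / tpm[f, "May"]), 4)
    expect_equal(unname(tpm[f, "Sep"]), unname(tpm[f, "Oct"]))
  }
  # planted neighbour pairs hit their target correlation exactly
  tm <- tissue_means(mat, meta)
  tp <- sim$truth$pairs
  for (i in seq_len(nrow(tp))) {
    r <- stats::cor(tm[tp$linc_tx[i], ], tm[tp$coding_id[i], ])
    expect_equal(r, tp$target_r[i], tolerance = 1e-12)
  }
  # a target correlation of 1 is achieved exactly even at the sample level
  cfg1 <- tiny_config(seed = 21, target_r = 1, spatiotemporal_r = 1)
  sim1 <- simulate_study(cfg1)
  tp1 <- sim1$truth$pairs
  tm1 <- tissue_means(sim1$expression, sim1$metadata)
  expect_equal(stats::cor(tm1[tp1$linc_tx[3], ], tm1[tp1$coding_id[3], ]), 1,
               tolerance = 1e-12)
})

test_that("Ct generation inverts exactly through 2^-ddCt", {
  # hand-built matrix: target abundance 8 vs calibrator abundance 1
  mat <- rbind(T1 = c(8, 8, 1, 1), REF = c(4, 4, 4, 4))
  colnames(mat) <- c("May_r1", "May_r2", "Oct_r1", "Oct_r2")
  meta <- sample_metadata(colnames(mat), tissue = NA,
                          time_point = rep(c("May", "Oct"), each = 2),
                          replicate = rep(1:2, 2))
  ct <- generate_qpcr(mat, meta, targets = "T1", reference_ids = "REF")
  rq <- delta_delta_ct(ct, "T1", "REF", calibrator = "Oct")
  expect_equal(rq$relative_quantity[rq$condition == "May"], 8)
  expect_equal(rq$relative_quantity[rq$condition == "Oct"], 1)
  # all conditions equal -> all relative quantities 1
  flat <- rbind(T1 = rep(5, 4), REF = rep(4, 4))
  colnames(flat) <- colnames(mat)
  ctf <- generate_qpcr(flat, meta, "T1", "REF")
  expect_true(all(delta_delta_ct(ctf, "T1", "REF", "Oct")$relative_quantity == 1))
  # seeded noise is reproducible; zero abundance is capped and flagged
  n1 <- generate_qpcr(mat, meta, "T1", "REF", noise_sd = 0.2, seed = 4)
  n2 <- generate_qpcr(mat, meta, "T1", "REF", noise_sd = 0.2, seed = 4)
  expect_identical(n1, n2)
  zero <- rbind(T1 = c(0, 0, 2, 2), REF = rep(4, 4))
  colnames(zero) <- colnames(mat)
  ctz <- generate_qpcr(zero, meta, "T1", "REF", ct_max = 40)
  expect_true(all(ctz$capped[ctz$assay == "T1" & ctz$condition == "May"]))
  expect_true(all(ctz$ct[ctz$capped] == 40))
})

test_that("the two fold rules of the HF-high construction hold at noise 0", {
  sim <- noise_free_study()
  feat <- sim$truth$features
  tm <- tissue_means(sim$expression, sim$metadata)
  hf_ids <- feat$feature_id[feat$hf_high]
  expect_gt(length(hf_ids), 0)
  for (f in hf_ids) {
    others <- tm[f, setdiff(colnames(tm), "HF")]
    expect_gte(tm[f, "HF"], 20 * mean(others))
    expect_true(all(tm[f, "HF"] >= 2.5 * others))
  }
})
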