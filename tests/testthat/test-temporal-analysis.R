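time_design <- function(n_rep = 3) {
  tps <- linc_time_points()
  samples <- as.vector(t(outer(tps, seq_len(n_rep), paste, sep = "_r")))
  sample_metadata(samples, tissue = NA,
                  time_point = rep(tps, each = n_rep),
                  replicate = rep(seq_len(n_rep), times = length(tps)))
}

test_that("pairwise DE applies the fold-change and q-value rule", {
  meta <- time_design(3)
  base <- rep(10, 15)
  m <- rbind(up = base, flat = base)
  colnames(m) <- meta$sample
  m["up", meta$time_point %in% c("Aug", "Sep", "Oct")] <- 40
  de <- pairwise_de(m, meta)
  expect_equal(nrow(de), 2 * choose(5, 2))
  ma <- de[de$feature_id == "up" & de$comparison == "May_vs_Aug", ]
  expect_equal(ma$log2_fold_change, log2(40.1 / 10.1))
  expect_true(ma$significant)
  expect_true(all(!de$significant[de$feature_id == "flat"]))
  expect_true(all(de$log2_fold_change[de$feature_id == "flat"] == 0))
  # positive lfc means up-regulation towards the later time point
  expect_gt(ma$log2_fold_change, 0)
  # q >= p always
  expect_true(all(de$q_value >= de$p_value))
  expect_error(pairwise_de(m[, -(1:2)], meta[-(1:2), ]), "< 2 replicates")
})

test_that("BH q-values match the brute-force step-up on the DE output", {
  set.seed(41)
  meta <- time_design(3)
  m <- matrix(2^rnorm(20 * 15, 4, 0.5), nrow = 20,
              dimnames = list(sprintf("f%02d", 1:20), meta$sample))
  de <- pairwise_de(m, meta)
  one <- de[de$comparison == "May_vs_Aug", ]
  expect_equal(one$q_value, oracle_bh(one$p_value), tolerance = 1e-12)
  # and on a tiny literal case
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"),
               oracle_bh(c(0.01, 0.02, 0.03)))
})

test_that("time-specific and transition-subset calls follow the block design", {
  meta <- time_design(3)
  m <- rbind(cross = rep(5, 15), none = rep(5, 15), withins = rep(5, 15))
  colnames(m) <- meta$sample
  m["cross", meta$time_point %in% c("Aug", "Sep", "Oct")] <- 20
  m["withins", meta$time_point == "Aug"] <- 40   # significant within Aug-Oct too
  tsg <- time_specific_genes(pairwise_de(m, meta))
  expect_setequal(tsg$time_specific, c("cross", "withins"))
  expect_equal(tsg$transition, "cross")
  expect_false("none" %in% tsg$time_specific)
})

test_that("planted cross-block DE features are recovered in the transition subset", {
  cfg <- sim_config(seed = 19, noise_sd = 0.1)
  truth <- make_expression_truth(cfg, 120, de = rep(c(TRUE, FALSE), c(100, 20)),
                                 template = rep(c(1L, 2L), 50))
  expr <- generate_expression(cfg, truth)
  tsg <- time_specific_genes(pairwise_de(expr$matrix, expr$metadata))
  planted <- truth$features$feature_id[truth$features$de]
  expect_gte(sum(planted %in% tsg$transition), 95)
})

test_that("PCA produces normalised explained variance and separates blocks", {
  # samples on a line in feature space -> PC1 explains everything
  line <- rbind(a = c(1, 3, 5, 7), b = c(2, 6, 10, 14))
  colnames(line) <- paste0("s", 1:4)
  pc <- pca_samples(line, log_base = 10)
  expect_equal(sum(pc$explained_variance), 1, tolerance = 1e-9)
  expect_gt(pc$explained_variance[1], 0.999)
  expect_error(pca_samples(matrix(1, 2, 3, dimnames = list(c("a", "b"), paste0("s", 1:3)))),
               "constant")
  # two-block time design with 30% shifted features: PC1 splits the blocks
  cfg <- sim_config(seed = 23, noise_sd = 0.2)
  truth <- make_expression_truth(cfg, 200, de = rep(c(TRUE, FALSE), c(60, 140)),
                                 template = 1L)
  expr <- generate_expression(cfg, truth)
  tc <- expr$metadata$sample[!is.na(expr$metadata$time_point)]
  pc2 <- pca_samples(expr$matrix[, tc])
  early <- expr$metadata$time_point[match(tc, expr$metadata$sample)] %in% c("May", "Jun")
  s1 <- pc2$scores[, 1]
  expect_true(max(s1[early]) < min(s1[!early]) || min(s1[early]) > max(s1[!early]))
})

test_that("complete-linkage correlation clustering behaves on canonical shapes", {
  meta <- time_design(2)
  m <- rbind(a = rep(c(1, 1, 9, 9, 9), each = 2),
             b = rep(c(2, 2, 18, 18, 18), each = 2),
             c = rep(c(9, 9, 1, 1, 1), each = 2),
             flat = rep(3, 10))
  colnames(m) <- meta$sample
  expect_warning(cl <- hierarchical_cluster(m, meta, k = 2), "zero-variance")
  expect_false("flat" %in% names(cl$cluster))
  expect_equal(cl$cluster[["a"]], cl$cluster[["b"]])   # identical shapes co-cluster
  expect_false(cl$cluster[["a"]] == cl$cluster[["c"]])
  # anti-correlated profiles sit at distance 2
  d <- 1 - stats::cor(t(cl$profiles))
  expect_equal(d["a", "c"], 2, tolerance = 1e-9)
  # cluster 1 is the largest by the relabelling convention
  expect_equal(unname(table(cl$cluster)[["1"]]), 2L)
})

test_that("five planted templates are recovered (ARI >= 0.9) and match the mclust oracle", {
  cfg <- sim_config(seed = 29, noise_sd = 0.05)
  truth <- make_expression_truth(cfg, 200, de = TRUE, template = rep(1:5, 40))
  expr <- generate_expression(cfg, truth)
  cl <- hierarchical_cluster(expr$matrix[truth$features$feature_id, ],
                             expr$metadata, k = 5)
  planted <- stats::setNames(truth$features$template, truth$features$feature_id)
  ari <- adjusted_rand_index(cl$cluster, planted[names(cl$cluster)])
  expect_gte(ari, 0.9)
  expect_equal(ari,
               mclust::adjustedRandIndex(cl$cluster, planted[names(cl$cluster)]),
               tolerance = 1e-12)
})

test_that("hypergeometric enrichment matches closed forms and exact enumeration", {
  universe <- paste0("u", 1:10)
  res <- hypergeometric_enrichment(universe[1:5],
                                   list(hit = universe[1:5],
                                        miss = universe[6:10]),
                                   universe)
  expect_equal(res$p_value[res$term == "hit"], 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$p_value[res$term == "miss"], 1)   # overlap 0 boundary
  expect_error(hypergeometric_enrichment("a", list(t = "a"), character()),
               "empty universe")
  # exact enumeration oracle on all small configurations
  set.seed(53)
  for (i in 1:30) {
    N <- sample(5:12, 1)
    uni <- paste0("g", seq_len(N))
    K <- sample(1:N, 1); n <- sample(1:N, 1)
    set <- sample(uni, K); clus <- sample(uni, n)
    got <- hypergeometric_enrichment(clus, list(s = set), uni)
    expect_equal(got$p_value,
                 oracle_hyper(got$overlap, K, N, n), tolerance = 1e-12)
  }
})

test_that("enrichment p-values are calibrated under random clusters", {
  # discrete upper-tail p-values are super-uniform; the randomised PIT
  # P(X > x) + U * P(X = x) is exactly uniform under the null
  set.seed(61)
  N <- 500
  uni <- paste0("g", seq_len(N))
  term <- uni[1:100]
  n_draw <- 2000
  p <- numeric(n_draw)
  pit <- numeric(n_draw)
  for (i in seq_len(n_draw)) {
    clus <- sample(uni, 50)
    x <- length(intersect(clus, term))
    p[i] <- stats::phyper(x - 1, 100, N - 100, 50, lower.tail = FALSE)
    pit[i] <- stats::phyper(x, 100, N - 100, 50, lower.tail = FALSE) +
      stats::runif(1) * stats::dhyper(x, 100, N - 100, 50)
  }
  # super-uniformity: P(p <= a) <= a (within binomial tolerance)
  for (a in c(0.01, 0.05, 0.1, 0.25)) {
    expect_lte(mean(p <= a), a + 3 * sqrt(a * (1 - a) / n_draw))
  }
  ks <- suppressWarnings(stats::ks.test(pit, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("spatiotemporal overlap reduces to brute-force set operations", {
  empty <- spatiotemporal_overlap(character(), c("x"), NULL,
                                  data.frame(linc_id = character(),
                                             coding_id = character(),
                                             gap = numeric(),
                                             pair_class = character()),
                                  NULL, NULL)
  expect_length(empty$spatiotemporal, 0)
  expect_equal(nrow(empty$neighbors), 0)

  sim <- noise_free_study()
  feat <- sim$truth$features
  hf <- feat$feature_id[feat$hf_high]
  de <- feat$feature_id[feat$de]
  meta <- sim$metadata
  cl <- hierarchical_cluster(sim$expression[de, ], meta, k = 5)
  pairs <- find_neighbor_pairs(
    subset_transcripts(sim$candidates,
                       feat$feature_id[feat$role == "candidate"]),
    sim$reference)
  sp <- spatiotemporal_overlap(hf, de, cl, pairs, sim$expression, meta)
  expect_setequal(sp$spatiotemporal, intersect(hf, de))
  expect_equal(sum(sp$by_cluster), length(intersect(hf, de)))
  # the planted spatiotemporal lincs appear with their neighbour at r = 0.95
  st <- feat$feature_id[feat$hf_high & feat$de]
  got <- sp$neighbors[sp$neighbors$linc_id %in% st, ]
  expect_equal(nrow(got), 2L)
  expect_equal(got$pearson_r, rep(0.95, 2), tolerance = 1e-9)
})
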