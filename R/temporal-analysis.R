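# Time-course analysis across the five hair-follicle-cycle time points:
# pairwise differential expression, time-specific gene calls, sample PCA,
# hierarchical co-expression clustering and hypergeometric set enrichment.

#' Canonical time-point order of the study design
#' @export
linc_time_points <- function() c("May", "Jun", "Aug", "Sep", "Oct")

# The anagen transition splits the design into an early (May-Jun) and a
# late (Aug-Oct) block; the 6 cross-block comparisons carry the seasonal
# transition signal.
.early_block <- c("May", "Jun")
.late_block <- c("Aug", "Sep", "Oct")

.time_columns <- function(matrix, metadata) {
  meta <- metadata[match(colnames(matrix), metadata$sample), ]
  ok <- !is.na(meta$time_point)
  list(meta = meta[ok, , drop = FALSE],
       matrix = matrix[, ok, drop = FALSE])
}

# Two-sample t-test on two numeric vectors, with a defined degenerate rule:
# when the standard error is zero the p-value is 1 for equal means and 0
# otherwise (stats::t.test refuses essentially-constant data, but the
# noise-free planted-truth runs need this limit). The pooled-variance form
# is the default: with a balanced design and a shared noise model it is
# exact at n = 3, where the Welch-Satterthwaite approximation is
# conservative (true size ~0.035 at alpha = 0.05). Welch remains available
# for unequal-variance settings.
.t_test_p <- function(x, y, var_equal = TRUE) {
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  dm <- mean(x) - mean(y)
  if (var_equal) {
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- s2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- if (se2 > 0) {
      se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    } else {
      n1 + n2 - 2
    }
  }
  if (se2 == 0) return(if (dm == 0) 1 else 0)
  2 * stats::pt(-abs(dm / sqrt(se2)), df)
}

.welch_p <- function(x, y) .t_test_p(x, y, var_equal = FALSE)

#' Pairwise time-point differential expression
#'
#' For each of the 10 unordered time-point pairs: the log2 fold change is
#' `log2((meanB + eps) / (meanA + eps))` on mean FPKM (with A the earlier
#' time point, so positive values are up-regulation towards the later time
#' point); the p-value is a two-sample t-test on `log2(FPKM + 1)` replicate
#' values (pooled variance by default, which is exact for the balanced
#' small-n design; set `var_equal = FALSE` for Welch); q-values are
#' Benjamini-Hochberg across all features within each comparison. A feature
#' is significant in a comparison when `|log2FC| >= lfc_cut` and
#' `q <= alpha` (the fold-change-of-2, corrected-p 0.05 rule).
#'
#' @param matrix FPKM matrix.
#' @param metadata `SampleMetadata`; every time point needs >= 2 replicates.
#' @param eps Fold-change stabiliser added to both means (FPKM).
#' @param lfc_cut,alpha Significance thresholds.
#' @param var_equal Pooled-variance t-test (default) or Welch.
#' @return data.frame of class `DEResult` with columns `feature_id`,
#'   `comparison` (e.g. `"May_vs_Aug"`), `time_a`, `time_b`,
#'   `log2_fold_change`, `p_value`, `q_value`, `significant`.
#' @export
pairwise_de <- function(matrix, metadata, eps = 0.1, lfc_cut = 1, alpha = 0.05,
                        var_equal = TRUE) {
  tc <- .time_columns(matrix, metadata)
  tps <- intersect(linc_time_points(), unique(tc$meta$time_point))
  if (length(tps) < 2) stop("pairwise_de: need >= 2 time points")
  cols <- lapply(tps, function(tp) which(tc$meta$time_point == tp))
  names(cols) <- tps
  bad <- tps[vapply(cols, length, integer(1)) < 2]
  if (length(bad)) {
    stop("pairwise_de: time point(s) with < 2 replicates: ",
         paste(bad, collapse = ", "))
  }
  logm <- log2(tc$matrix + 1)
  out <- list()
  for (i in seq_len(length(tps) - 1)) {
    for (j in seq(i + 1, length(tps))) {
      a <- tps[i]; b <- tps[j]
      ca <- cols[[a]]; cb <- cols[[b]]
      mean_a <- rowMeans(tc$matrix[, ca, drop = FALSE])
      mean_b <- rowMeans(tc$matrix[, cb, drop = FALSE])
      lfc <- log2((mean_b + eps) / (mean_a + eps))
      p <- vapply(seq_len(nrow(logm)), function(k) {
        .t_test_p(logm[k, cb], logm[k, ca], var_equal = var_equal)
      }, numeric(1))
      q <- stats::p.adjust(p, method = "BH")
      out[[paste(a, b)]] <- data.frame(
        feature_id = rownames(matrix),
        comparison = paste0(a, "_vs_", b), time_a = a, time_b = b,
        log2_fold_change = lfc, p_value = p, q_value = q,
        significant = abs(lfc) >= lfc_cut & q <= alpha,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("DEResult", class(res))
  res
}

#' Time-specific genes and the seasonal-transition subset
#'
#' A feature is time-specific when it is significant in at least one of the
#' pairwise comparisons. The transition subset contains the features
#' significant only in cross-block comparisons (one time point in May-Jun,
#' the other in Aug-Oct), i.e. whose differential expression is confined to
#' the early-to-late seasonal transition.
#'
#' @param results `DEResult` data.frame from [pairwise_de()].
#' @return List with `time_specific` (character vector of feature ids),
#'   `transition` (the cross-block-only subset), and `per_comparison`
#'   (named count of significant features per comparison).
#' @export
time_specific_genes <- function(results) {
  stopifnot(is.data.frame(results))
  sig <- results[results$significant, , drop = FALSE]
  time_specific <- sort(unique(sig$feature_id))
  cross <- (sig$time_a %in% .early_block & sig$time_b %in% .late_block) |
    (sig$time_a %in% .late_block & sig$time_b %in% .early_block)
  by_feature <- split(cross, sig$feature_id)
  transition <- sort(names(by_feature)[vapply(by_feature, all, logical(1))])
  per_comparison <- vapply(split(sig$feature_id, sig$comparison), length, integer(1))
  list(time_specific = time_specific, transition = transition,
       per_comparison = per_comparison)
}

#' Principal component analysis of samples
#'
#' Transforms to `log10(FPKM + 1)` (configurable), centres features and
#' projects the samples; explained-variance fractions sum to 1 over all
#' components.
#'
#' @param matrix FPKM matrix with >= 3 samples.
#' @param log_base Base of the log transform applied before PCA.
#' @param offset Added before the log.
#' @return List with `scores` (samples x components) and
#'   `explained_variance` (fractions).
#' @export
pca_samples <- function(matrix, log_base = 10, offset = 1) {
  .check_matrix(matrix)
  if (ncol(matrix) < 3) stop("pca_samples: need >= 3 samples")
  x <- t(log(matrix + offset, base = log_base))
  keep <- apply(x, 2, stats::sd) > 0
  if (!any(keep)) stop("pca_samples: constant matrix")
  pc <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  list(scores = pc$x, explained_variance = ev / sum(ev))
}

#' Hierarchical co-expression clustering of feature profiles
#'
#' Feature profiles are the per-time-point means of `log10(FPKM + 1)`.
#' Distance is `1 - Pearson r` between profiles; the complete-linkage tree
#' is cut to exactly `k` clusters. Cluster ids are relabelled by descending
#' size (ties broken by the lexicographically smallest member id). Features
#' with a zero-variance profile are dropped with a warning before
#' clustering.
#'
#' @param matrix FPKM matrix (typically restricted to DE features).
#' @param metadata `SampleMetadata` with time-point annotations.
#' @param k Number of clusters (default 5).
#' @param log_base,offset Transform applied before profiling.
#' @return List of class `ClusterAssignment` with `cluster` (named integer
#'   vector in `1..k`), `profiles` (feature x time-point matrix used),
#'   `tree` (the `hclust` object) and `k`.
#' @export
hierarchical_cluster <- function(matrix, metadata, k = 5, log_base = 10,
                                 offset = 1) {
  tc <- .time_columns(matrix, metadata)
  tps <- intersect(linc_time_points(), unique(tc$meta$time_point))
  logm <- log(tc$matrix + offset, base = log_base)
  profiles <- vapply(tps, function(tp) {
    rowMeans(logm[, tc$meta$time_point == tp, drop = FALSE])
  }, numeric(nrow(logm)))
  profiles <- base::matrix(profiles, nrow = nrow(logm),
                           dimnames = list(rownames(logm), tps))
  keep <- apply(profiles, 1, stats::sd) > 0
  if (any(!keep)) {
    warning("hierarchical_cluster: dropped ", sum(!keep),
            " feature(s) with zero-variance profiles")
    profiles <- profiles[keep, , drop = FALSE]
  }
  if (nrow(profiles) < k) stop("hierarchical_cluster: fewer features than clusters")
  d <- stats::as.dist(1 - stats::cor(t(profiles)))
  tree <- stats::hclust(d, method = "complete")
  raw <- stats::cutree(tree, k = k)
  # relabel by descending size; ties by smallest member id
  first_member <- vapply(split(names(raw), raw), function(m) sort(m)[1], character(1))
  sizes <- table(raw)
  ord <- order(-as.integer(sizes), first_member)
  relabel <- stats::setNames(seq_len(k), names(sizes)[ord])
  cluster <- stats::setNames(as.integer(relabel[as.character(raw)]), names(raw))
  structure(list(cluster = cluster, profiles = profiles, tree = tree, k = k),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat("ClusterAssignment: ", length(x$cluster), " features in ", x$k,
      " clusters (complete linkage, 1 - Pearson r)\n", sep = "")
  print(table(cluster = x$cluster))
  invisible(x)
}

#' Hypergeometric over-representation of gene sets
#'
#' For each term, the p-value is the upper hypergeometric tail
#' `P(X >= overlap)` of drawing `|cluster|` features from the universe, with
#' the term's features as successes (term sets are intersected with the
#' universe first); q-values are Benjamini-Hochberg across terms.
#'
#' @param cluster_features Character vector, a subset of `universe`.
#' @param gene_sets Named list of character vectors (term -> feature set).
#' @param universe Character vector of all features considered.
#' @return data.frame with `term`, `set_size`, `overlap`, `p_value`,
#'   `q_value`.
#' @export
hypergeometric_enrichment <- function(cluster_features, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("hypergeometric_enrichment: empty universe")
  cluster_features <- intersect(unique(cluster_features), universe)
  n_univ <- length(universe)
  n_clus <- length(cluster_features)
  rows <- lapply(names(gene_sets), function(term) {
    set <- intersect(unique(gene_sets[[term]]), universe)
    overlap <- length(intersect(cluster_features, set))
    p <- stats::phyper(overlap - 1, length(set), n_univ - length(set), n_clus,
                       lower.tail = FALSE)
    data.frame(term = term, set_size = length(set), overlap = overlap,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Spatiotemporal lincRNA report
#'
#' Intersects the hair-follicle highly expressed lincRNAs with the
#' differentially expressed ones, reports each member's co-expression
#' cluster, and lists its proximal (<= 10 kb) protein-coding neighbours
#' with the Pearson correlation (and test p-value) of the two genes'
#' time-point mean expression profiles - the linc/DLX3-style neighbour
#' analysis.
#'
#' @param hf_high Character vector of HF-high lincRNA ids.
#' @param de_lincs Character vector of differentially expressed lincRNA ids.
#' @param clusters `ClusterAssignment` covering the DE features.
#' @param pairs data.frame from [find_neighbor_pairs()].
#' @param matrix FPKM matrix with time-course samples.
#' @param metadata `SampleMetadata`.
#' @return List with `spatiotemporal` (ids in both sets), `by_cluster`
#'   (named counts), and `neighbors` (data.frame `linc_id`, `coding_id`,
#'   `gap`, `cluster`, `pearson_r`, `p_value`).
#' @export
spatiotemporal_overlap <- function(hf_high, de_lincs, clusters, pairs,
                                   matrix, metadata) {
  members <- sort(intersect(hf_high, de_lincs))
  if (!length(members)) {
    return(list(spatiotemporal = character(),
                by_cluster = integer(),
                neighbors = data.frame(linc_id = character(),
                                       coding_id = character(), gap = numeric(),
                                       cluster = integer(), pearson_r = numeric(),
                                       p_value = numeric(),
                                       stringsAsFactors = FALSE)))
  }
  cl <- clusters$cluster[members]
  by_cluster <- table(factor(cl, levels = seq_len(clusters$k)))
  nb <- pairs[pairs$pair_class == "linc_coding" & pairs$linc_id %in% members, ,
              drop = FALSE]
  tc <- .time_columns(matrix, metadata)
  tps <- intersect(linc_time_points(), unique(tc$meta$time_point))
  tp_means <- vapply(tps, function(tp) {
    rowMeans(tc$matrix[, tc$meta$time_point == tp, drop = FALSE])
  }, numeric(nrow(tc$matrix)))
  tp_means <- base::matrix(tp_means, nrow = nrow(tc$matrix),
                           dimnames = list(rownames(tc$matrix), tps))
  res <- lapply(seq_len(nrow(nb)), function(i) {
    x <- tp_means[nb$linc_id[i], ]
    y <- tp_means[nb$coding_id[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      r <- NA_real_; p <- NA_real_
    } else {
      ct <- stats::cor.test(x, y)
      r <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(linc_id = nb$linc_id[i], coding_id = nb$coding_id[i],
               gap = nb$gap[i],
               cluster = unname(clusters$cluster[nb$linc_id[i]]),
               pearson_r = r, p_value = p, stringsAsFactors = FALSE)
  })
  neighbors <- if (length(res)) do.call(rbind, res) else
    data.frame(linc_id = character(), coding_id = character(), gap = numeric(),
               cluster = integer(), pearson_r = numeric(), p_value = numeric(),
               stringsAsFactors = FALSE)
  list(spatiotemporal = members,
       by_cluster = stats::setNames(as.integer(by_cluster), names(by_cluster)),
       neighbors = neighbors)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' used to quantify cluster recovery against planted templates.
#'
#' @param a,b Vectors of cluster labels over the same items (matched by
#'   name when both are named).
#' @return Numeric ARI in `[-1, 1]`; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  }
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
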