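# FPKM handling, transforms, tissue-specificity and hair-follicle enrichment
# calls, and neighbour-pair co-expression analysis across a tissue panel.

#' Sample metadata table
#'
#' @param sample Character vector of sample ids (matrix column names).
#' @param tissue Tissue per sample (e.g. `"kidney"`, `"HF"` for hair
#'   follicle); may be `NA` for pure time-course samples.
#' @param time_point Time point per sample (one of the study's five months)
#'   or `NA` for tissue-panel samples.
#' @param replicate Integer replicate index.
#' @return data.frame of class `SampleMetadata`.
#' @export
sample_metadata <- function(sample, tissue = NA_character_,
                            time_point = NA_character_, replicate = 1L) {
  df <- data.frame(sample = as.character(sample),
                   tissue = as.character(tissue),
                   time_point = as.character(time_point),
                   replicate = as.integer(replicate),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample)) stop("sample_metadata: duplicate sample ids")
  if (any(is.na(df$tissue) & is.na(df$time_point))) {
    stop("sample_metadata: every sample needs a tissue or a time point")
  }
  class(df) <- c("SampleMetadata", class(df))
  df
}

.check_matrix <- function(matrix, metadata = NULL) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("expression matrix needs feature row names and sample column names")
  }
  if (any(!is.finite(matrix)) || any(matrix < 0)) {
    stop("expression matrix must be finite and non-negative")
  }
  if (!is.null(metadata)) {
    missing <- setdiff(colnames(matrix), metadata$sample)
    if (length(missing)) {
      stop("metadata missing for sample(s): ", paste(missing, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Convert raw counts to FPKM
#'
#' FPKM = count / (length / 1000) / (mapped_reads / 1e6): fragments per
#' kilobase of transcript per million mapped reads.
#'
#' @param counts Integer feature-by-sample matrix of fragment counts.
#' @param lengths Named vector of feature lengths in bp (all > 0).
#' @param mapped_reads Named (or positionally matched) vector of per-sample
#'   mapped-read totals (all > 0).
#' @return FPKM matrix with the same dimnames as `counts`.
#' @export
compute_fpkm <- function(counts, lengths, mapped_reads) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("compute_fpkm: negative counts")
  if (any(lengths <= 0)) stop("compute_fpkm: lengths must be > 0")
  if (any(mapped_reads <= 0)) stop("compute_fpkm: mapped_reads must be > 0")
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  if (!is.null(names(mapped_reads))) mapped_reads <- mapped_reads[colnames(counts)]
  kb <- as.numeric(lengths) / 1000
  mill <- as.numeric(mapped_reads) / 1e6
  sweep(sweep(counts, 1, kb, "/"), 2, mill, "/")
}

#' Log transform and per-group Z-score of an FPKM matrix
#'
#' Values become `log(FPKM + offset)` in the chosen base, then each column
#' group (by default each column on its own; pass `groups` to pool, e.g.,
#' all samples of a tissue) is standardised: subtract the group mean and
#' divide by the group standard deviation, computed over all entries of the
#' group's columns. A zero-variance group maps to Z = 0.
#'
#' @param matrix FPKM matrix.
#' @param log_base 2 or 10.
#' @param offset Added before the log (default 1).
#' @param groups Optional vector (length `ncol`) assigning columns to
#'   groups.
#' @param z Set `FALSE` to return the log-transformed matrix without
#'   standardisation.
#' @return Transformed matrix.
#' @export
log_z_transform <- function(matrix, log_base = 2, offset = 1, groups = NULL,
                            z = TRUE) {
  .check_matrix(matrix)
  stopifnot(log_base %in% c(2, 10))
  x <- log(matrix + offset, base = log_base)
  if (!z) return(x)
  if (is.null(groups)) groups <- colnames(matrix)
  stopifnot(length(groups) == ncol(matrix))
  for (g in unique(groups)) {
    cols <- which(groups == g)
    v <- x[, cols, drop = FALSE]
    s <- stats::sd(as.vector(v))
    x[, cols] <- if (is.na(s) || s == 0) 0 else (v - mean(v)) / s
  }
  x
}

#' Per-feature tissue mean expression
#'
#' @param matrix FPKM matrix.
#' @param metadata `SampleMetadata`; only samples with a non-`NA` tissue are
#'   used.
#' @return Feature-by-tissue matrix of mean FPKM.
#' @export
tissue_means <- function(matrix, metadata) {
  .check_matrix(matrix, metadata)
  meta <- metadata[match(colnames(matrix), metadata$sample), ]
  tissues <- unique(meta$tissue[!is.na(meta$tissue)])
  if (!length(tissues)) stop("tissue_means: no tissue-annotated samples")
  out <- vapply(tissues, function(t) {
    cols <- which(!is.na(meta$tissue) & meta$tissue == t)
    if (!length(cols)) stop("tissue_means: tissue with zero samples: ", t)
    rowMeans(matrix[, cols, drop = FALSE])
  }, numeric(nrow(matrix)))
  out <- base::matrix(out, nrow = nrow(matrix),
                      dimnames = list(rownames(matrix), tissues))
  out
}

#' Call tissue-specific features
#'
#' A feature counts as expressed in a tissue when its mean FPKM there
#' reaches `expressed_threshold`. The label is the tissue name when the
#' feature is expressed in exactly one tissue, `"multi"` for two or more,
#' and `"not_expressed"` for none.
#'
#' @param matrix FPKM matrix.
#' @param metadata `SampleMetadata` with at least two tissues.
#' @param expressed_threshold Mean-FPKM threshold for "expressed".
#' @return Named character vector of labels per feature.
#' @export
classify_tissue_specific <- function(matrix, metadata, expressed_threshold = 0.5) {
  tm <- tissue_means(matrix, metadata)
  if (ncol(tm) < 2) stop("classify_tissue_specific: need >= 2 tissues")
  expressed <- tm >= expressed_threshold
  n_exp <- rowSums(expressed)
  label <- rep("multi", nrow(tm))
  label[n_exp == 0] <- "not_expressed"
  one <- which(n_exp == 1)
  label[one] <- colnames(tm)[apply(expressed[one, , drop = FALSE], 1, which)]
  stats::setNames(label, rownames(tm))
}

#' Call hair-follicle highly expressed features
#'
#' A feature is HF-high when its mean hair-follicle FPKM is (a) at least
#' `fold_vs_mean` times the mean of the pooled other-tissue means and
#' (b) at least `fold_vs_each` times every individual other-tissue mean.
#' Other-tissue means of zero pass their comparison (provided the HF mean
#' itself is positive).
#'
#' @param matrix FPKM matrix.
#' @param metadata `SampleMetadata` containing tissue `hf_tissue` plus at
#'   least one other tissue.
#' @param fold_vs_mean,fold_vs_each Fold thresholds.
#' @param hf_tissue Name of the hair-follicle tissue.
#' @return Named logical vector per feature.
#' @export
detect_hf_high <- function(matrix, metadata, fold_vs_mean = 20,
                           fold_vs_each = 2.5, hf_tissue = "HF") {
  tm <- tissue_means(matrix, metadata)
  if (!hf_tissue %in% colnames(tm)) {
    stop("detect_hf_high: tissue '", hf_tissue, "' absent from metadata")
  }
  hf <- tm[, hf_tissue]
  others <- tm[, setdiff(colnames(tm), hf_tissue), drop = FALSE]
  if (!ncol(others)) stop("detect_hf_high: need at least one non-HF tissue")
  pooled <- rowMeans(others)
  vs_mean <- hf >= fold_vs_mean * pooled
  # per-tissue comparison with zero-denominator pass
  vs_each <- vapply(seq_len(nrow(tm)), function(i) {
    o <- others[i, ]
    all(o == 0 | hf[i] >= fold_vs_each * o)
  }, logical(1))
  out <- hf > 0 & vs_mean & vs_each
  stats::setNames(out, rownames(tm))
}

#' Find proximal gene pairs
#'
#' Emits a pair for every lincRNA gene / protein-coding gene combination
#' whose gene-span gap is at most `max_gap` bp (boundary inclusive; spans
#' that touch or overlap have gap 0), and likewise every proximal
#' coding-coding pair, which serve as the comparison class for the
#' co-expression analysis.
#'
#' @param lincs,codings `AnnotationSet`s on a shared chromosome namespace.
#' @param max_gap Maximum span-to-span gap in bp (default 10 kb).
#' @return data.frame with columns `linc_id` (or first gene), `coding_id`,
#'   `gap` and `pair_class` (`"linc_coding"` or `"coding_coding"`).
#' @export
find_neighbor_pairs <- function(lincs, codings, max_gap = 10000) {
  stopifnot(inherits(lincs, "AnnotationSet"), inherits(codings, "AnnotationSet"))
  linc_spans <- gene_span_granges(lincs)
  coding_spans <- gene_span_granges(codings)
  pair_up <- function(a, b, class, self = FALSE) {
    if (!length(a) || !length(b)) {
      return(data.frame(linc_id = character(), coding_id = character(),
                        gap = numeric(), pair_class = character(),
                        stringsAsFactors = FALSE))
    }
    hits <- GenomicRanges::findOverlaps(a, b, maxgap = max_gap,
                                        ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    if (self) {
      keep <- a$gene_id[qi] < b$gene_id[si]  # each unordered pair once
      qi <- qi[keep]; si <- si[keep]
    }
    if (!length(qi)) {
      return(data.frame(linc_id = character(), coding_id = character(),
                        gap = numeric(), pair_class = character(),
                        stringsAsFactors = FALSE))
    }
    gap <- GenomicRanges::distance(a[qi], b[si], ignore.strand = TRUE)
    data.frame(linc_id = a$gene_id[qi], coding_id = b$gene_id[si],
               gap = as.numeric(gap), pair_class = class,
               stringsAsFactors = FALSE)
  }
  out <- rbind(pair_up(linc_spans, coding_spans, "linc_coding"),
               pair_up(coding_spans, coding_spans, "coding_coding", self = TRUE))
  out <- out[order(out$pair_class, out$linc_id, out$coding_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Neighbour-pair co-expression analysis
#'
#' Computes the Pearson correlation of each pair over the tissue-mean
#' expression vectors, draws `n_random` random lincRNA/protein-coding pairs
#' (without replacement, seeded) as the null, and compares the linc-coding
#' correlation distribution with both the coding-coding and the random
#' distributions by two-sample, two-sided, asymptotic Kolmogorov-Smirnov
#' tests. Pairs with a zero-variance member are dropped with a warning.
#'
#' @param pairs data.frame from [find_neighbor_pairs()].
#' @param matrix FPKM matrix covering all paired genes.
#' @param metadata `SampleMetadata`.
#' @param n_random Number of random pairs for the null.
#' @param seed Integer seed for the random-pair draw.
#' @return List with `pairs` (input plus `pearson_r`, including the random
#'   pairs) and `ks` (data.frame `comparison`, `statistic`, `p_value`).
#' @export
pair_correlation_analysis <- function(pairs, matrix, metadata,
                                      n_random = 100, seed = 1) {
  tm <- tissue_means(matrix, metadata)
  missing <- setdiff(unique(c(pairs$linc_id, pairs$coding_id)), rownames(tm))
  if (length(missing)) {
    stop("pair_correlation_analysis: expression missing for ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  linc_ids <- unique(pairs$linc_id[pairs$pair_class == "linc_coding"])
  coding_ids <- unique(c(pairs$coding_id,
                         pairs$linc_id[pairs$pair_class == "coding_coding"]))
  rnd <- if (n_random > 0 && length(linc_ids) && length(coding_ids)) {
    combos <- expand.grid(linc_id = linc_ids, coding_id = coding_ids,
                          stringsAsFactors = FALSE)
    existing <- paste(pairs$linc_id, pairs$coding_id)
    combos <- combos[!paste(combos$linc_id, combos$coding_id) %in% existing, ]
    set.seed(seed)
    take <- sample(nrow(combos), min(n_random, nrow(combos)))
    data.frame(linc_id = combos$linc_id[take], coding_id = combos$coding_id[take],
               gap = NA_real_, pair_class = "random", stringsAsFactors = FALSE)
  } else {
    NULL
  }
  all_pairs <- rbind(pairs, rnd)
  r <- vapply(seq_len(nrow(all_pairs)), function(i) {
    x <- tm[all_pairs$linc_id[i], ]
    y <- tm[all_pairs$coding_id[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  if (anyNA(r)) {
    warning("pair_correlation_analysis: dropped ", sum(is.na(r)),
            " pair(s) with zero-variance expression")
  }
  all_pairs$pearson_r <- r
  all_pairs <- all_pairs[!is.na(r), , drop = FALSE]

  ks_row <- function(a, b, label) {
    ra <- all_pairs$pearson_r[all_pairs$pair_class == a]
    rb <- all_pairs$pearson_r[all_pairs$pair_class == b]
    if (!length(ra) || !length(rb)) {
      return(data.frame(comparison = label, statistic = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    kt <- suppressWarnings(stats::ks.test(ra, rb, exact = FALSE))
    data.frame(comparison = label, statistic = unname(kt$statistic),
               p_value = kt$p.value, stringsAsFactors = FALSE)
  }
  ks <- rbind(ks_row("linc_coding", "coding_coding", "linc_coding_vs_coding_coding"),
              ks_row("linc_coding", "random", "linc_coding_vs_random"))
  list(pairs = all_pairs, ks = ks)
}
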