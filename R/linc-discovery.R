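# lincRNA discovery: positional classification of candidate transcripts
# against a reference annotation, CuffMerge-style collapsing of per-sample
# assemblies, and the auditable filter cascade that produces the lincRNA
# catalogue.

#' Classify candidate transcripts against a reference annotation
#'
#' Assigns each candidate a positional class relative to the protein-coding
#' reference, mirroring the Cuffcompare class codes needed by an intergenic
#' lincRNA pipeline:
#' * `overlap` - any candidate exon shares at least 1 bp with any reference
#'   exon, on either strand (intergenic-ness is positional, so strand is
#'   ignored);
#' * `intronic` - the candidate span lies inside a reference gene span with
#'   no exon overlap;
#' * `near` - no overlap, but the gap to the nearest gene span is < 500 bp
#'   (or the spans overlap without exon overlap);
#' * `u` - intergenic: everything else, i.e. at least 500 bp from every
#'   reference gene span.
#'
#' @param candidates,reference `AnnotationSet`s on the same chromosome
#'   namespace.
#' @param near_distance Gap (bp) below which a non-overlapping candidate is
#'   `near` rather than `u`.
#' @return data.frame with one row per candidate transcript:
#'   `transcript_id`, `gene_id`, `class`, `distance` (bp gap to the nearest
#'   reference gene span; 0 when spans overlap; `Inf` with a warning when
#'   the candidate's chromosome is absent from the reference).
#' @export
classify_vs_reference <- function(candidates, reference, near_distance = 500) {
  stopifnot(inherits(candidates, "AnnotationSet"), inherits(reference, "AnnotationSet"))
  tx <- candidates$transcripts
  out <- data.frame(transcript_id = tx$transcript_id, gene_id = tx$gene_id,
                    class = rep("u", nrow(tx)), distance = rep(Inf, nrow(tx)),
                    stringsAsFactors = FALSE)
  if (!nrow(tx)) return(out)
  if (!nrow(reference$transcripts)) {
    warning("classify_vs_reference: empty reference; all candidates classed 'u'")
    return(out)
  }
  cand_ex <- exon_granges(candidates)
  ref_ex <- exon_granges(reference)
  gene_spans <- gene_span_granges(reference)
  cand_span <- GenomicRanges::GRanges(
    seqnames = tx$chrom,
    ranges = IRanges::IRanges(start = tx$start, end = tx$end),
    strand = "*"
  )

  # exon-level overlap, either strand
  hits <- GenomicRanges::findOverlaps(cand_ex, ref_ex, ignore.strand = TRUE)
  overlap_tx <- unique(cand_ex$transcript_id[S4Vectors::queryHits(hits)])

  # containment within a gene span (candidate fully inside)
  within_hits <- GenomicRanges::findOverlaps(cand_span, gene_spans,
                                             type = "within", ignore.strand = TRUE)
  within_tx <- tx$transcript_id[unique(S4Vectors::queryHits(within_hits))]

  # gap to the nearest gene span (0 when spans overlap)
  dtn <- GenomicRanges::distanceToNearest(cand_span, gene_spans, ignore.strand = TRUE)
  dist <- rep(Inf, nrow(tx))
  dist[S4Vectors::queryHits(dtn)] <- S4Vectors::mcols(dtn)$distance
  if (any(is.infinite(dist))) {
    warning("classify_vs_reference: candidate chromosome absent from reference; ",
            "classed 'u' with infinite distance")
  }
  out$distance <- dist

  is_overlap <- out$transcript_id %in% overlap_tx
  is_intronic <- !is_overlap & out$transcript_id %in% within_tx
  is_near <- !is_overlap & !is_intronic & dist < near_distance
  out$class[is_overlap] <- "overlap"
  out$class[is_intronic] <- "intronic"
  out$class[is_near] <- "near"
  out$distance[is_overlap] <- 0
  out
}

# union-find
.uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Merge per-sample transcript sets into a consensus annotation
#'
#' Collapses transcripts with identical intron chains (for mono-exon
#' transcripts, identical exon intervals) into one transcript whose terminal
#' exons extend to the outermost observed boundaries, then groups transcripts
#' sharing at least 1 bp of same-strand exonic overlap into one gene.
#' Gene and transcript ids are reassigned deterministically in
#' (chromosome, start, end) order.
#'
#' @param per_sample_sets A list of `AnnotationSet`s (or a single one).
#' @param gene_prefix,tx_prefix Prefixes for the reassigned ids.
#' @return A merged `AnnotationSet`.
#' @export
merge_transcripts <- function(per_sample_sets, gene_prefix = "XLOC",
                              tx_prefix = "TCONS") {
  if (inherits(per_sample_sets, "AnnotationSet")) {
    per_sample_sets <- list(per_sample_sets)
  }
  stopifnot(length(per_sample_sets) > 0,
            all(vapply(per_sample_sets, inherits, logical(1), "AnnotationSet")))
  ex_all <- do.call(rbind, lapply(seq_along(per_sample_sets), function(i) {
    e <- per_sample_sets[[i]]$exons
    if (nrow(e)) e$transcript_id <- paste0("s", i, "::", e$transcript_id)
    e
  }))
  if (is.null(ex_all) || !nrow(ex_all)) return(annotation_set(NULL))

  sp <- split(ex_all, ex_all$transcript_id)
  keys <- vapply(sp, function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) == 1L) {
      paste(d$chrom[1], d$strand[1], "mono", d$start[1], d$end[1], sep = "|")
    } else {
      introns <- paste(d$end[-nrow(d)] + 1L, d$start[-1] - 1L, sep = "-",
                       collapse = ",")
      paste(d$chrom[1], d$strand[1], introns, sep = "|")
    }
  }, character(1))

  merged <- lapply(split(names(sp), keys), function(members) {
    ds <- lapply(sp[members], function(d) d[order(d$start), , drop = FALSE])
    d0 <- ds[[1]]
    # extend terminal exons to the outermost observed boundaries
    d0$start[1] <- min(vapply(ds, function(d) d$start[1], integer(1)))
    d0$end[nrow(d0)] <- max(vapply(ds, function(d) d$end[nrow(d)], integer(1)))
    d0
  })
  n_tx <- length(merged)

  # same-strand exonic overlap groups transcripts into genes (union-find)
  tx_of_exon <- rep(seq_len(n_tx), vapply(merged, nrow, integer(1)))
  ex_df <- do.call(rbind, merged)
  gr <- GenomicRanges::GRanges(
    seqnames = ex_df$chrom,
    ranges = IRanges::IRanges(start = ex_df$start, end = ex_df$end),
    strand = ifelse(ex_df$strand == ".", "*", ex_df$strand)
  )
  parent <- seq_len(n_tx)
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = FALSE)
  qa <- tx_of_exon[S4Vectors::queryHits(hits)]
  sa <- tx_of_exon[S4Vectors::subjectHits(hits)]
  for (k in seq_along(qa)) {
    ra <- .uf_find(parent, qa[k])
    rb <- .uf_find(parent, sa[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n_tx), function(i) .uf_find(parent, i), integer(1))

  # deterministic id assignment: order transcripts, then number genes by
  # first transcript appearance
  spans <- data.frame(
    chrom = vapply(merged, function(d) d$chrom[1], character(1)),
    start = vapply(merged, function(d) min(d$start), integer(1)),
    end = vapply(merged, function(d) max(d$end), integer(1)),
    strand = vapply(merged, function(d) d$strand[1], character(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(spans$chrom, spans$start, spans$end, spans$strand)
  gene_no <- stats::setNames(rep(NA_integer_, n_tx), NULL)
  next_gene <- 0L
  tx_ids <- character(n_tx)
  gene_ids <- character(n_tx)
  for (pos in seq_along(ord)) {
    i <- ord[pos]
    r <- root[i]
    if (is.na(gene_no[r])) {
      next_gene <- next_gene + 1L
      gene_no[r] <- next_gene
    }
    tx_ids[i] <- sprintf("%s_%05d", tx_prefix, pos)
    gene_ids[i] <- sprintf("%s_%05d", gene_prefix, gene_no[r])
  }
  out_ex <- do.call(rbind, lapply(seq_len(n_tx), function(i) {
    d <- merged[[i]]
    d$transcript_id <- tx_ids[i]
    d$gene_id <- gene_ids[i]
    d
  }))
  annotation_set(out_ex)
}

#' Apply the lincRNA filter cascade
#'
#' Retains, in order, candidates that are (1) intergenic (class `u`),
#' (2) multi-exon, (3) reliably expressed (FPKM at least `min_fpkm` in at
#' least one sample under the default `fpkm_mode = "max"`, or in every
#' sample under `"all"`), (4) at least `min_distance` bp from the nearest
#' protein-coding gene span, (5) at least `min_length` bp of spliced length
#' and (6) consensus-noncoding under the three-scorer coding-potential
#' report. Every stage is recorded in an audit table.
#'
#' @param candidates `AnnotationSet` of candidate transcripts.
#' @param classification data.frame from [classify_vs_reference()].
#' @param expression Numeric FPKM matrix with candidate transcript ids as
#'   row names.
#' @param coding_report `CodingPotentialReport` covering the candidates.
#' @param min_fpkm,min_distance,min_length Survival thresholds (inclusive).
#' @param fpkm_mode `"max"` (default: maximum over samples) or `"all"`
#'   (every sample).
#' @return List with `lincrnas` (an `AnnotationSet`, biotype `"lincRNA"`)
#'   and `audit` (data.frame `stage`, `n_in`, `n_removed`, `n_out`; stages
#'   chain so that each `n_out` equals the next `n_in`).
#' @export
apply_filter_cascade <- function(candidates, classification, expression,
                                 coding_report,
                                 min_fpkm = 0.5, min_distance = 500,
                                 min_length = 200,
                                 fpkm_mode = c("max", "all")) {
  stopifnot(inherits(candidates, "AnnotationSet"))
  fpkm_mode <- match.arg(fpkm_mode)
  tx <- candidates$transcripts
  cls <- classification[match(tx$transcript_id, classification$transcript_id), ]
  if (any(is.na(cls$class))) {
    stop("apply_filter_cascade: classification missing for transcript ",
         tx$transcript_id[which(is.na(cls$class))[1]])
  }

  audit <- data.frame(stage = character(), n_in = integer(),
                      n_removed = integer(), n_out = integer(),
                      stringsAsFactors = FALSE)
  current <- tx$transcript_id
  step <- function(name, keep_ids) {
    removed <- setdiff(current, keep_ids)
    audit <<- rbind(audit, data.frame(
      stage = name, n_in = length(current), n_removed = length(removed),
      n_out = length(keep_ids), stringsAsFactors = FALSE))
    current <<- keep_ids
  }

  keep <- current[cls$class[match(current, tx$transcript_id)] == "u"]
  step("class_u", keep)

  keep <- current[tx$n_exons[match(current, tx$transcript_id)] >= 2L]
  step("multi_exon", keep)

  missing_expr <- setdiff(current, rownames(expression))
  if (length(missing_expr)) {
    stop("apply_filter_cascade: missing expression row for transcript ",
         missing_expr[1])
  }
  expr_ok <- if (fpkm_mode == "max") {
    apply(expression[current, , drop = FALSE], 1, max) >= min_fpkm
  } else {
    apply(expression[current, , drop = FALSE], 1, min) >= min_fpkm
  }
  step("expressed", current[expr_ok])

  keep <- current[cls$distance[match(current, cls$transcript_id)] >= min_distance]
  step("distance", keep)

  keep <- current[tx$spliced_length[match(current, tx$transcript_id)] >= min_length]
  step("length", keep)

  missing_rep <- setdiff(current, coding_report$transcript_id)
  if (length(missing_rep)) {
    stop("apply_filter_cascade: missing coding-potential report for transcript ",
         missing_rep[1])
  }
  nc <- coding_report$consensus_noncoding[match(current, coding_report$transcript_id)]
  step("noncoding_consensus", current[nc])

  list(lincrnas = subset_transcripts(candidates, current, biotype = "lincRNA"),
       audit = audit)
}

#' Genomic feature statistics of a transcript catalogue
#'
#' Summarises exon, transcript and length structure: mean number of distinct
#' exonic intervals per gene (union over the gene's transcripts), mean exons
#' per transcript, mean transcripts per gene, and mean spliced transcript
#' length, together with the underlying distributions.
#'
#' @param ann A non-empty `AnnotationSet`.
#' @return Object of class `linc_feature_stats` (a list).
#' @export
feature_stats <- function(ann) {
  stopifnot(inherits(ann, "AnnotationSet"))
  if (!nrow(ann$transcripts)) stop("feature_stats: empty annotation set")
  tx <- ann$transcripts
  ex <- ann$exons
  exon_key <- paste(ex$chrom, ex$start, ex$end)
  exons_per_gene <- vapply(split(exon_key, ex$gene_id),
                           function(k) length(unique(k)), integer(1))
  tx_per_gene <- vapply(split(tx$transcript_id, tx$gene_id), length, integer(1))
  out <- list(
    n_transcripts = nrow(tx),
    n_genes = length(tx_per_gene),
    mean_exons_per_gene = mean(exons_per_gene),
    mean_exons_per_transcript = mean(tx$n_exons),
    mean_transcripts_per_gene = mean(tx_per_gene),
    mean_transcript_length = mean(tx$spliced_length),
    exon_count_distribution = table(tx$n_exons),
    transcript_count_distribution = table(tx_per_gene),
    length_summary = summary(tx$spliced_length)
  )
  class(out) <- "linc_feature_stats"
  out
}

#' @export
print.linc_feature_stats <- function(x, ...) {
  cat(sprintf("Catalogue: %d transcripts in %d genes\n", x$n_transcripts, x$n_genes))
  cat(sprintf("  mean exons/gene (distinct intervals): %.2f\n", x$mean_exons_per_gene))
  cat(sprintf("  mean exons/transcript:                %.2f\n", x$mean_exons_per_transcript))
  cat(sprintf("  mean transcripts/gene:                %.2f\n", x$mean_transcripts_per_gene))
  cat(sprintf("  mean spliced transcript length:       %.1f bp\n", x$mean_transcript_length))
  invisible(x)
}

#' Audit a deposited lincRNA catalogue GTF
#'
#' Parses a catalogue GTF (plain text or a one-column table export, see
#' [read_gtf()]) and reports the transcript and gene counts together with
#' the [feature_stats()] summary, for comparison with a published catalogue.
#'
#' @param path Path to the GTF (or table-export) file.
#' @return List with `n_transcripts`, `n_genes` and `stats`.
#' @export
audit_lincrna_gtf <- function(path) {
  ann <- read_gtf(path)
  if (!nrow(ann$transcripts)) stop("audit_lincrna_gtf: no transcripts parsed from ", path)
  st <- feature_stats(ann)
  list(n_transcripts = st$n_transcripts, n_genes = st$n_genes, stats = st)
}

#' Audit a deposited hair-follicle expression table
#'
#' Counts the catalogue rows (one feature per row) of a delimited
#' feature-by-sample expression table with a header line.
#'
#' @param path Path to the table.
#' @param sep Field separator.
#' @return List with `n_features` and the parsed feature ids.
#' @export
audit_hf_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("audit_hf_table: file not found: ", path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  list(n_features = nrow(df), feature_ids = as.character(df[[1]]))
}

#' One-call lincRNA discovery
#'
#' Convenience wrapper: classifies candidates against the reference, scores
#' coding potential and applies the filter cascade.
#'
#' @param reference,candidates `AnnotationSet`s.
#' @param expression FPKM matrix with candidate transcript ids as row names.
#' @param seqs Named character vector of candidate transcript sequences.
#' @param hexamer_table A trained `HexamerTable`.
#' @param ... Passed on to [apply_filter_cascade()].
#' @return List with `lincrnas`, `audit`, `classification` and
#'   `coding_report`.
#' @export
discover_lincrnas <- function(reference, candidates, expression, seqs,
                              hexamer_table, ...) {
  classification <- classify_vs_reference(candidates, reference)
  report <- score_coding_potential(seqs[candidates$transcripts$transcript_id],
                                   hexamer_table)
  res <- apply_filter_cascade(candidates, classification, expression, report, ...)
  c(res, list(classification = classification, coding_report = report))
}
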