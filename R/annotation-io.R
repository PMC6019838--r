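#' Transcript model collections
#'
#' An `AnnotationSet` holds a collection of transcript models: for every
#' transcript its chromosome, strand, ordered exon intervals (1-based,
#' inclusive, the GTF convention), its gene, and a biotype tag
#' (`"coding"`, `"linc_candidate"`, `"lincRNA"` or `"other"`).
#'
#' Internally the object stores two data frames: `exons` (one row per exon)
#' and `transcripts` (one row per transcript with its span, exon count and
#' spliced length). Transcripts are kept in a canonical order
#' (chromosome, span start, transcript id) so that serialisation is
#' deterministic.
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end` and optionally `biotype`. Several rows with the
#'   same `transcript_id` form one multi-exon transcript; they must agree on
#'   chromosome, strand, gene and biotype, and their intervals must not
#'   overlap.
#' @return An object of class `AnnotationSet`.
#' @export
annotation_set <- function(exons) {
  required <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  if (missing(exons) || is.null(exons)) {
    exons <- data.frame(transcript_id = character(), gene_id = character(),
                        chrom = character(), strand = character(),
                        start = integer(), end = integer(),
                        biotype = character())
  }
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols)) {
    stop("annotation_set: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"biotype" %in% names(exons)) exons$biotype <- rep("other", nrow(exons))
  exons <- data.frame(
    transcript_id = as.character(exons$transcript_id),
    gene_id       = as.character(exons$gene_id),
    chrom         = as.character(exons$chrom),
    strand        = as.character(exons$strand),
    start         = as.integer(exons$start),
    end           = as.integer(exons$end),
    biotype       = as.character(exons$biotype),
    stringsAsFactors = FALSE
  )
  if (nrow(exons)) {
    if (any(!exons$strand %in% c("+", "-", "."))) {
      stop("annotation_set: strand must be one of '+', '-', '.'")
    }
    if (any(is.na(exons$start)) || any(is.na(exons$end))) {
      stop("annotation_set: non-numeric exon coordinates")
    }
    if (any(exons$end < exons$start)) stop("annotation_set: exon end < start")
    if (any(exons$start < 1L)) stop("annotation_set: coordinates are 1-based; start must be >= 1")
    # per-transcript consistency and non-overlap
    exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
    sp <- split(seq_len(nrow(exons)), exons$transcript_id)
    for (idx in sp) {
      for (col in c("gene_id", "chrom", "strand", "biotype")) {
        if (length(unique(exons[[col]][idx])) != 1L) {
          stop("annotation_set: transcript '", exons$transcript_id[idx[1]],
               "' has inconsistent ", col)
        }
      }
      if (length(idx) > 1L) {
        s <- exons$start[idx]; e <- exons$end[idx]
        if (any(s[-1] <= e[-length(e)])) {
          stop("annotation_set: overlapping exons in transcript '",
               exons$transcript_id[idx[1]], "'")
        }
      }
    }
  }
  tx <- if (nrow(exons)) {
    agg <- lapply(split(exons, exons$transcript_id), function(d) {
      data.frame(transcript_id = d$transcript_id[1], gene_id = d$gene_id[1],
                 chrom = d$chrom[1], strand = d$strand[1],
                 biotype = d$biotype[1],
                 start = min(d$start), end = max(d$end),
                 n_exons = nrow(d),
                 spliced_length = sum(d$end - d$start + 1L),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, agg)
  } else {
    data.frame(transcript_id = character(), gene_id = character(),
               chrom = character(), strand = character(), biotype = character(),
               start = integer(), end = integer(), n_exons = integer(),
               spliced_length = integer(), stringsAsFactors = FALSE)
  }
  ord <- order(tx$chrom, tx$start, tx$transcript_id)
  tx <- tx[ord, , drop = FALSE]
  rownames(tx) <- NULL
  # exon rows follow transcript canonical order
  exons <- exons[order(match(exons$transcript_id, tx$transcript_id), exons$start), ,
                 drop = FALSE]
  rownames(exons) <- NULL
  structure(list(exons = exons, transcripts = tx), class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat("AnnotationSet:", nrow(x$transcripts), "transcripts,",
      length(unique(x$transcripts$gene_id)), "genes,",
      nrow(x$exons), "exons\n")
  if (nrow(x$transcripts)) {
    bt <- table(x$transcripts$biotype)
    cat("  biotypes:", paste(sprintf("%s=%d", names(bt), bt), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.AnnotationSet <- function(x) nrow(x$transcripts)

#' Spliced transcript lengths
#'
#' @param ann An `AnnotationSet`.
#' @return Named integer vector of spliced lengths (sum of exon widths) per
#'   transcript.
#' @export
spliced_lengths <- function(ann) {
  stopifnot(inherits(ann, "AnnotationSet"))
  stats::setNames(ann$transcripts$spliced_length, ann$transcripts$transcript_id)
}

#' Map gene ids to their member transcript ids
#' @param ann An `AnnotationSet`.
#' @return Named list, one character vector of transcript ids per gene.
#' @export
gene_index <- function(ann) {
  stopifnot(inherits(ann, "AnnotationSet"))
  split(ann$transcripts$transcript_id, ann$transcripts$gene_id)
}

#' Restrict an AnnotationSet to a subset of transcripts
#' @param ann An `AnnotationSet`.
#' @param transcript_ids Character vector of transcript ids to keep.
#' @param biotype Optional biotype to assign to the kept transcripts.
#' @export
subset_transcripts <- function(ann, transcript_ids, biotype = NULL) {
  stopifnot(inherits(ann, "AnnotationSet"))
  ex <- ann$exons[ann$exons$transcript_id %in% transcript_ids, , drop = FALSE]
  if (!is.null(biotype)) ex$biotype <- rep(biotype, nrow(ex))
  annotation_set(ex)
}

# GRanges views of the annotation (internal): exon-level ranges and
# per-gene span ranges. All geometry downstream goes through IRanges.
exon_granges <- function(ann) {
  GenomicRanges::GRanges(
    seqnames = ann$exons$chrom,
    ranges = IRanges::IRanges(start = ann$exons$start, end = ann$exons$end),
    strand = ifelse(ann$exons$strand == ".", "*", ann$exons$strand),
    transcript_id = ann$exons$transcript_id,
    gene_id = ann$exons$gene_id
  )
}

gene_span_granges <- function(ann) {
  tx <- ann$transcripts
  if (!nrow(tx)) {
    return(GenomicRanges::GRanges(gene_id = character()))
  }
  sp <- split(seq_len(nrow(tx)), tx$gene_id)
  gid <- names(sp)
  chrom <- vapply(sp, function(i) tx$chrom[i[1]], character(1))
  strand <- vapply(sp, function(i) tx$strand[i[1]], character(1))
  gstart <- vapply(sp, function(i) min(tx$start[i]), integer(1))
  gend <- vapply(sp, function(i) max(tx$end[i]), integer(1))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = gstart, end = gend),
    strand = ifelse(strand == ".", "*", strand),
    gene_id = gid
  )
  gr[order(as.character(GenomicRanges::seqnames(gr)), GenomicRanges::start(gr),
           gr$gene_id)]
}

gtf_attr <- function(attr, key) {
  m <- regmatches(attr, regexec(paste0(key, '\\s+"([^"]*)"'), attr))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, character(1))
}

#' Read transcript models from a GTF file
#'
#' Parses the tab-separated nine-column GTF format; only `exon` feature rows
#' contribute geometry, other feature rows (`transcript`, `CDS`, ...) are
#' ignored. Coordinates are kept 1-based inclusive. The reader also accepts
#' "table export" files in which each GTF row was flattened into a single
#' whitespace-separated column (as produced by exporting a spreadsheet-wrapped
#' GTF), provided the nine fields are still recognisable.
#'
#' @param path Path to a GTF file.
#' @return An [annotation_set()].
#' @details A malformed line (wrong column count, non-numeric coordinates) or
#'   a missing `transcript_id` attribute raises an error naming the offending
#'   line number. A missing `gene_id` falls back to the transcript id.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("read_gtf: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  rows <- vector("list", length(keep))
  n <- 0L
  for (ln in keep) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) == 1L) {
      # single-column table export: fall back to whitespace splitting,
      # re-joining everything after field 8 as the attribute column
      toks <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (length(toks) < 9L) {
        stop("read_gtf: malformed line ", ln, " (", length(toks), " columns)")
      }
      fields <- c(toks[1:8], paste(toks[-(1:8)], collapse = " "))
    } else if (length(fields) < 9L) {
      stop("read_gtf: malformed line ", ln, " (", length(fields), " columns)")
    } else if (length(fields) > 9L) {
      fields <- c(fields[1:8], paste(fields[-(1:8)], collapse = "\t"))
    }
    if (tolower(fields[3]) != "exon") next
    start <- suppressWarnings(as.integer(fields[4]))
    end <- suppressWarnings(as.integer(fields[5]))
    if (is.na(start) || is.na(end)) {
      stop("read_gtf: non-numeric coordinates at line ", ln)
    }
    tid <- gtf_attr(fields[9], "transcript_id")
    if (is.na(tid) || !nzchar(tid)) {
      stop("read_gtf: missing transcript_id at line ", ln)
    }
    gid <- gtf_attr(fields[9], "gene_id")
    if (is.na(gid) || !nzchar(gid)) gid <- tid
    bt <- gtf_attr(fields[9], "biotype")
    if (is.na(bt) || !nzchar(bt)) bt <- "other"
    strand <- fields[7]
    if (!strand %in% c("+", "-")) strand <- "."
    n <- n + 1L
    rows[[n]] <- data.frame(transcript_id = tid, gene_id = gid,
                            chrom = fields[1], strand = strand,
                            start = start, end = end, biotype = bt,
                            stringsAsFactors = FALSE)
  }
  if (n == 0L) return(annotation_set(NULL))
  annotation_set(do.call(rbind, rows[seq_len(n)]))
}

#' Write an AnnotationSet as GTF
#'
#' Emits one `exon` row per exon with `gene_id`, `transcript_id` and
#' `biotype` attributes, ordered deterministically by (chromosome, transcript
#' span start, transcript id); two runs on the same input produce
#' byte-identical files.
#'
#' @param ann An `AnnotationSet`.
#' @param path Output file path.
#' @export
write_gtf <- function(ann, path) {
  stopifnot(inherits(ann, "AnnotationSet"))
  ex <- ann$exons  # already canonically ordered by the constructor
  lines <- sprintf(
    '%s\tlincscan\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; biotype "%s";',
    ex$chrom, ex$start, ex$end, ex$strand, ex$gene_id, ex$transcript_id, ex$biotype
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n")
  invisible(NULL)
}

#' Read a FASTA file as a named character vector
#'
#' Sequences are uppercased; record ids are the first whitespace-delimited
#' token of each header. Characters outside `A`, `C`, `G`, `T`, `N` raise a
#' warning but are retained; duplicate ids are an error.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("read_fasta: duplicate sequence id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- toupper(as.character(seqs))
  names(out) <- ids
  if (any(grepl("[^ACGTN]", out))) {
    warning("read_fasta: characters outside {A,C,G,T,N} present; retained")
  }
  out
}

#' Write sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (id in names(seqs)) {
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", id), substring(s, starts, pmin(starts + width - 1L, nchar(s)))),
               con = con, sep = "\n")
  }
  invisible(NULL)
}

#' Read BLAST tabular output (outfmt 6/7)
#'
#' Reads the 12 standard columns; `#` comment lines (outfmt 7 headers) are
#' skipped.
#'
#' @param path Path to a BLAST tabular file.
#' @return data.frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `bit_score`.
#' @export
read_blast_tabular <- function(path) {
  if (!file.exists(path)) stop("read_blast_tabular: file not found: ", path)
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
            "evalue", "bit_score")
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = cols, fill = FALSE)
  df
}

#' Filter BLAST hits by identity, mismatches, gap opens and length
#'
#' Keeps a hit only if it clears all four bounds, applied as strict
#' inequalities: fewer than `max_mismatches` mismatches, identity greater
#' than `min_identity`, fewer than `max_gap_opens` gap opens, and length
#' greater than `min_length`. By default the length bound applies to the
#' alignment length; set `length_on = "transcript"` (and supply
#' `transcript_lengths`) to bound the query transcript length instead.
#'
#' @param hits data.frame as returned by [read_blast_tabular()].
#' @param max_mismatches,min_identity,max_gap_opens,min_length Filter bounds.
#' @param length_on `"alignment"` or `"transcript"`.
#' @param transcript_lengths Named vector of query transcript lengths,
#'   required when `length_on = "transcript"`.
#' @return The subset of `hits` passing all bounds. Idempotent: applying the
#'   filter twice equals applying it once.
#' @export
filter_blast_hits <- function(hits, max_mismatches = 3, min_identity = 98,
                              max_gap_opens = 6, min_length = 200,
                              length_on = c("alignment", "transcript"),
                              transcript_lengths = NULL) {
  length_on <- match.arg(length_on)
  if (!nrow(hits)) return(hits)
  len <- if (length_on == "alignment") {
    hits$alignment_length
  } else {
    if (is.null(transcript_lengths)) {
      stop("filter_blast_hits: transcript_lengths required when length_on = 'transcript'")
    }
    unname(transcript_lengths[hits$query_id])
  }
  keep <- hits$mismatches < max_mismatches &
    hits$percent_identity > min_identity &
    hits$gap_opens < max_gap_opens &
    !is.na(len) & len > min_length
  hits[keep, , drop = FALSE]
}
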