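# Coding-potential scoring: three independent desk-scale scorers (longest
# ORF, Fickett TESTCODE, hexamer log-likelihood ratio) combined by an
# intersection-consensus rule. A transcript is kept as noncoding only when
# all three scorers agree it is noncoding.

# Fickett (1982) TESTCODE lookup tables. Position parameter: for each base,
# counts in the three frame phases, max/(min+1). Content parameter: base
# fraction. Each parameter value is converted through the published interval
# tables below and the weighted probabilities are summed. Scores above 0.95
# are the published "coding" call.
.fickett_position_prob <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
)
.fickett_position_weight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
.fickett_position_cuts <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
.fickett_content_prob <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
)
.fickett_content_weight <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
.fickett_content_cuts <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0)

.seq_chars <- function(sequence) {
  strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
}

#' Longest open reading frame in the three forward frames
#'
#' Scans the three forward frames of a (stranded) transcript sequence for
#' complete ORFs: an `ATG` followed by an in-frame stop (`TAA`, `TAG`,
#' `TGA`), stop included. Returns the longest; ties are broken by the
#' smallest start position.
#'
#' @param sequence Nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @return Named numeric vector `c(start, length)` in nucleotides (1-based
#'   start), or `c(0, 0)` when no complete ORF exists or the sequence is
#'   shorter than 6 nt.
#' @export
longest_orf <- function(sequence) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 6L) return(c(start = 0, length = 0))
  best_start <- 0L
  best_len <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    codon_starts <- seq(1L + frame, n - 2L, by = 3L)
    if (!length(codon_starts)) next
    codons <- substring(sequence, codon_starts, codon_starts + 2L)
    open_at <- NA_integer_  # position of earliest unclosed ATG
    for (i in seq_along(codons)) {
      if (is.na(open_at) && codons[i] == "ATG") open_at <- codon_starts[i]
      if (!is.na(open_at) && codons[i] %in% stops) {
        len <- codon_starts[i] + 2L - open_at + 1L
        if (len > best_len || (len == best_len && open_at < best_start)) {
          best_len <- len
          best_start <- open_at
        }
        open_at <- NA_integer_
      }
    }
  }
  c(start = best_start, length = best_len)
}

.fickett_lookup <- function(value, cuts, probs) {
  probs[which(value >= cuts)[1]]
}

#' Fickett TESTCODE coding-potential statistic
#'
#' Computes the classic TESTCODE statistic: for each base, a position
#' parameter (maximum over the three frame-phase counts divided by the
#' minimum plus one) and a composition parameter (base fraction), each
#' converted through the published lookup tables and combined with the
#' published weights. Higher values are more coding-like; the published
#' coding call is a score of at least 0.95.
#'
#' @param sequence Nucleotide string, at least 50 nt (the statistic is
#'   undefined at tiny lengths).
#' @return Numeric TESTCODE score.
#' @export
fickett_score <- function(sequence) {
  chars <- .seq_chars(sequence)
  n <- length(chars)
  if (n < 50L) stop("fickett_score: sequence shorter than 50 nt")
  score <- 0
  phase <- rep_len(1:3, n)
  for (base in c("A", "C", "G", "T")) {
    counts <- vapply(1:3, function(p) sum(chars == base & phase == p), numeric(1))
    pos_param <- max(counts) / (min(counts) + 1)
    comp_param <- sum(counts) / n
    score <- score +
      .fickett_lookup(pos_param, .fickett_position_cuts, .fickett_position_prob[[base]]) *
        .fickett_position_weight[[base]] +
      .fickett_lookup(comp_param, .fickett_content_cuts, .fickett_content_prob[[base]]) *
        .fickett_content_weight[[base]]
  }
  unname(score)
}

.count_hexamers <- function(sequences) {
  counts <- integer(0)
  all_hex <- character(0)
  acc <- new.env(parent = emptyenv())
  for (s in sequences) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < 6L) next
    wins <- substring(s, 1:(n - 5L), 6:n)
    wins <- wins[!grepl("N", wins, fixed = TRUE)]
    if (!length(wins)) next
    tab <- table(wins)
    for (h in names(tab)) {
      prev <- if (is.null(acc[[h]])) 0L else acc[[h]]
      acc[[h]] <- prev + as.integer(tab[[h]])
    }
  }
  as.list(acc)
}

.all_hexamers <- function() {
  bases <- c("A", "C", "G", "T")
  g <- expand.grid(bases, bases, bases, bases, bases, bases,
                   stringsAsFactors = FALSE)
  sort(apply(g, 1, paste0, collapse = ""))
}

#' Train coding/noncoding hexamer frequency tables
#'
#' Counts all overlapping hexamers (step 1; windows containing `N` are
#' skipped) in each training set, adds a pseudocount to every one of the
#' 4096 hexamers and normalises each table to sum to 1.
#'
#' @param coding_seqs,noncoding_seqs Non-empty character vectors of training
#'   sequences, each at least 6 nt.
#' @param pseudocount Pseudocount added to every hexamer before
#'   normalisation.
#' @return Object of class `HexamerTable`: list with named numeric vectors
#'   `coding` and `noncoding` over all 4096 hexamers, plus the pseudocount.
#' @export
train_hexamer_table <- function(coding_seqs, noncoding_seqs, pseudocount = 1.0) {
  if (!length(coding_seqs) || !length(noncoding_seqs)) {
    stop("train_hexamer_table: both training sets must be non-empty")
  }
  if (any(nchar(coding_seqs) < 6L) || any(nchar(noncoding_seqs) < 6L)) {
    stop("train_hexamer_table: all training sequences must be >= 6 nt")
  }
  hex <- .all_hexamers()
  make_table <- function(seqs) {
    counts <- stats::setNames(rep(pseudocount, length(hex)), hex)
    obs <- .count_hexamers(seqs)
    for (h in names(obs)) counts[[h]] <- counts[[h]] + obs[[h]]
    counts / sum(counts)
  }
  structure(list(coding = make_table(coding_seqs),
                 noncoding = make_table(noncoding_seqs),
                 pseudocount = pseudocount),
            class = "HexamerTable")
}

#' Hexamer log-likelihood ratio of a sequence
#'
#' Mean over all overlapping hexamer windows (step 1, `N`-containing windows
#' skipped) of `log2(coding_freq / noncoding_freq)` under a trained
#' [train_hexamer_table()]. Positive values are coding-like.
#'
#' @param sequence Nucleotide string of at least 6 nt.
#' @param table A `HexamerTable`.
#' @return Numeric mean log2 ratio.
#' @export
hexamer_llr <- function(sequence, table) {
  stopifnot(inherits(table, "HexamerTable"))
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < 6L) stop("hexamer_llr: sequence shorter than 6 nt")
  wins <- substring(s, 1:(n - 5L), 6:n)
  wins <- wins[!grepl("N", wins, fixed = TRUE)]
  if (!length(wins)) stop("hexamer_llr: no valid hexamer window")
  mean(log2(table$coding[wins] / table$noncoding[wins]))
}

#' Three-scorer consensus coding-potential call
#'
#' Applies the three scorer thresholds and the intersection-consensus rule:
#' scorer A calls coding when the ORF is long (`orf_length >= min_orf_length`)
#' or covers most of the transcript (`orf_coverage >= min_orf_coverage`);
#' scorer B calls coding when the Fickett score reaches the published
#' TESTCODE coding cut; scorer C calls coding when the hexamer LLR is
#' positive. Under the default `rule = "all_noncoding"` a transcript is
#' consensus-noncoding only when all three scorers label it noncoding
#' (the intersection of the three noncoding sets). The alternative
#' `rule = "not_all_coding"` discards only transcripts called coding by all
#' three scorers.
#'
#' @param orf_length ORF length in nt.
#' @param orf_coverage ORF length divided by transcript length.
#' @param fickett Fickett TESTCODE score.
#' @param llr Hexamer log-likelihood ratio.
#' @param min_orf_length,min_orf_coverage,fickett_cut,llr_cut Scorer
#'   thresholds.
#' @param rule Consensus rule, see Details.
#' @return List with the three per-scorer labels (`"coding"`/`"noncoding"`)
#'   and the logical `consensus_noncoding`.
#' @export
consensus_call <- function(orf_length, orf_coverage, fickett, llr,
                           min_orf_length = 300, min_orf_coverage = 0.5,
                           fickett_cut = 0.95, llr_cut = 0,
                           rule = c("all_noncoding", "not_all_coding")) {
  rule <- match.arg(rule)
  lab <- function(x) ifelse(x, "coding", "noncoding")
  a <- lab(orf_length >= min_orf_length | orf_coverage >= min_orf_coverage)
  b <- lab(fickett >= fickett_cut)
  c_ <- lab(llr > llr_cut)
  consensus <- if (rule == "all_noncoding") {
    a == "noncoding" & b == "noncoding" & c_ == "noncoding"
  } else {
    !(a == "coding" & b == "coding" & c_ == "coding")
  }
  list(orf_label = a, fickett_label = b, hexamer_label = c_,
       consensus_noncoding = consensus)
}

#' Score coding potential for a set of transcript sequences
#'
#' Runs [longest_orf()], [fickett_score()] and [hexamer_llr()] on every
#' sequence and applies [consensus_call()].
#'
#' @param seqs Named character vector of transcript sequences.
#' @param table A trained `HexamerTable`.
#' @param ... Thresholds passed to [consensus_call()].
#' @return A `CodingPotentialReport` data.frame with one row per transcript:
#'   `transcript_id`, `orf_start`, `orf_length`, `orf_coverage`,
#'   `fickett_score`, `hexamer_llr`, the three per-scorer labels and
#'   `consensus_noncoding`.
#' @export
score_coding_potential <- function(seqs, table, ...) {
  stopifnot(length(seqs) > 0, !is.null(names(seqs)))
  rows <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    orf <- longest_orf(s)
    cov <- if (nchar(s) > 0) unname(orf["length"]) / nchar(s) else 0
    fs <- fickett_score(s)
    llr <- hexamer_llr(s, table)
    call <- consensus_call(unname(orf["length"]), cov, fs, llr, ...)
    data.frame(transcript_id = id,
               orf_start = unname(orf["start"]),
               orf_length = unname(orf["length"]),
               orf_coverage = cov,
               fickett_score = fs,
               hexamer_llr = llr,
               orf_label = call$orf_label,
               fickett_label = call$fickett_label,
               hexamer_label = call$hexamer_label,
               consensus_noncoding = call$consensus_noncoding,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("CodingPotentialReport", class(out))
  out
}
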