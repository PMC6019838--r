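# Small programmatic fixtures shared across test files.

# quick exon-table builder: ex("t1", "g1", "chr1", "+", 100, 200, 300, 400)
ex_rows <- function(tid, gid, chrom, strand, ...) {
  coords <- c(...)
  stopifnot(length(coords) %% 2 == 0)
  starts <- coords[seq(1, length(coords), by = 2)]
  ends <- coords[seq(2, length(coords), by = 2)]
  data.frame(transcript_id = tid, gene_id = gid, chrom = chrom,
             strand = strand, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

# random valid AnnotationSet with n transcripts (non-overlapping exons)
random_annotation <- function(n, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    n_ex <- sample(1:4, 1)
    start <- sample(1:100000, 1)
    widths <- sample(50:300, n_ex, replace = TRUE)
    gaps <- sample(30:500, n_ex, replace = TRUE)
    starts <- start + cumsum(c(0, (widths + gaps)[-n_ex]))
    ex_rows(sprintf("t%03d", i), sprintf("g%03d", i),
            sample(c("chr1", "chr2"), 1), sample(c("+", "-"), 1),
            rbind(starts, starts + widths - 1))
  })
  annotation_set(do.call(rbind, rows))
}

# small noise-free study shared by several test files (computed once)
tiny_config <- function(seed = 11, noise_sd = 0, ...) {
  sim_config(seed = seed, noise_sd = noise_sd, ...)
}

study_cache <- new.env(parent = emptyenv())
noise_free_study <- function() {
  if (is.null(study_cache$sim)) {
    study_cache$sim <- simulate_study(tiny_config())
  }
  study_cache$sim
}
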