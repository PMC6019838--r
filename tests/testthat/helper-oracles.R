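# Independent brute-force oracles used to cross-check the implementation.
# Each is written as a direct transliteration of the defining formula, with
# its own literal constants, so it shares no code path with the package.

# Fickett TESTCODE by explicit per-phase counting and if-else table walks.
oracle_fickett <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  pos_prob <- list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
  pos_w <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
  con_prob <- list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
  con_w <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  pos_cuts <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1)
  con_cuts <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17)
  slot <- function(value, cuts) {
    for (i in seq_along(cuts)) if (value >= cuts[i]) return(i)
    length(cuts) + 1L
  }
  total <- 0
  for (b in c("A", "C", "G", "T")) {
    counts <- numeric(3)
    for (p in 1:3) {
      hits <- 0L
      for (i in seq(p, n, by = 3)) if (substr(s, i, i) == b) hits <- hits + 1L
      counts[p] <- hits
    }
    posv <- max(counts) / (min(counts) + 1)
    conv <- sum(counts) / n
    total <- total + pos_prob[[b]][slot(posv, pos_cuts)] * pos_w[[b]] +
      con_prob[[b]][slot(conv, con_cuts)] * con_w[[b]]
  }
  total
}

# hexamer mean log2 ratio by explicit window enumeration
oracle_hexamer_llr <- function(s, tab) {
  s <- toupper(s)
  total <- 0
  k <- 0L
  for (i in 1:(nchar(s) - 5L)) {
    w <- substr(s, i, i + 5L)
    if (grepl("N", w, fixed = TRUE)) next
    total <- total + log2(tab$coding[[w]] / tab$noncoding[[w]])
    k <- k + 1L
  }
  total / k
}

# two-sample KS statistic by empirical-CDF sweep over all observed values
oracle_ks <- function(x, y) {
  vals <- sort(unique(c(x, y)))
  d <- 0
  for (v in vals) {
    d <- max(d, abs(mean(x <= v) - mean(y <= v)))
  }
  d
}

# Benjamini-Hochberg step-up by the defining min-over-larger-ranks form
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (pos in seq_len(n)) {
    i <- o[pos]
    q[i] <- min(vapply(pos:n, function(j) min(p[o[j]] * n / j, 1), numeric(1)))
  }
  q
}

# upper hypergeometric tail by direct enumeration
oracle_hyper <- function(overlap, set_size, universe_size, cluster_size) {
  xs <- overlap:min(set_size, cluster_size)
  sum(vapply(xs, function(x) {
    choose(set_size, x) * choose(universe_size - set_size, cluster_size - x) /
      choose(universe_size, cluster_size)
  }, numeric(1)))
}

# textbook Pearson correlation closed form
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# brute-force base counting of spliced length over exon intervals
oracle_spliced_length <- function(starts, ends) {
  total <- 0L
  for (k in seq_along(starts)) {
    total <- total + length(seq(starts[k], ends[k]))
  }
  total
}
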