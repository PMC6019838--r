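# Synthetic study generator: toy genome annotation with coding genes and
# candidate transcripts of controlled class, transcript sequences from two
# hexamer regimes, FPKM matrices across a tissue panel and a five-time-point
# skin course with planted tissue-specific, HF-high, differentially
# expressed, cluster-patterned and neighbour-correlated features, and Ct
# tables consistent with the planted expression. Every planted label is
# returned as ground truth so the whole pipeline can be verified end to end.

.default_tissues <- c("lymph", "lung", "spleen", "kidney", "liver", "muscle",
                      "heart", "brain", "bladder", "ovary", "HF")

#' Simulation configuration
#'
#' Bundles and validates all knobs of the synthetic study. The defaults
#' emulate the study design the pipeline targets: a ten-tissue panel plus
#' hair follicle, five time points (May, Jun, Aug, Sep, Oct) with three
#' replicates each, a candidate-class mix dominated by intergenic
#' transcripts, cross-block differential expression with a log2 fold change
#' of 2, five co-expression templates, and log-normal expression noise on
#' the log2(FPKM+1) scale.
#'
#' @param seed Integer master seed; all generator randomness derives from it.
#' @param n_coding_genes Number of reference protein-coding genes.
#' @param n_candidates Number of candidate transcripts.
#' @param genome data.frame with columns `chrom`, `length`.
#' @param class_mix Named proportions over the candidate classes
#'   `intergenic_far` (>= 500 bp from coding genes), `intergenic_near`
#'   (< 500 bp), `exon_overlap`, `intronic`, `single_exon`, `short`
#'   (< 200 bp); must sum to 1.
#' @param prop_coding_like,prop_low_expr Fractions of the `intergenic_far`
#'   candidates planted with a coding-like sequence (long ORF, coding-regime
#'   hexamers) or with sub-threshold expression.
#' @param tissues Tissue panel (must include `"HF"` for the HF analyses).
#' @param time_points Time-course design.
#' @param n_replicates Replicates per time point.
#' @param n_tissue_specific,n_hf_high,n_de,n_de_coding Planted feature
#'   counts (lincRNA tissue-specific, HF-high, DE lincRNAs, DE coding
#'   genes).
#' @param de_log2fc True cross-block log2 fold change of the block
#'   templates.
#' @param n_clusters Number of co-expression templates (fixed at 5 shapes).
#' @param n_corr_pairs Planted lincRNA/coding neighbour pairs (within 10 kb)
#'   with target tissue-profile correlation `target_r`.
#' @param n_cc_pairs Proximal coding-coding gene pairs (comparison class).
#' @param target_r Target Pearson correlation of planted neighbour pairs
#'   (achieved exactly in the noise-free case).
#' @param n_spatiotemporal Number of planted pair lincRNAs that are
#'   additionally HF-high and up-regulated (template 1), with a time-course
#'   neighbour correlation of `spatiotemporal_r`.
#' @param spatiotemporal_r Planted time-profile correlation of the
#'   spatiotemporal neighbour pairs.
#' @param noise_sd SD of Gaussian noise added on log2(FPKM+1).
#' @param baseline_log2_mean,baseline_log2_sd Log2-scale location/spread of
#'   the log-normal baseline FPKM.
#' @return Validated list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L,
                       n_coding_genes = 60L,
                       n_candidates = 160L,
                       genome = data.frame(chrom = c("chr1", "chr2", "chr3"),
                                           length = rep(1.2e6, 3)),
                       class_mix = c(intergenic_far = 0.55,
                                     intergenic_near = 0.09,
                                     exon_overlap = 0.09,
                                     intronic = 0.09,
                                     single_exon = 0.09,
                                     short = 0.09),
                       prop_coding_like = 0.15,
                       prop_low_expr = 0.10,
                       tissues = .default_tissues,
                       time_points = linc_time_points(),
                       n_replicates = 3L,
                       n_tissue_specific = 15L,
                       n_hf_high = 8L,
                       n_de = 23L,
                       n_de_coding = 40L,
                       de_log2fc = 2,
                       n_clusters = 5L,
                       n_corr_pairs = 12L,
                       n_cc_pairs = 12L,
                       target_r = 0.9,
                       n_spatiotemporal = 2L,
                       spatiotemporal_r = 0.95,
                       noise_sd = 0.2,
                       baseline_log2_mean = log2(15),
                       baseline_log2_sd = 0.8) {
  cfg <- list(seed = as.integer(seed), n_coding_genes = as.integer(n_coding_genes),
              n_candidates = as.integer(n_candidates), genome = genome,
              class_mix = class_mix, prop_coding_like = prop_coding_like,
              prop_low_expr = prop_low_expr, tissues = tissues,
              time_points = time_points, n_replicates = as.integer(n_replicates),
              n_tissue_specific = as.integer(n_tissue_specific),
              n_hf_high = as.integer(n_hf_high), n_de = as.integer(n_de),
              n_de_coding = as.integer(n_de_coding), de_log2fc = de_log2fc,
              n_clusters = as.integer(n_clusters),
              n_corr_pairs = as.integer(n_corr_pairs),
              n_cc_pairs = as.integer(n_cc_pairs), target_r = target_r,
              n_spatiotemporal = as.integer(n_spatiotemporal),
              spatiotemporal_r = spatiotemporal_r, noise_sd = noise_sd,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd)
  classes <- c("intergenic_far", "intergenic_near", "exon_overlap", "intronic",
               "single_exon", "short")
  if (!setequal(names(cfg$class_mix), classes)) {
    stop("sim_config: class_mix must name exactly: ", paste(classes, collapse = ", "))
  }
  if (abs(sum(cfg$class_mix) - 1) > 1e-8) stop("sim_config: class_mix must sum to 1")
  counts <- c(cfg$n_coding_genes, cfg$n_candidates, cfg$n_replicates,
              cfg$n_tissue_specific, cfg$n_hf_high, cfg$n_de, cfg$n_de_coding,
              cfg$n_corr_pairs, cfg$n_cc_pairs, cfg$n_spatiotemporal)
  if (any(counts < 0)) stop("sim_config: counts must be >= 0")
  if (cfg$noise_sd < 0) stop("sim_config: noise_sd must be >= 0")
  if (cfg$n_spatiotemporal > min(cfg$n_corr_pairs, cfg$n_de, cfg$n_hf_high)) {
    stop("sim_config: n_spatiotemporal cannot exceed n_corr_pairs, n_de or n_hf_high")
  }
  if (cfg$n_clusters != 5L) {
    stop("sim_config: the generator plants exactly 5 template shapes")
  }
  class(cfg) <- "SimConfig"
  cfg
}

# largest-remainder integer allocation of n into proportions p
.alloc_counts <- function(n, p) {
  raw <- n * p / sum(p)
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

# cluster template profiles over the five time points (FPKM scale):
# 1 block-up, 2 block-down, 3 peak-Aug, 4 peak-Oct, 5 peak-May. Templates
# 1-2 are significant only across the May-Jun / Aug-Oct block boundary.
.cluster_templates <- function(time_points, de_log2fc = 2) {
  low <- 5
  high <- low * 2^de_log2fc
  peak <- low * 2^(de_log2fc + 1)
  m <- rbind(c(low, low, high, high, high),
             c(high, high, low, low, low),
             c(low, low, peak, low, low),
             c(low, low, low, low, peak),
             c(peak, low, low, low, low))
  dimnames(m) <- list(paste0("template", 1:5), time_points)
  m
}

# template allocation proportions (descending, so relabel-by-size is stable)
.template_props <- c(0.35, 0.25, 0.16, 0.14, 0.10)

.random_seq <- function(n, probs = c(A = 0.34, C = 0.16, G = 0.16, T = 0.34)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# GC-rich non-stop codons used for the coding regime
.coding_codons <- c("GCC", "GCT", "GGC", "GGA", "CTG", "CTC", "GAG", "GAC",
                    "AAG", "ATC", "GTG", "CAG", "TTC", "TAC", "CCC", "ACC")

.coding_seq <- function(n) {
  stopifnot(n %% 3 == 0, n >= 9)
  n_codons <- n / 3 - 2
  paste0("ATG", paste(sample(.coding_codons, n_codons, replace = TRUE),
                      collapse = ""), "TAA")
}

# force every ORF below max_len nt by planting in-frame stops at ORF middles
.break_orfs <- function(sequence, max_len) {
  repeat {
    orf <- longest_orf(sequence)
    if (orf["length"] < max_len) return(sequence)
    mid_codon <- orf["start"] + 3 * floor(orf["length"] / 6)
    substr(sequence, mid_codon, mid_codon + 2) <- "TAA"
  }
}

.noncoding_seq <- function(n) {
  s <- .random_seq(n)
  .break_orfs(s, max_len = min(300, 2 * floor(n / 4) - 3))
}

# exact-correlation construction: a positive vector with sample Pearson
# correlation exactly rho against z (affine in a unit vector built from z
# and an orthogonalised Gaussian draw)
.exact_corr_vector <- function(z, rho, location = 6, spread = 5,
                               residual = NULL) {
  n <- length(z)
  zc <- z - mean(z)
  if (sqrt(sum(zc^2)) == 0) stop("exact_corr_vector: z has zero variance")
  u <- zc / sqrt(sum(zc^2))
  e <- if (is.null(residual)) stats::rnorm(n) else residual
  ec <- e - mean(e)
  ec <- ec - sum(ec * u) * u
  if (sqrt(sum(ec^2)) == 0) ec <- rep(c(1, -1), length.out = n) - mean(rep(c(1, -1), length.out = n))
  v <- ec / sqrt(sum(ec^2))
  raw <- rho * u + sqrt(1 - rho^2) * v
  location + spread * raw / max(abs(raw))
}

#' Generate the toy annotation, candidate classes and sequences
#'
#' Places coding genes (3 exons of 200 bp, 400 bp introns) in deterministic
#' 40-kb slots and realises each candidate's class label exactly by
#' construction: `intergenic_far` candidates sit >= 500 bp (planted
#' neighbour pairs at a 1000 bp gap, all others > 10 kb) from every coding
#' span, `intergenic_near` at a 200 bp gap, `exon_overlap` sharing 100 bp
#' with a coding exon, `intronic` inside an intron, `single_exon` and
#' `short` (< 200 bp spliced) far from genes. Candidate sequences come from
#' two hexamer regimes: planted coding-like candidates carry a full-length
#' ORF of GC-rich codons; all others are AT-rich with every ORF broken
#' below the coding thresholds.
#'
#' @param config A [sim_config()].
#' @return List with `reference` and `candidates` (`AnnotationSet`s),
#'   `truth` (list of data.frames: `candidates`, `features`, `pairs`, plus
#'   the `templates` matrix), `sequences` (candidate sequences) and
#'   `training` (coding/noncoding training sequences for
#'   [train_hexamer_table()]).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  W <- 40000L
  n_class <- .alloc_counts(config$n_candidates, config$class_mix)
  names(n_class) <- names(config$class_mix)
  n_far <- n_class[["intergenic_far"]]
  n_pair <- config$n_corr_pairs
  n_codlike <- round(config$prop_coding_like * n_far)
  n_lowexpr <- round(config$prop_low_expr * n_far)
  n_lone <- n_far - n_pair - n_codlike - n_lowexpr
  if (n_lone < 0) {
    stop("generate_annotation: class 'intergenic_far' infeasible: fewer far ",
         "candidates than planted pairs + coding-like + low-expression")
  }
  n_hf_lone <- config$n_hf_high - config$n_spatiotemporal
  n_de_lone <- config$n_de - config$n_spatiotemporal
  if (n_lone < config$n_tissue_specific + n_hf_lone + n_de_lone) {
    stop("generate_annotation: class 'intergenic_far' infeasible: not enough ",
         "lone intergenic candidates to carry the planted expression labels")
  }

  n_host <- max(n_class[["intergenic_near"]], n_class[["exon_overlap"]],
                n_class[["intronic"]])
  core_genes <- n_pair + 2L * config$n_cc_pairs + n_host
  if (config$n_coding_genes < core_genes) {
    stop("generate_annotation: n_coding_genes too small; need >= ", core_genes)
  }
  n_spare <- config$n_coding_genes - core_genes
  n_far_residents <- n_lone + n_codlike + n_lowexpr +
    n_class[["single_exon"]] + n_class[["short"]]
  n_far_slots <- ceiling(n_far_residents / 5)
  gene_part <- c(rep("pair", n_pair), rep("cc", config$n_cc_pairs),
                 rep("host", n_host), rep("spare", n_spare))
  far_part <- rep("far", n_far_slots)
  # interleave candidate-only slots among gene slots so every chromosome
  # carries reference genes
  pos <- c(seq(0, 1, length.out = max(length(gene_part), 2L))[seq_along(gene_part)],
           seq(0, 1, length.out = max(length(far_part), 2L))[seq_along(far_part)] + 1e-9)
  slot_types <- c(gene_part, far_part)[order(pos)]
  capacity <- sum(floor(config$genome$length / W))
  if (length(slot_types) > capacity) {
    stop("generate_annotation: genome too small to place all features ",
         "without forced overlap (need ", length(slot_types), " slots, have ",
         capacity, ")")
  }
  # slot -> (chrom, start)
  slot_chrom <- character(length(slot_types))
  slot_start <- integer(length(slot_types))
  i <- 1L
  for (ci in seq_len(nrow(config$genome))) {
    n_here <- min(floor(config$genome$length[ci] / W),
                  length(slot_types) - i + 1L)
    if (n_here <= 0) next
    idx <- seq(i, i + n_here - 1L)
    slot_chrom[idx] <- as.character(config$genome$chrom[ci])
    slot_start[idx] <- as.integer((seq_len(n_here) - 1L) * W + 1L)
    i <- i + n_here
    if (i > length(slot_types)) break
  }

  gene_exons <- function(gid, chrom, s) {
    data.frame(transcript_id = paste0(gid, ".1"), gene_id = gid, chrom = chrom,
               strand = "+", start = s + c(0L, 600L, 1200L),
               end = s + c(199L, 799L, 1399L), biotype = "coding",
               stringsAsFactors = FALSE)
  }
  two_exon <- function(tid, gid, chrom, s, strand, exon_len, intron_len) {
    data.frame(transcript_id = tid, gene_id = gid, chrom = chrom,
               strand = strand,
               start = c(s, s + exon_len + intron_len),
               end = c(s + exon_len - 1L, s + 2L * exon_len + intron_len - 1L),
               biotype = "linc_candidate", stringsAsFactors = FALSE)
  }

  ref_rows <- list()
  cand_rows <- list()
  truth_rows <- list()
  pair_rows <- list()
  gene_i <- 0L
  cand_i <- 0L
  next_gene <- function() {
    gene_i <<- gene_i + 1L
    sprintf("CG%04d", gene_i)
  }
  next_cand <- function() {
    cand_i <<- cand_i + 1L
    sprintf("CAND%04d", cand_i)
  }
  add_cand <- function(df, class, coding_like = FALSE, low_expr = FALSE,
                       pair_partner = NA_character_) {
    cand_rows[[length(cand_rows) + 1L]] <<- df
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      transcript_id = df$transcript_id[1], gene_id = df$gene_id[1],
      class = class, coding_like = coding_like, low_expr = low_expr,
      spliced_length = sum(df$end - df$start + 1L),
      is_lincRNA = class == "intergenic_far" && !coding_like && !low_expr,
      pair_partner = pair_partner, stringsAsFactors = FALSE)
  }

  host_counters <- c(near = 0L, overlap = 0L, intronic = 0L)
  far_queue <- c(rep("lone", n_lone), rep("coding_like", n_codlike),
                 rep("low_expr", n_lowexpr),
                 rep("single_exon", n_class[["single_exon"]]),
                 rep("short", n_class[["short"]]))
  far_q_pos <- 0L

  for (si in seq_along(slot_types)) {
    chrom <- slot_chrom[si]
    s <- slot_start[si]
    type <- slot_types[si]
    if (type == "pair") {
      gid <- next_gene()
      ref_rows[[length(ref_rows) + 1L]] <- gene_exons(gid, chrom, s)
      tid <- next_cand()
      gene_end <- s + 1399L
      df <- two_exon(tid, tid, chrom, gene_end + 1001L, "+", 201L, 300L)
      add_cand(df, "intergenic_far", pair_partner = gid)
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        linc_id = tid, linc_tx = tid, coding_id = gid,
        gap = 1000, stringsAsFactors = FALSE)
    } else if (type == "cc") {
      g1 <- next_gene(); g2 <- next_gene()
      ref_rows[[length(ref_rows) + 1L]] <- gene_exons(g1, chrom, s)
      ref_rows[[length(ref_rows) + 1L]] <- gene_exons(g2, chrom, s + 4000L)
    } else if (type == "host") {
      gid <- next_gene()
      ref_rows[[length(ref_rows) + 1L]] <- gene_exons(gid, chrom, s)
      gene_end <- s + 1399L
      if (host_counters[["near"]] < n_class[["intergenic_near"]]) {
        host_counters[["near"]] <- host_counters[["near"]] + 1L
        tid <- next_cand()
        add_cand(two_exon(tid, tid, chrom, gene_end + 201L, "-",
                          150L, 100L), "intergenic_near")
      }
      if (host_counters[["overlap"]] < n_class[["exon_overlap"]]) {
        host_counters[["overlap"]] <- host_counters[["overlap"]] + 1L
        tid <- next_cand()
        add_cand(two_exon(tid, tid, chrom, s + 1300L, "-",
                          150L, 100L), "exon_overlap")
      }
      if (host_counters[["intronic"]] < n_class[["intronic"]]) {
        host_counters[["intronic"]] <- host_counters[["intronic"]] + 1L
        tid <- next_cand()
        add_cand(two_exon(tid, tid, chrom, s + 240L, "-",
                          80L, 50L), "intronic")
      }
    } else if (type == "spare") {
      gid <- next_gene()
      ref_rows[[length(ref_rows) + 1L]] <- gene_exons(gid, chrom, s)
    } else if (type == "far") {
      offsets <- c(4000L, 10000L, 16000L, 22000L, 28000L)
      for (o in offsets) {
        if (far_q_pos >= length(far_queue)) break
        far_q_pos <- far_q_pos + 1L
        kind <- far_queue[far_q_pos]
        tid <- next_cand()
        pos <- s + o
        if (kind == "single_exon") {
          df <- data.frame(transcript_id = tid, gene_id = tid,
                           chrom = chrom, strand = "+", start = pos,
                           end = pos + 401L, biotype = "linc_candidate",
                           stringsAsFactors = FALSE)
          add_cand(df, "single_exon")
        } else if (kind == "short") {
          add_cand(two_exon(tid, tid, chrom, pos, "+", 80L, 100L),
                   "short")
        } else {
          df <- two_exon(tid, tid, chrom, pos, "+", 201L, 300L)
          add_cand(df, "intergenic_far",
                   coding_like = kind == "coding_like",
                   low_expr = kind == "low_expr")
        }
      }
    }
  }

  reference <- annotation_set(do.call(rbind, ref_rows))
  candidates <- if (length(cand_rows)) {
    annotation_set(do.call(rbind, cand_rows))
  } else {
    annotation_set(NULL)
  }
  cand_truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(transcript_id = character(), gene_id = character(),
               class = character(), coding_like = logical(),
               low_expr = logical(), spliced_length = integer(),
               is_lincRNA = logical(), pair_partner = character(),
               stringsAsFactors = FALSE)
  pairs_truth <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(linc_id = character(), linc_tx = character(),
               coding_id = character(), gap = numeric(), stringsAsFactors = FALSE)

  # sequences: coding-like candidates carry a full ORF; all others are
  # AT-rich with broken ORFs
  seqs <- character(nrow(cand_truth))
  names(seqs) <- cand_truth$transcript_id
  for (k in seq_len(nrow(cand_truth))) {
    len <- cand_truth$spliced_length[k]
    seqs[k] <- if (cand_truth$coding_like[k]) .coding_seq(len) else
      .noncoding_seq(len)
  }
  training <- list(
    coding = vapply(seq_len(30), function(i) .coding_seq(600L), character(1)),
    noncoding = vapply(seq_len(30), function(i) .random_seq(600L), character(1))
  )

  truth <- list(candidates = cand_truth, pairs = pairs_truth,
                templates = .cluster_templates(config$time_points,
                                               config$de_log2fc))
  truth$features <- .plant_feature_labels(config, cand_truth, pairs_truth,
                                          reference)
  truth$pairs$target_r <- ifelse(
    seq_len(nrow(truth$pairs)) <= config$n_spatiotemporal,
    config$spatiotemporal_r, config$target_r)
  list(reference = reference, candidates = candidates, truth = truth,
       sequences = seqs, training = training)
}

# assign planted expression labels to candidate/coding features
.plant_feature_labels <- function(config, cand_truth, pairs_truth, reference) {
  other_tissues <- setdiff(config$tissues, "HF")
  feat <- data.frame(
    feature_id = c(cand_truth$transcript_id,
                   unique(reference$transcripts$gene_id)),
    role = c(rep("candidate", nrow(cand_truth)),
             rep("coding", length(unique(reference$transcripts$gene_id)))),
    stringsAsFactors = FALSE)
  feat$tissue <- NA_character_
  feat$hf_high <- FALSE
  feat$de <- FALSE
  feat$template <- NA_integer_
  feat$low_expr <- feat$feature_id %in%
    cand_truth$transcript_id[cand_truth$low_expr]
  feat$pair_partner <- NA_character_
  feat$pair_r <- NA_real_
  feat$spatio_partner <- FALSE

  pair_tx <- pairs_truth$linc_tx
  st_tx <- utils::head(pair_tx, config$n_spatiotemporal)
  lone_tx <- cand_truth$transcript_id[cand_truth$class == "intergenic_far" &
                                        !cand_truth$coding_like &
                                        !cand_truth$low_expr &
                                        !cand_truth$transcript_id %in% pair_tx]
  n_hf_lone <- config$n_hf_high - config$n_spatiotemporal
  n_de_lone <- config$n_de - config$n_spatiotemporal
  ts_tx <- utils::head(lone_tx, config$n_tissue_specific)
  hf_tx <- utils::head(setdiff(lone_tx, ts_tx), n_hf_lone)
  de_tx <- utils::head(setdiff(lone_tx, c(ts_tx, hf_tx)), n_de_lone)

  idx <- function(ids) match(ids, feat$feature_id)
  if (length(ts_tx)) {
    feat$tissue[idx(ts_tx)] <- rep(other_tissues, length.out = length(ts_tx))
  }
  feat$hf_high[idx(c(hf_tx, st_tx))] <- TRUE
  # template allocation: spatiotemporal lincs forced onto template 1
  de_all <- c(st_tx, de_tx)
  feat$de[idx(de_all)] <- TRUE
  alloc <- .alloc_counts(length(de_all), .template_props)
  if (alloc[1] < length(st_tx)) alloc[1] <- length(st_tx)
  templ <- rep(seq_len(5), times = alloc)[seq_along(de_all)]
  templ[seq_along(st_tx)] <- 1L
  feat$template[idx(de_all)] <- templ

  # DE coding genes: drawn from genes that are not pair partners
  coding_ids <- feat$feature_id[feat$role == "coding"]
  de_coding_pool <- setdiff(coding_ids, pairs_truth$coding_id)
  if (config$n_de_coding > length(de_coding_pool)) {
    stop("generate_annotation: n_de_coding exceeds available coding genes")
  }
  de_cg <- utils::head(de_coding_pool, config$n_de_coding)
  feat$de[idx(de_cg)] <- TRUE
  feat$template[idx(de_cg)] <- rep(seq_len(5),
                                   times = .alloc_counts(length(de_cg),
                                                         .template_props))[seq_along(de_cg)]

  # neighbour pairs: linc side records partner and target correlation
  if (nrow(pairs_truth)) {
    pr <- ifelse(seq_len(nrow(pairs_truth)) <= config$n_spatiotemporal,
                 config$spatiotemporal_r, config$target_r)
    feat$pair_partner[idx(pairs_truth$linc_tx)] <- pairs_truth$coding_id
    feat$pair_r[idx(pairs_truth$linc_tx)] <- pr
  }
  # the spatiotemporal lincs' coding partners co-vary with template 1 by
  # construction, so they are themselves differentially expressed
  if (config$n_spatiotemporal > 0 && nrow(pairs_truth)) {
    partners <- pairs_truth$coding_id[seq_len(config$n_spatiotemporal)]
    feat$de[idx(partners)] <- TRUE
    feat$template[idx(partners)] <- 1L
    feat$spatio_partner[idx(partners)] <- TRUE
  }
  # expected membership in the seasonal-transition subset: block templates
  # are significant only across the block boundary; the partner profiles
  # also move within blocks
  feat$transition <- feat$de & !feat$spatio_partner &
    !is.na(feat$template) & feat$template %in% c(1L, 2L)
  feat
}

#' Generate the expression matrix and sample metadata
#'
#' Builds one FPKM matrix whose columns cover the tissue panel (one sample
#' per tissue) and the time course (`n_replicates` per time point), with all
#' planted structure realised exactly at `noise_sd = 0`: tissue-specific
#' features have a positive mean in exactly one tissue and 0 elsewhere;
#' HF-high features satisfy the fold rules by construction; DE features
#' follow their cluster template across the time points (templates 1-2 are
#' the cross-block shifts with the configured log2 fold change); planted
#' neighbour pairs achieve their target Pearson correlation over the tissue
#' profile exactly (affine construction); three constant reference assays
#' (`SDHA`, `UBC`, `YWHAZ`) are appended for qPCR normalisation. Gaussian
#' noise with SD `noise_sd` is added on log2(FPKM+1) and back-transformed
#' (clamped at 0).
#'
#' @param config A [sim_config()].
#' @param truth The `truth` element of [generate_annotation()] (or a
#'   compatible list with a `features` data.frame and `templates` matrix,
#'   e.g. from [make_expression_truth()]).
#' @param features Optional feature id vector; defaults to all truth
#'   features. Every truth feature must be covered.
#' @return List with `matrix` (FPKM) and `metadata` (`SampleMetadata`).
#' @export
generate_expression <- function(config, truth, features = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed + 1L)
  feat <- truth$features
  if (is.null(features)) features <- feat$feature_id
  unknown <- setdiff(feat$feature_id, features)
  if (length(unknown)) {
    stop("generate_expression: unknown feature id in truth: ", unknown[1])
  }
  templates <- truth$templates
  other_tissues <- setdiff(config$tissues, "HF")
  tissue_samples <- paste0("tissue_", config$tissues)
  time_samples <- as.vector(t(outer(config$time_points,
                                    seq_len(config$n_replicates),
                                    function(tp, r) paste0(tp, "_r", r))))
  samples <- c(tissue_samples, time_samples)
  meta <- sample_metadata(
    sample = samples,
    tissue = c(config$tissues, rep(NA_character_, length(time_samples))),
    time_point = c(rep(NA_character_, length(tissue_samples)),
                   rep(config$time_points, each = config$n_replicates)),
    replicate = c(rep(1L, length(tissue_samples)),
                  rep(seq_len(config$n_replicates), times = length(config$time_points)))
  )
  n_feat <- nrow(feat)
  mu <- base::matrix(0, nrow = n_feat, ncol = length(samples),
                     dimnames = list(feat$feature_id, samples))
  t_cols <- stats::setNames(match(tissue_samples, samples), config$tissues)
  tp_cols <- lapply(config$time_points, function(tp) {
    which(grepl(paste0("^", tp, "_r"), samples))
  })
  names(tp_cols) <- config$time_points

  baselines <- 2^stats::rnorm(n_feat, config$baseline_log2_mean,
                              config$baseline_log2_sd)
  # mean FPKM per feature/sample
  for (k in seq_len(n_feat)) {
    b <- baselines[k]
    # tissue columns
    if (feat$low_expr[k]) {
      # unreliable but flat: below the reliability cut in every sample
      mu[k, ] <- stats::runif(1, 0.05, 0.45)
      next
    }
    if (!is.na(feat$tissue[k])) {
      mu[k, t_cols[feat$tissue[k]]] <- stats::runif(1, 30, 80)
      # 0 elsewhere, including the time course (not a skin-expressed gene)
    } else if (feat$hf_high[k]) {
      mu[k, t_cols["HF"]] <- stats::runif(1, 80, 150)
      mu[k, t_cols[other_tissues]] <- stats::runif(length(other_tissues), 0.8, 1.2)
    } else {
      # variable-but-unstructured tissue profile
      mu[k, t_cols] <- b * 2^stats::rnorm(length(t_cols), 0, 0.8)
    }
    # time columns
    if (feat$de[k]) {
      prof <- templates[feat$template[k], config$time_points]
      for (tp in config$time_points) mu[k, tp_cols[[tp]]] <- prof[tp]
    } else if (is.na(feat$tissue[k])) {
      mu[k, unlist(tp_cols)] <- b
    }
  }
  # planted neighbour pairs: overwrite the partner's tissue profile with an
  # exact-correlation construction against the linc's tissue profile; the
  # spatiotemporal pairs also get a correlated time profile
  paired <- which(!is.na(feat$pair_partner))
  for (k in paired) {
    partner <- match(feat$pair_partner[k], feat$feature_id)
    z <- mu[k, t_cols]
    mu[partner, t_cols] <- .exact_corr_vector(z, feat$pair_r[k])
    if (feat$de[k]) {
      zt <- vapply(config$time_points, function(tp) mu[k, tp_cols[[tp]][1]],
                   numeric(1))
      # deterministic residual direction keeps the partner profile (and its
      # planted correlation) exactly reproducible
      resid <- c(1, -1, rep(0, length(zt) - 2L))
      xt <- .exact_corr_vector(zt, feat$pair_r[k], location = 12, spread = 10,
                               residual = resid)
      for (j in seq_along(config$time_points)) {
        mu[partner, tp_cols[[config$time_points[j]]]] <- xt[j]
      }
    }
  }
  # constant reference assays for qPCR normalisation
  refs <- c("SDHA", "UBC", "YWHAZ")
  ref_block <- base::matrix(8, nrow = 3, ncol = ncol(mu),
                            dimnames = list(refs, colnames(mu)))
  mu <- rbind(mu, ref_block)

  if (config$noise_sd > 0) {
    noise <- stats::rnorm(length(mu), 0, config$noise_sd)
    mat <- pmax(2^(log2(mu + 1) + noise) - 1, 0)
    mat <- base::matrix(mat, nrow = nrow(mu), dimnames = dimnames(mu))
  } else {
    mat <- mu
  }
  list(matrix = mat, metadata = meta)
}

#' Build a label table for pure expression simulations
#'
#' Constructs a `truth` object compatible with [generate_expression()]
#' without any genome geometry: useful for statistical calibration runs
#' (null false-positive rate, DE power, cluster recovery) on arbitrary
#' feature counts.
#'
#' @param config A [sim_config()].
#' @param n_features Number of features.
#' @param de Logical vector (recycled) marking DE features.
#' @param template Integer vector (recycled) of template ids for DE
#'   features.
#' @return List with `features` and `templates` as in
#'   [generate_annotation()]'s truth.
#' @export
make_expression_truth <- function(config, n_features, de = FALSE,
                                  template = 1L) {
  feat <- data.frame(
    feature_id = sprintf("F%05d", seq_len(n_features)),
    role = "feature",
    tissue = NA_character_,
    hf_high = FALSE,
    de = rep_len(de, n_features),
    template = NA_integer_,
    low_expr = FALSE,
    pair_partner = NA_character_,
    pair_r = NA_real_,
    stringsAsFactors = FALSE)
  feat$template[feat$de] <- rep_len(template, sum(feat$de))
  list(features = feat,
       templates = .cluster_templates(config$time_points, config$de_log2fc))
}

#' Generate a Ct table consistent with an expression matrix
#'
#' Simulates qPCR of the time-course samples under perfect amplification
#' efficiency: `Ct = ct_at_unit_expression - log2(FPKM)`, so that inverting
#' via 2^-ddCt recovers relative expression exactly in the noise-free case.
#' Non-positive abundances are capped at `ct_max` and flagged.
#'
#' @param expression FPKM matrix (from [generate_expression()]).
#' @param metadata `SampleMetadata` matching the matrix.
#' @param targets Assay feature ids to measure.
#' @param reference_ids Reference assay ids (constant expression).
#' @param ct_at_unit_expression Ct corresponding to FPKM 1.
#' @param ct_max Cap applied to non-positive abundances.
#' @param noise_sd SD of Gaussian Ct noise (cycles).
#' @param seed Seed for the Ct noise.
#' @return A [ct_table()] with one row per (time-course sample, assay).
#' @export
generate_qpcr <- function(expression, metadata, targets, reference_ids,
                          ct_at_unit_expression = 30, ct_max = 40,
                          noise_sd = 0, seed = 1L) {
  .check_matrix(expression, metadata)
  set.seed(seed)
  meta <- metadata[match(colnames(expression), metadata$sample), ]
  tc <- which(!is.na(meta$time_point))
  if (!length(tc)) stop("generate_qpcr: no time-course samples in metadata")
  assays <- c(targets, reference_ids)
  missing <- setdiff(assays, rownames(expression))
  if (length(missing)) stop("generate_qpcr: unknown assay: ", missing[1])
  rows <- list()
  for (j in tc) {
    for (a in assays) {
      ab <- expression[a, j]
      capped <- ab <= 0
      ct <- if (capped) ct_max else ct_at_unit_expression - log2(ab)
      if (noise_sd > 0) ct <- ct + stats::rnorm(1, 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = meta$sample[j], condition = meta$time_point[j], assay = a,
        ct = ct, replicate = meta$replicate[j], capped = capped,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  ct_table(df$sample, df$condition, df$assay, df$ct, df$replicate, df$capped)
}

#' Per-feature time-point mean expression
#'
#' @param matrix FPKM matrix.
#' @param metadata `SampleMetadata`; only time-annotated samples are used.
#' @return Feature-by-time-point matrix of mean FPKM, columns in canonical
#'   time order.
#' @export
time_point_means <- function(matrix, metadata) {
  .check_matrix(matrix, metadata)
  meta <- metadata[match(colnames(matrix), metadata$sample), ]
  tps <- intersect(linc_time_points(), unique(meta$time_point))
  if (!length(tps)) stop("time_point_means: no time-annotated samples")
  out <- vapply(tps, function(tp) {
    rowMeans(matrix[, which(!is.na(meta$time_point) & meta$time_point == tp),
                    drop = FALSE])
  }, numeric(nrow(matrix)))
  base::matrix(out, nrow = nrow(matrix),
               dimnames = list(rownames(matrix), tps))
}

#' Run the full synthetic study
#'
#' Generates annotation, sequences, hexamer training sets and expression in
#' one call.
#'
#' @param config A [sim_config()].
#' @return List with `reference`, `candidates`, `truth`, `sequences`,
#'   `training`, `hexamer_table`, `expression` (matrix) and `metadata`.
#' @export
simulate_study <- function(config = sim_config()) {
  ann <- generate_annotation(config)
  expr <- generate_expression(config, ann$truth)
  tab <- train_hexamer_table(ann$training$coding, ann$training$noncoding)
  c(ann, list(hexamer_table = tab, expression = expr$matrix,
              metadata = expr$metadata))
}
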