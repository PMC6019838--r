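# Relative quantification by the 2^-ddCt method with multi-reference
# normalisation, and concordance of qPCR quantities with RNA-seq expression.

#' Ct table constructor
#'
#' Long-format table of qPCR threshold cycles: one row per measured well.
#'
#' @param sample Sample id.
#' @param condition Condition id (e.g. time point) used for averaging and
#'   calibration.
#' @param assay Assay (target or reference gene) id.
#' @param ct Threshold cycle; may carry `capped = TRUE` when the reaction
#'   never crossed threshold and Ct was set to the instrument maximum.
#' @param replicate Technical replicate index.
#' @param capped Logical flag per row.
#' @return data.frame of class `CtTable`.
#' @export
ct_table <- function(sample, condition, assay, ct, replicate = 1L,
                     capped = FALSE) {
  df <- data.frame(sample = as.character(sample),
                   condition = as.character(condition),
                   assay = as.character(assay),
                   ct = as.numeric(ct),
                   replicate = as.integer(replicate),
                   capped = as.logical(capped),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$ct))) stop("ct_table: non-finite Ct values")
  class(df) <- c("CtTable", class(df))
  df
}

#' Relative quantification by 2^-ddCt
#'
#' Technical replicates are averaged first (arithmetic mean of Ct). Within
#' each condition, `dCt = Ct_target - mean(Ct_references)`; the arithmetic
#' mean over reference Cts is equivalent to normalising against the
#' geometric mean of the reference quantities. `ddCt` subtracts the
#' calibrator condition's `dCt`, and the relative quantity is
#' `efficiency^(-ddCt)` (perfect amplification, efficiency 2, by default).
#' The calibrator's quantity is identically 1.
#'
#' @param table `CtTable` containing the target and all reference assays in
#'   every condition.
#' @param target Assay id to quantify.
#' @param references Character vector of reference assay ids.
#' @param calibrator Condition id used as the calibrator.
#' @param efficiency Amplification base (2 = perfect doubling).
#' @return data.frame with `condition`, `delta_ct`, `delta_delta_ct`,
#'   `relative_quantity`, `unreliable` (TRUE when a capped Ct entered the
#'   computation for that condition).
#' @export
delta_delta_ct <- function(table, target, references, calibrator,
                           efficiency = 2) {
  stopifnot(inherits(table, "CtTable"), length(references) >= 1)
  conditions <- unique(table$condition)
  if (!calibrator %in% conditions) {
    stop("delta_delta_ct: calibrator condition '", calibrator, "' not present")
  }
  mean_ct <- function(cond, assay) {
    rows <- table$condition == cond & table$assay == assay
    if (!any(rows)) {
      stop("delta_delta_ct: assay '", assay, "' missing in condition '", cond, "'")
    }
    list(ct = mean(table$ct[rows]), capped = any(table$capped[rows]))
  }
  per_cond <- lapply(conditions, function(cond) {
    tgt <- mean_ct(cond, target)
    refs <- lapply(references, function(r) mean_ct(cond, r))
    data.frame(condition = cond,
               delta_ct = tgt$ct - mean(vapply(refs, `[[`, numeric(1), "ct")),
               unreliable = tgt$capped || any(vapply(refs, `[[`, logical(1), "capped")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_cond)
  cal_dct <- out$delta_ct[out$condition == calibrator]
  out$delta_delta_ct <- out$delta_ct - cal_dct
  out$relative_quantity <- efficiency^(-out$delta_delta_ct)
  rownames(out) <- NULL
  out
}

#' Concordance of qPCR and RNA-seq time-course series
#'
#' Both series are converted to log2 ratios relative to the reference time
#' point (`log2(value / value_at_reference)`, the reference mapping to 0)
#' and compared per assay by the Pearson correlation over time points. A
#' zero at the reference (or any) time point of the RNA-seq series is
#' stabilised with an additive `eps` and flagged.
#'
#' @param qpcr Assay-by-time-point matrix of relative quantities (from
#'   [delta_delta_ct()], reference column equal to 1).
#' @param rnaseq Assay-by-time-point matrix of FPKM over the same time
#'   points (row/column names matched).
#' @param reference Reference time point (calibrator), default `"Oct"`.
#' @param eps Stabiliser applied when a series contains zeros.
#' @return data.frame with `assay`, `pearson_r`, `flagged`.
#' @export
rnaseq_concordance <- function(qpcr, rnaseq, reference = "Oct", eps = 0.1) {
  stopifnot(is.matrix(qpcr), is.matrix(rnaseq))
  assays <- intersect(rownames(qpcr), rownames(rnaseq))
  tps <- intersect(colnames(qpcr), colnames(rnaseq))
  if (!reference %in% tps) {
    stop("rnaseq_concordance: reference time point '", reference, "' not shared")
  }
  rows <- lapply(assays, function(a) {
    q <- qpcr[a, tps]
    s <- rnaseq[a, tps]
    flagged <- FALSE
    if (any(s == 0)) {
      s <- s + eps
      flagged <- TRUE
    }
    qlr <- log2(q / q[reference])
    slr <- log2(s / s[reference])
    r <- if (stats::sd(qlr) == 0 || stats::sd(slr) == 0) NA_real_ else
      stats::cor(qlr, slr)
    data.frame(assay = a, pearson_r = r, flagged = flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
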