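#' Normalise arrays
#'
#' Removes array-to-array technical variation before fold-change
#' computation. Quantile normalisation (default; delegated to
#' [limma::normalizeQuantiles()]) forces every array onto the average
#' order-statistic distribution; median scaling subtracts each array's
#' median offset from the grand median. Both operate on log2 signals and
#' are idempotent on already-normalised data.
#'
#' @param raw an `intensity_matrix`.
#' @param method "quantile" or "median".
#' @return an `intensity_matrix` with normalised values.
#' @export
normalize_arrays <- function(raw, method = c("quantile", "median")) {
  method <- match.arg(method)
  v <- raw$values
  if (ncol(v) < 2) stop("need at least 2 arrays", call. = FALSE)
  if (any(!is.finite(v))) stop("non-finite intensities", call. = FALSE)
  v <- switch(method,
    quantile = {
      out <- limma::normalizeQuantiles(v)
      dimnames(out) <- dimnames(v)
      out
    },
    median = {
      med <- apply(v, 2, stats::median)
      sweep(v, 2, med - stats::median(med))
    })
  raw$values <- v
  raw
}

#' Per-probe log2 fold change of an accession against the reference
#'
#' Averages log2 signals over the accession's replicate arrays and over
#' the reference accession's replicate arrays, and returns the difference
#' (log2 of the signal ratio). Negative values indicate weakened
#' hybridisation of the accession's DNA to the reference-design probe.
#'
#' @param norm a normalised `intensity_matrix`.
#' @param accession accession id.
#' @return named numeric vector, one log2FC per probe.
#' @export
compute_log2fc <- function(norm, accession) {
  arr <- norm$arrays
  a_cols <- arr$array_id[arr$accession == accession]
  r_cols <- arr$array_id[arr$accession == norm$reference]
  if (!length(a_cols)) stop("unknown accession: ", accession, call. = FALSE)
  if (!length(r_cols)) stop("reference accession not present", call. = FALSE)
  rowMeans(norm$values[, a_cols, drop = FALSE]) -
    rowMeans(norm$values[, r_cols, drop = FALSE])
}

#' log2 fold changes for all accessions
#'
#' @param norm a normalised `intensity_matrix`.
#' @param accessions accession ids (default: all non-reference).
#' @return probe x accession matrix of log2FC.
#' @export
log2fc_matrix <- function(norm, accessions = NULL) {
  if (is.null(accessions)) {
    accessions <- setdiff(unique(norm$arrays$accession), norm$reference)
  }
  vapply(accessions, function(a) compute_log2fc(norm, a),
         numeric(nrow(norm$values)))
}

#' Call single feature polymorphisms
#'
#' A probe is called an SFP for an accession when it has a single exact
#' genomic match (unique flag) and its log2 fold change is at or below the
#' threshold (inclusive boundary; -1.5 corresponds to a 2.8-fold signal
#' decrease). Non-unique probes are never called regardless of fold
#' change.
#'
#' @param log2fc numeric vector (one accession) or probe x accession
#'   matrix.
#' @param probes probe map aligned with `log2fc` rows.
#' @param threshold log2FC call threshold (negative).
#' @return An `sfp_call_set`: list with `log2fc`, `called` (same shape,
#'   logical), `threshold`, `probes`.
#' @export
call_sfps <- function(log2fc, probes, threshold = -1.5) {
  if (!is.matrix(log2fc)) log2fc <- matrix(log2fc, ncol = 1,
                                           dimnames = list(names(log2fc), "acc"))
  stopifnot(nrow(log2fc) == nrow(probes))
  if (threshold >= 0) stop("threshold must be negative", call. = FALSE)
  called <- !is.na(log2fc) & log2fc <= threshold & probes$unique
  structure(list(log2fc = log2fc, called = called,
                 threshold = threshold, probes = probes),
            class = "sfp_call_set")
}

#' Genotype matrix from SFP calls
#'
#' 0 = reference-like, 1 = SFP, restricted to unique probes.
#'
#' @param calls an `sfp_call_set`.
#' @return accession x site integer matrix (sites named by probe id).
#' @export
sfp_genotypes <- function(calls) {
  keep <- calls$probes$unique
  g <- t(calls$called[keep, , drop = FALSE]) * 1L
  colnames(g) <- calls$probes$probe_id[keep]
  g
}

#' Calibrate the SFP threshold with ROC against a truth set
#'
#' Sweeps a grid of log2FC thresholds, classifying each (accession,
#' unique probe) pair against the truth polymorphism labels, and reports
#' the ROC together with the false discovery rate (false positives among
#' called SFPs) and false negative rate (false negatives among all truly
#' polymorphic probes) at each threshold. The chosen threshold is the
#' smallest-magnitude grid value with FDR at or below `fdr_cap`.
#'
#' @param log2fc probe x accession matrix.
#' @param truth_genotypes accession x probe 0/1 truth matrix (1 = probe
#'   truly polymorphic in that accession).
#' @param probes probe map (non-unique probes are excluded).
#' @param grid thresholds to sweep.
#' @param fdr_cap FDR cap used to pick the threshold.
#' @return A `calibration_report` data.frame (threshold, TP, FP, FN, TN,
#'   TPR, FPR, FDR, FNR) with attributes `chosen` and `fdr_cap`.
#' @export
calibrate_threshold <- function(log2fc, truth_genotypes, probes,
                                grid = seq(-3, -0.5, by = 0.1),
                                fdr_cap = 0.1) {
  keep <- probes$unique
  acc <- colnames(log2fc)
  truth <- t(truth_genotypes[acc, keep, drop = FALSE]) > 0
  fc <- log2fc[keep, acc, drop = FALSE]
  n_pos <- sum(truth)
  if (n_pos == 0) stop("degenerate truth: no polymorphic probes", call. = FALSE)

  rows <- lapply(sort(grid), function(th) {
    call <- fc <= th
    tp <- sum(call & truth); fp <- sum(call & !truth)
    fn <- sum(!call & truth); tn <- sum(!call & !truth)
    data.frame(threshold = th, TP = tp, FP = fp, FN = fn, TN = tn,
               TPR = tp / (tp + fn), FPR = fp / (fp + tn),
               FDR = if (tp + fp > 0) fp / (tp + fp) else 0,
               FNR = fn / (tp + fn))
  })
  rep <- do.call(rbind, rows)
  ok <- rep$FDR <= fdr_cap
  chosen <- if (any(ok)) max(rep$threshold[ok]) else min(rep$threshold)
  attr(rep, "chosen") <- chosen
  attr(rep, "fdr_cap") <- fdr_cap
  class(rep) <- c("calibration_report", "data.frame")
  rep
}

#' Pairwise accession distance from SFP calls
#'
#' Hamming fraction over unique probes: the proportion of probes whose
#' call flags differ between two accessions. Used for distance-based
#' clustering of accessions.
#'
#' @param calls an `sfp_call_set` with >= 2 accessions.
#' @return symmetric matrix with zero diagonal.
#' @export
pairwise_accession_distance <- function(calls) {
  g <- sfp_genotypes(calls)
  if (nrow(g) < 2) stop("need >= 2 accessions", call. = FALSE)
  d <- as.matrix(stats::dist(g, method = "manhattan")) / ncol(g)
  dimnames(d) <- list(rownames(g), rownames(g))
  d
}
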