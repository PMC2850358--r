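#' Run-length segmentation utilities
#'
#' Deletions and duplications are detected as maximal runs of consecutive
#' unique probes satisfying a fold-change criterion. Runs never bridge
#' chromosomes, and intervening non-unique probes break runs (the analysis
#' is restricted to unique probes, and genome-order adjacency across a
#' masked gap is ambiguous). Segment bp extent runs from the first probe's
#' start to the last probe's end (0-based half-open).
#'
#' @name segment-calls
NULL

# maximal runs of TRUE within one chromosome, respecting unique-probe gaps
find_runs <- function(flag, chrom, unique_probe, min_run) {
  eligible <- flag & unique_probe
  # a run may only contain consecutive unique probes of one chromosome:
  # split on chromosome changes and on non-unique probes
  grp <- cumsum(c(TRUE, chrom[-1] != chrom[-length(chrom)])) +
    cumsum(!unique_probe) * length(chrom)
  out <- list()
  r <- rle(paste0(grp, "_", eligible))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- grepl("_TRUE$", r$values) & r$lengths >= min_run
  data.frame(from = starts[keep], to = ends[keep])
}

segment_rows <- function(runs, probes, accession, kind) {
  if (!nrow(runs)) {
    return(data.frame(accession = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_probes = integer(), kind = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(accession = accession,
             chrom = probes$chrom[runs$from],
             start = probes$start[runs$from],
             end = probes$start[runs$to] + probes$length[runs$to],
             n_probes = runs$to - runs$from + 1L,
             kind = kind, stringsAsFactors = FALSE)
}

#' Call deletions as runs of consecutive SFPs
#'
#' Stretches of called SFPs longer than a typical exon are interpreted as
#' deletions: maximal runs of at least `min_run` consecutive called unique
#' probes (default 10 probes, about 350 bp) become one deletion each.
#'
#' @param calls an `sfp_call_set`.
#' @param probes probe map aligned to the calls (defaults to
#'   `calls$probes`).
#' @param min_run minimum run length in probes.
#' @return data.frame of segments: `accession`, `chrom`, `start`, `end`
#'   (0-based half-open bp), `n_probes`, `kind`.
#' @export
call_deletions <- function(calls, probes = calls$probes, min_run = 10L) {
  out <- lapply(colnames(calls$called), function(a) {
    runs <- find_runs(calls$called[, a], probes$chrom, probes$unique, min_run)
    segment_rows(runs, probes, a, "deletion")
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call duplications as runs of strong positive fold change
#'
#' Maximal runs of at least `min_run` consecutive unique probes whose
#' log2FC is at or above `min_log2fc` (default +2, i.e. > 4-fold gain; a
#' permissive 2-fold variant uses `min_log2fc = 1`).
#'
#' @param log2fc probe x accession matrix.
#' @param probes probe map.
#' @param min_run minimum run length in probes.
#' @param min_log2fc positive log2FC threshold.
#' @return data.frame of segments as in [call_deletions()].
#' @export
call_duplications <- function(log2fc, probes, min_run = 10L, min_log2fc = 2) {
  if (min_log2fc <= 0) stop("min_log2fc must be positive", call. = FALSE)
  if (!is.matrix(log2fc)) log2fc <- matrix(log2fc, ncol = 1,
                                           dimnames = list(NULL, "acc"))
  out <- lapply(colnames(log2fc), function(a) {
    flag <- !is.na(log2fc[, a]) & log2fc[, a] >= min_log2fc
    runs <- find_runs(flag, probes$chrom, probes$unique, min_run)
    segment_rows(runs, probes, a, "duplication")
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise segment calls
#'
#' Per-accession and overall counts, mean bp length and total bp, plus a
#' per-segment sharing count: how many accessions carry a segment of the
#' same kind overlapping it.
#'
#' @param segments data.frame from [call_deletions()] /
#'   [call_duplications()] (may mix kinds).
#' @return list with `per_accession`, `overall` and `segments` (input plus
#'   a `shared_by` column).
#' @export
summarize_segments <- function(segments) {
  if (!nrow(segments)) {
    return(list(per_accession = data.frame(accession = character(),
                                           kind = character(), n = integer(),
                                           mean_bp = numeric(), total_bp = numeric()),
                overall = data.frame(kind = character(), n = integer(),
                                     mean_bp = numeric(), total_bp = numeric()),
                segments = segments))
  }
  segments$length_bp <- segments$end - segments$start
  per_acc <- do.call(rbind, lapply(split(segments,
      list(segments$accession, segments$kind), drop = TRUE), function(d) {
    data.frame(accession = d$accession[1], kind = d$kind[1], n = nrow(d),
               mean_bp = mean(d$length_bp), total_bp = sum(d$length_bp))
  }))
  overall <- do.call(rbind, lapply(split(segments, segments$kind), function(d) {
    data.frame(kind = d$kind[1], n = nrow(d), mean_bp = mean(d$length_bp),
               total_bp = sum(d$length_bp),
               mean_per_accession = nrow(d) / length(unique(d$accession)))
  }))
  rownames(per_acc) <- rownames(overall) <- NULL

  gr <- GenomicRanges::GRanges(segments$chrom,
          IRanges::IRanges(segments$start + 1L, segments$end))
  hits <- GenomicRanges::findOverlaps(gr, gr)
  same_kind <- segments$kind[S4Vectors::queryHits(hits)] ==
    segments$kind[S4Vectors::subjectHits(hits)]
  acc_pair <- segments$accession[S4Vectors::subjectHits(hits)]
  shared <- vapply(seq_len(nrow(segments)), function(i) {
    j <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i & same_kind]
    length(unique(segments$accession[j]))
  }, integer(1))
  segments$shared_by <- shared
  list(per_accession = per_acc, overall = overall, segments = segments)
}
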