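#' Map genomic sites to annotation features
#'
#' Assigns every site (a 1 bp position, or a probe midpoint) all
#' overlapping annotation classes and gene ids; a site inside a CDS that
#' also lies in a transposon counts for both. Positions covered by no
#' feature are classed `intergenic`. Overlap is computed with
#' GenomicRanges interval trees.
#'
#' @param sites data.frame with `chrom` and `pos` (0-based bp).
#' @param annotation data.frame (`chrom`, `start`, `end` 0-based half-open,
#'   `class`, `gene`, optional `family`, `metabolic_gene`).
#' @param chrom_lengths optional named vector; sites beyond a chromosome
#'   end raise a coordinate error.
#' @return data.frame with one row per (site, overlapping feature):
#'   `site_index`, `chrom`, `pos`, `class`, `gene`, `family`,
#'   `metabolic_gene`.
#' @export
map_sites_to_features <- function(sites, annotation, chrom_lengths = NULL) {
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[sites$chrom]
    if (any(!is.na(lim) & sites$pos >= lim)) {
      stop("coordinate error: site beyond chromosome end", call. = FALSE)
    }
  }
  sg <- GenomicRanges::GRanges(sites$chrom,
          IRanges::IRanges(sites$pos + 1L, sites$pos + 1L))
  ag <- GenomicRanges::GRanges(annotation$chrom,
          IRanges::IRanges(annotation$start + 1L, annotation$end))
  hits <- GenomicRanges::findOverlaps(sg, ag)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  getcol <- function(nm) if (nm %in% names(annotation))
    annotation[[nm]][sh] else rep(NA_character_, length(sh))
  mapped <- data.frame(site_index = qh, chrom = sites$chrom[qh],
                       pos = sites$pos[qh],
                       class = annotation$class[sh],
                       gene = getcol("gene"), family = getcol("family"),
                       metabolic_gene = getcol("metabolic_gene"),
                       stringsAsFactors = FALSE)
  orphan <- setdiff(seq_len(nrow(sites)), unique(qh))
  if (length(orphan)) {
    mapped <- rbind(mapped, data.frame(
      site_index = orphan, chrom = sites$chrom[orphan],
      pos = sites$pos[orphan], class = "intergenic",
      gene = NA_character_, family = NA_character_,
      metabolic_gene = NA_character_, stringsAsFactors = FALSE))
  }
  mapped[order(mapped$site_index), , drop = FALSE]
}

#' Expected counts under a length-proportional null
#'
#' Under the null that polymorphisms fall uniformly on the genome, a class
#' covering `class_bp` of `genome_bp` bases is expected to receive
#' `total_sfps * class_bp / genome_bp` SFPs.
#'
#' @param total_sfps total SFP count.
#' @param class_bp named vector of per-class bp (computed on the union of
#'   each class's intervals).
#' @param genome_bp total genome size, bp.
#' @return named numeric vector of expected counts.
#' @export
expected_counts <- function(total_sfps, class_bp, genome_bp) {
  if (genome_bp <= 0) stop("genome_bp must be positive", call. = FALSE)
  if (any(class_bp > genome_bp)) {
    stop("annotation error: class_bp exceeds genome_bp", call. = FALSE)
  }
  total_sfps * class_bp / genome_bp
}

#' Union bp covered by each annotation class
#'
#' @param annotation feature annotation data.frame.
#' @param by column to group on ("class" or "family" or "gene").
#' @return named numeric vector of union-reduced interval lengths.
#' @export
class_bp <- function(annotation, by = "class") {
  ann <- annotation[!is.na(annotation[[by]]), , drop = FALSE]
  vapply(split(ann, ann[[by]]), function(d) {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(d$chrom,
            IRanges::IRanges(d$start + 1L, d$end)))
    sum(GenomicRanges::width(gr))
  }, numeric(1))
}

#' Enrichment/depletion test for one feature class
#'
#' `chi2`: two-cell goodness-of-fit chi-squared on (in-class,
#' out-of-class) counts against the length-proportional expectation,
#' df = 1. `t_across_accessions`: unpaired Student's t-test of the
#' per-accession observed counts against the per-accession expected
#' counts.
#'
#' @param observed in-class SFP count (scalar for chi2, or per-accession
#'   vector for the t method).
#' @param expected expected in-class count(s) under the null.
#' @param total total SFP count (chi2 method).
#' @param method "chi2" or "t_across_accessions".
#' @return one-row data.frame: `observed`, `expected`, `statistic`, `p`,
#'   `direction`.
#' @export
test_enrichment <- function(observed, expected, total = NULL,
                            method = c("chi2", "t_across_accessions")) {
  method <- match.arg(method)
  if (any(expected <= 0)) stop("expected must be > 0", call. = FALSE)
  if (method == "chi2") {
    stopifnot(length(observed) == 1, length(expected) == 1)
    if (total < observed) stop("count error: total < observed", call. = FALSE)
    if (observed == expected) {
      stat <- 0; p <- 1
    } else {
      ht <- suppressWarnings(stats::chisq.test(
        c(observed, total - observed),
        p = c(expected / total, 1 - expected / total)))
      stat <- unname(ht$statistic); p <- ht$p.value
    }
    obs_sum <- observed; exp_sum <- expected
  } else {
    ht <- stats::t.test(observed, expected, var.equal = TRUE)
    stat <- unname(ht$statistic); p <- ht$p.value
    obs_sum <- mean(observed); exp_sum <- mean(expected)
  }
  data.frame(observed = obs_sum, expected = exp_sum, statistic = stat,
             p = p,
             direction = if (obs_sum >= exp_sum) "enriched" else "depleted",
             stringsAsFactors = FALSE)
}

#' Feature-class enrichment table
#'
#' Observed versus expected SFP counts for every annotation class, with
#' chi-squared p-values and a Benjamini-Hochberg adjusted column.
#'
#' @param sites data.frame `chrom`, `pos` of SFP sites (one row per site).
#' @param annotation feature annotation.
#' @param genome_bp total genome bp.
#' @return data.frame, one row per class, sorted by p.
#' @export
feature_enrichment_table <- function(sites, annotation, genome_bp) {
  mapped <- map_sites_to_features(sites, annotation)
  # count each site once per class
  obs <- table(unique(mapped[, c("site_index", "class")])$class)
  bp <- class_bp(annotation)
  bp["intergenic"] <- genome_bp - sum(GenomicRanges::width(
    GenomicRanges::reduce(GenomicRanges::GRanges(annotation$chrom,
      IRanges::IRanges(annotation$start + 1L, annotation$end)))))
  total <- nrow(sites)
  classes <- names(bp)[bp > 0]
  rows <- lapply(classes, function(cl) {
    e <- expected_counts(total, bp[[cl]], genome_bp)
    o <- if (cl %in% names(obs)) as.integer(obs[[cl]]) else 0L
    cbind(class = cl, test_enrichment(o, e, total, "chi2"),
          class_bp = bp[[cl]])
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}

#' Gene-family SFP and segment report
#'
#' Per gene family: observed and expected SFP counts (length-proportional
#' null over the annotated genome), chi-squared enrichment p, BH-adjusted
#' p, and total deletion / duplication bp overlapping the family's genes.
#' Families with no annotated intervals are excluded. Rows are sorted by
#' significance.
#'
#' @param sites SFP site data.frame (`chrom`, `pos`), pooled over
#'   accessions.
#' @param segments segment data.frame (may be empty).
#' @param annotation feature annotation with a `family` column.
#' @param genome_bp total genome bp.
#' @return data.frame, one row per family.
#' @export
gene_family_report <- function(sites, segments, annotation, genome_bp) {
  fam_bp <- class_bp(annotation, by = "family")
  fam_bp <- fam_bp[fam_bp > 0]
  if (!length(fam_bp)) return(data.frame())
  mapped <- map_sites_to_features(sites, annotation)
  mapped <- mapped[!is.na(mapped$family), , drop = FALSE]
  obs <- table(unique(mapped[, c("site_index", "family")])$family)
  total <- nrow(sites)

  seg_bp <- function(kind) {
    segs <- segments[segments$kind == kind, , drop = FALSE]
    if (is.null(segs) || !nrow(segs)) {
      return(stats::setNames(numeric(length(fam_bp)), names(fam_bp)))
    }
    sg <- GenomicRanges::GRanges(segs$chrom,
            IRanges::IRanges(segs$start + 1L, segs$end))
    vapply(names(fam_bp), function(f) {
      d <- annotation[!is.na(annotation$family) & annotation$family == f, ]
      fg <- GenomicRanges::reduce(GenomicRanges::GRanges(d$chrom,
              IRanges::IRanges(d$start + 1L, d$end)))
      sum(GenomicRanges::width(suppressWarnings(GenomicRanges::intersect(
        GenomicRanges::reduce(sg), fg))))
    }, numeric(1))
  }
  del_bp <- seg_bp("deletion"); dup_bp <- seg_bp("duplication")

  rows <- lapply(names(fam_bp), function(f) {
    e <- expected_counts(total, fam_bp[[f]], genome_bp)
    o <- if (f %in% names(obs)) as.integer(obs[[f]]) else 0L
    cbind(family = f, test_enrichment(o, e, total, "chi2"),
          family_bp = fam_bp[[f]], deletion_bp = del_bp[[f]],
          duplication_bp = dup_bp[[f]])
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
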