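#' Simulate a genome annotation
#'
#' Lays out protein-coding genes (alternating CDS/intron parts),
#' transposons and a few non-coding RNA genes along each chromosome and
#' assigns gene-family labels; a subset of genes is tagged as metabolic and
#' linked to the simulated reaction network's gene ids. Coordinates are
#' 0-based half-open internally (the GFF3 writer converts to 1-based
#' inclusive).
#'
#' @param probes probe map (defines chromosome extents).
#' @param config a [sim_config()] object.
#' @param network optional `metabolic_network` whose gene ids are attached
#'   to metabolic genes.
#' @return data.frame with columns `chrom`, `start`, `end`, `class`,
#'   `gene`, `family`, `metabolic_gene` (NA where not applicable).
#' @export
generate_annotation <- function(probes, config, network = NULL) {
  set.seed(stage_seed(config$seed, "annotation"))
  chr_len <- chromosome_lengths(probes)
  fam_levels <- paste0("FAM", sprintf("%02d", seq_len(config$n_families)))
  net_genes <- if (!is.null(network)) unique(network$gene_map$gene) else character()
  net_i <- 0L

  rows <- list()
  gi <- 0L
  fam_i <- 0L
  for (ch in names(chr_len)) {
    pos <- 200L
    L <- chr_len[[ch]]
    while (pos + 1500L < L) {
      u <- stats::runif(1)
      if (u < 0.70) {                       # protein-coding gene
        gi <- gi + 1L
        gene <- sprintf("GENE%04d", gi)
        glen <- round(stats::runif(1, 1500, 3000))
        glen <- min(glen, L - pos - 1L)
        # round-robin family labels so every configured family is populated
        fam <- NA_character_
        if (stats::runif(1) < 0.4) {
          fam_i <- fam_i + 1L
          fam <- fam_levels[((fam_i - 1L) %% length(fam_levels)) + 1L]
        }
        met <- NA_character_
        if (length(net_genes) && stats::runif(1) < 0.35) {
          net_i <- net_i + 1L
          met <- net_genes[((net_i - 1L) %% length(net_genes)) + 1L]
        }
        # alternate CDS / intron parts across the gene body
        n_ex <- sample(2:5, 1)
        cuts <- sort(c(0, round(stats::runif(2 * n_ex - 2, 0, glen)), glen))
        for (k in seq_len(length(cuts) - 1L)) {
          if (cuts[k + 1] <= cuts[k]) next
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = ch, start = pos + cuts[k], end = pos + cuts[k + 1],
            class = if (k %% 2 == 1) "CDS" else "intron",
            gene = gene, family = fam, metabolic_gene = met,
            stringsAsFactors = FALSE)
        }
        pos <- pos + glen + round(stats::runif(1, 400, 2000))
      } else if (u < 0.90) {                # transposon
        tlen <- round(stats::runif(1, 500, 4000))
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = pos, end = min(pos + tlen, L),
          class = "transposon", gene = NA_character_,
          family = NA_character_, metabolic_gene = NA_character_,
          stringsAsFactors = FALSE)
        pos <- pos + tlen + round(stats::runif(1, 300, 1500))
      } else {                              # small ncRNA
        gi <- gi + 1L
        cls <- sample(c("ncRNA", "miRNA", "snRNA", "tRNA", "pseudogene"), 1)
        tlen <- round(stats::runif(1, 80, 400))
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = pos, end = min(pos + tlen, L),
          class = cls, gene = sprintf("GENE%04d", gi),
          family = NA_character_, metabolic_gene = NA_character_,
          stringsAsFactors = FALSE)
        pos <- pos + tlen + round(stats::runif(1, 300, 1500))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-probe SNP-rate multiplier implied by an annotation
#'
#' Probes overlapping genes of the designated enriched family get their
#' polymorphism rate multiplied by `config$enriched_family_factor`, so that
#' family-level SFP enrichment is recoverable downstream.
#'
#' @param probes probe map.
#' @param annotation from [generate_annotation()].
#' @param config a [sim_config()] object.
#' @param family family label to boost (default the first family).
#' @return numeric multiplier per probe (1 elsewhere).
#' @export
family_rate_multiplier <- function(probes, annotation, config,
                                   family = "FAM01") {
  fam <- annotation[!is.na(annotation$family) & annotation$family == family, ]
  mult <- rep(1, nrow(probes))
  if (!nrow(fam)) return(mult)
  pg <- GenomicRanges::GRanges(probes$chrom,
          IRanges::IRanges(probes$start + 1L, probes$start + probes$length))
  fg <- GenomicRanges::GRanges(fam$chrom, IRanges::IRanges(fam$start + 1L, fam$end))
  hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(pg, fg)))
  mult[hit] <- config$enriched_family_factor
  mult
}

#' Simulate a genetic map marker table
#'
#' Places markers with known physical and genetic positions along each
#' chromosome. The underlying true map is a monotone cubic in physical
#' position (recombination accelerates towards chromosome ends) with small
#' Gaussian noise on the genetic coordinate.
#'
#' @param probes probe map.
#' @param config a [sim_config()] object.
#' @param markers_per_chromosome marker count per chromosome.
#' @param cm_noise_frac sd of genetic-position noise as a fraction of the
#'   chromosome's total map length (noise scales with the genome size so
#'   scaled-down runs keep a usable map).
#' @return data.frame `chrom`, `bp`, `cm`.
#' @export
generate_genetic_map <- function(probes, config,
                                 markers_per_chromosome = 50L,
                                 cm_noise_frac = 0.01) {
  set.seed(stage_seed(config$seed, "genetic_map"))
  chr_len <- chromosome_lengths(probes)
  out <- do.call(rbind, lapply(names(chr_len), function(ch) {
    L <- chr_len[[ch]]
    bp <- sort(c(0, sample.int(L, markers_per_chromosome - 2L), L))
    x <- bp / 1e6
    X <- L / 1e6
    c1 <- 0.7 * config$cm_per_mb
    c3 <- 0.3 * config$cm_per_mb / X^2
    span <- c1 * X + c3 * X^3
    cm <- c1 * x + c3 * x^3 + stats::rnorm(length(x), 0, cm_noise_frac * span)
    cm <- cummax(pmax(cm, 0))                 # keep the truth monotone
    data.frame(chrom = ch, bp = bp, cm = cm, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
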