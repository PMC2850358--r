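#' Simulate a complete dataset
#'
#' Runs every generator in dependency order: probe map, annotation,
#' metabolic network, admixed population (with family-boosted SNP rates),
#' planted variants, intensities, phenotypes and genetic map.
#'
#' @param config a [sim_config()] object.
#' @return list with `config`, `probes`, `annotation`, `network`, `pop`,
#'   `truth`, `intensities`, `phenotypes`, `genetic_map`.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 1, n_accessions = 8,
#'   n_chromosomes = 1, probes_per_chromosome = 150))
#' dim(sim$truth$genotypes)
simulate_dataset <- function(config) {
  probes <- generate_probe_map(config)
  network <- generate_metabolic_network(config)
  annotation <- generate_annotation(probes, config, network)
  mult <- family_rate_multiplier(probes, annotation, config)
  pop <- generate_population(config, probes, rate_mult = mult)
  truth <- plant_variants(pop, probes, config)
  intensities <- simulate_intensities(truth, probes, config)
  phenotypes <- simulate_phenotypes(truth, pop$qmatrix, config)
  genetic_map <- generate_genetic_map(probes, config)
  list(config = config, probes = probes, annotation = annotation,
       network = network, pop = pop, truth = truth,
       intensities = intensities, phenotypes = phenotypes,
       genetic_map = genetic_map)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write all simulated inputs as plain-text files
#'
#' Emits the pipeline's external interface: probe map, intensity matrix,
#' truth files, GFF3 annotation, phenotype / Q-matrix / geography tables,
#' metabolic network and genetic map.
#'
#' @param sim list from [simulate_dataset()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_sim_data <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  paths <- c(probe_map = p("probe_map.tsv"),
             intensities = p("intensities.tsv"),
             genotype_truth = p("genotype_truth.tsv"),
             segments_truth = p("segments_truth.tsv"),
             sweep_truth = p("sweep_truth.tsv"),
             annotation = p("annotation.gff3"),
             phenotypes = p("phenotypes.tsv"),
             qmatrix = p("qmatrix.tsv"),
             geo = p("geo.tsv"),
             network = p("network.tsv"),
             gene_map = p("gene_map.tsv"),
             genetic_map = p("genetic_map.tsv"))

  write_tsv(sim$probes, paths["probe_map"])

  iv <- as.data.frame(sim$intensities$values)
  iv <- cbind(probe_id = sim$intensities$probe_id, iv)
  write_tsv(iv, paths["intensities"])

  gt <- as.data.frame(t(sim$truth$genotypes))
  gt <- cbind(probe_id = colnames(sim$truth$genotypes), gt)
  write_tsv(gt, paths["genotype_truth"])

  segs <- rbind(sim$truth$deletions, sim$truth$duplications)
  write_tsv(segs, paths["segments_truth"])

  sw <- data.frame(accession = rownames(sim$truth$genotypes))
  sw$carrier <- sw$accession %in% sim$truth$sweep_carriers
  write_tsv(sw, paths["sweep_truth"])

  write_annotation_gff3(sim$annotation, paths["annotation"],
                        chromosome_lengths(sim$probes))
  write_tsv(sim$phenotypes, paths["phenotypes"])

  qm <- cbind(accession = rownames(sim$pop$qmatrix),
              as.data.frame(sim$pop$qmatrix))
  write_tsv(qm, paths["qmatrix"])
  write_tsv(sim$pop$geo, paths["geo"])

  rx <- sim$network$reactions
  rx$pathway <- sim$network$gene_map$pathway[match(rx$reaction,
                                                  sim$network$gene_map$reaction)]
  write_tsv(rx, paths["network"])
  write_tsv(sim$network$gene_map, paths["gene_map"])
  write_tsv(sim$genetic_map, paths["genetic_map"])
  invisible(paths)
}

#' Write a feature annotation as GFF3
#'
#' Converts the internal 0-based half-open intervals to the 1-based
#' inclusive GFF3 convention and stores gene / family / metabolic tags as
#' attributes.
#'
#' @param annotation data.frame from [generate_annotation()].
#' @param path output file.
#' @param chrom_lengths named vector of chromosome lengths (for the GFF3
#'   sequence-region pragma).
#' @export
write_annotation_gff3 <- function(annotation, path, chrom_lengths = NULL) {
  gr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start + 1L, annotation$end),
    type = annotation$class,
    ID = sprintf("feat%05d", seq_len(nrow(annotation))))
  S4Vectors::mcols(gr)$gene <- annotation$gene
  S4Vectors::mcols(gr)$family <- annotation$family
  S4Vectors::mcols(gr)$metabolic_gene <- annotation$metabolic_gene
  S4Vectors::mcols(gr)$phase <- ifelse(annotation$class == "CDS", 0L,
                                       NA_integer_)
  if (!is.null(chrom_lengths)) {
    GenomeInfoDb::seqlengths(gr) <- chrom_lengths[GenomeInfoDb::seqlevels(gr)]
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 feature annotation
#'
#' Inverse of [write_annotation_gff3()]: returns the internal 0-based
#' half-open data.frame layout.
#'
#' @param path GFF3 file.
#' @return data.frame `chrom`, `start`, `end`, `class`, `gene`, `family`,
#'   `metabolic_gene`.
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  get <- function(nm) if (nm %in% names(mc)) as.character(mc[[nm]]) else
    rep(NA_character_, length(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             class = get("type"),
             gene = get("gene"),
             family = get("family"),
             metabolic_gene = get("metabolic_gene"),
             stringsAsFactors = FALSE)
}

#' Read an intensity matrix TSV
#' @param path intensity TSV written by [write_sim_data()].
#' @param arrays data.frame `array_id`, `accession`; if `NULL` the
#'   accession is parsed from array ids of the form `<accession>_A<rep>`.
#' @param reference reference accession id.
#' @return an `intensity_matrix`.
#' @export
read_intensity_matrix <- function(path, arrays = NULL, reference = "Col-0") {
  d <- read_tsv(path)
  vals <- as.matrix(d[, -1, drop = FALSE])
  rownames(vals) <- d$probe_id
  if (is.null(arrays)) {
    arrays <- data.frame(array_id = colnames(vals),
                         accession = sub("_A[0-9]+$", "", colnames(vals)),
                         stringsAsFactors = FALSE)
  }
  structure(list(values = vals, arrays = arrays, reference = reference,
                 probe_id = d$probe_id),
            class = "intensity_matrix")
}

#' Read a genotype matrix TSV (sites x accessions)
#' @param path TSV with a `probe_id` column then one column per accession.
#' @return accession x site 0/1 matrix.
#' @export
read_genotype_matrix <- function(path) {
  d <- read_tsv(path)
  g <- t(as.matrix(d[, -1, drop = FALSE]))
  colnames(g) <- d$probe_id
  storage.mode(g) <- "integer"
  g
}
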