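#' Simulation configuration
#'
#' Builds the configuration object consumed by every generator in the
#' synthetic-data module. Defaults emulate the structure of a 54-accession
#' *Arabidopsis thaliana* tiling-array study scaled to desk size: 5
#' chromosomes tiled by 25-mer probes, a 4-population admixed sample, planted
#' deletions/duplications, one planted selective sweep and nine quantitative
#' traits generated from a marker + environment + structure linear model.
#'
#' @param seed integer seed; every generator is a pure function of
#'   `(config, seed)`.
#' @param n_accessions number of non-reference accessions (default 54).
#' @param n_chromosomes number of chromosomes.
#' @param probes_per_chromosome probes tiled per chromosome.
#' @param probe_length probe footprint in bases (25-mer arrays).
#' @param probe_spacing distance between consecutive probe starts, bases.
#' @param n_populations number of ancestral populations (default 4).
#' @param snp_rate per-base SNP probability on a founder haplotype; the
#'   per-probe polymorphism rate is `1 - (1-snp_rate)^probe_length`.
#' @param prop_unique fraction of probes with a single exact genomic match;
#'   only those carry SFP calls.
#' @param gc_shape1,gc_shape2 Beta parameters for probe GC fraction.
#' @param deletion_specs list of planted deletions, each
#'   `list(accessions=, chrom=, start_probe=, n_probes=)` (1-based probe
#'   index within the chromosome).
#' @param duplication_specs list of planted duplications, same shape plus
#'   an implicit fold gain of `dup_fold`.
#' @param dup_fold raw fold gain of duplicated probes (default 8, log2FC
#'   +3, comfortably above the conservative 4-fold detection rule).
#' @param sweep_spec planted sweep:
#'   `list(chrom=, start_probe=, n_probes=, carrier_fraction=)`. Carriers
#'   receive one shared founder haplotype over the region. `NULL` disables.
#' @param trait_specs list of trait generators, each
#'   `list(name=, causal=, effect=, noise_sd=, env_effect=)` where `causal`
#'   is a global probe index or `NA` for a null trait.
#' @param n_experiments replicate experiments (environments) per accession.
#' @param n_replicate_arrays replicate arrays hybridised per accession
#'   (and for the reference).
#' @param atten_peak peak log2 attenuation caused by one SNP at the probe
#'   centre.
#' @param atten_gc_slope linear GC modulation of the attenuation (fractional
#'   change per unit GC deviation from 0.5).
#' @param noise_sd additive noise on the log2 intensity scale.
#' @param background_delta log2 drop of a deleted probe below the reference
#'   signal.
#' @param geo_dispersion within-population geographic scatter, km.
#' @param cm_per_mb average genetic-map slope, cM per Mb.
#' @param recomb_block_probes mean founder-mosaic block length in probes.
#' @param n_families number of labelled gene families in the annotation.
#' @param enriched_family_factor SNP-rate multiplier applied to the first
#'   gene family (so enrichment is recoverable).
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_chromosomes = 1, probes_per_chromosome = 200)
#' cfg$probe_length
sim_config <- function(seed = 1L,
                       n_accessions = 54L,
                       n_chromosomes = 5L,
                       probes_per_chromosome = 1200L,
                       probe_length = 25L,
                       probe_spacing = 35L,
                       n_populations = 4L,
                       snp_rate = 0.004,
                       prop_unique = 0.9,
                       gc_shape1 = 12, gc_shape2 = 12,
                       deletion_specs = NULL,
                       duplication_specs = NULL,
                       dup_fold = 8,
                       sweep_spec = default_sweep_spec(probes_per_chromosome),
                       trait_specs = NULL,
                       n_experiments = 2L,
                       n_replicate_arrays = 2L,
                       atten_peak = 3.2,
                       atten_gc_slope = 0.4,
                       noise_sd = 0.35,
                       background_delta = 4,
                       geo_dispersion = 150,
                       cm_per_mb = 4,
                       recomb_block_probes = 60,
                       n_families = 6L,
                       enriched_family_factor = 3) {
  cfg <- list(
    seed = as.integer(seed),
    n_accessions = as.integer(n_accessions),
    n_chromosomes = as.integer(n_chromosomes),
    probes_per_chromosome = as.integer(probes_per_chromosome),
    probe_length = as.integer(probe_length),
    probe_spacing = as.integer(probe_spacing),
    n_populations = as.integer(n_populations),
    snp_rate = snp_rate,
    prop_unique = prop_unique,
    gc_shape1 = gc_shape1, gc_shape2 = gc_shape2,
    deletion_specs = deletion_specs %||%
      default_deletion_specs(n_chromosomes, probes_per_chromosome,
                             n_accessions),
    duplication_specs = duplication_specs %||%
      default_duplication_specs(n_chromosomes, probes_per_chromosome,
                                n_accessions),
    dup_fold = dup_fold,
    sweep_spec = sweep_spec,
    trait_specs = trait_specs %||%
      default_trait_specs(n_chromosomes * probes_per_chromosome),
    n_experiments = as.integer(n_experiments),
    n_replicate_arrays = as.integer(n_replicate_arrays),
    atten_peak = atten_peak,
    atten_gc_slope = atten_gc_slope,
    noise_sd = noise_sd,
    background_delta = background_delta,
    geo_dispersion = geo_dispersion,
    cm_per_mb = cm_per_mb,
    recomb_block_probes = recomb_block_probes,
    n_families = as.integer(n_families),
    enriched_family_factor = enriched_family_factor
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# planted-segment defaults scale to the configured genome so that scaled-down
# test runs keep the same study conditions (28/15/12-probe deletions, 14/11-
# probe duplications, mostly private to one accession)
default_deletion_specs <- function(n_chrom, n_probes, n_acc) {
  sp <- list(
    list(accessions = c(2L, 3L), chrom = 1L, frac = 0.15, n_probes = 28L),
    list(accessions = 5L,        chrom = 2L, frac = 0.25, n_probes = 15L),
    list(accessions = 7L,        chrom = 3L, frac = 0.55, n_probes = 12L)
  )
  scale_segment_specs(sp, n_chrom, n_probes, n_acc)
}

default_duplication_specs <- function(n_chrom, n_probes, n_acc) {
  sp <- list(
    list(accessions = 4L, chrom = 2L, frac = 0.65, n_probes = 14L),
    list(accessions = 9L, chrom = 4L, frac = 0.35, n_probes = 11L)
  )
  scale_segment_specs(sp, n_chrom, n_probes, n_acc)
}

scale_segment_specs <- function(sp, n_chrom, n_probes, n_acc) {
  sp <- Filter(function(s) all(s$accessions <= n_acc), sp)
  sp <- lapply(sp, function(s) {
    s$chrom <- ((s$chrom - 1L) %% n_chrom) + 1L
    s$start_probe <- max(1L, min(as.integer(round(s$frac * n_probes)),
                                 n_probes - s$n_probes + 1L))
    s$frac <- NULL
    s
  })
  Filter(function(s) s$start_probe + s$n_probes - 1L <= n_probes, sp)
}

#' @rdname sim_config
#' @export
default_sweep_spec <- function(n_probes = 1200L) {
  # one long shared haplotype: a quarter of chromosome 1, carried by 40%
  # of accessions (block length >> founder-mosaic block scale)
  len <- max(20L, as.integer(round(0.25 * n_probes)))
  start <- max(1L, as.integer(round(0.4 * n_probes)))
  if (start + len - 1L > n_probes) start <- max(1L, n_probes - len + 1L)
  list(chrom = 1L, start_probe = start, n_probes = len,
       carrier_fraction = 0.4)
}

#' @rdname sim_config
#' @export
default_trait_specs <- function(n_sites = 6000L) {
  # nine traits: fresh weight style lead trait plus eight metabolic traits;
  # a mix of causal markers (at fixed genome fractions) and two null traits
  nm <- c("fresh_weight", "protein", "amino_acids", "sucrose", "starch",
          "myo_inositol", "beta_alanine", "threonic_acid", "erythritol")
  frac <- c(0.025, 0.085, 0.22, NA, 0.45, 0.65, NA, 0.75, 0.12)
  causal <- as.integer(pmax(1, round(frac * n_sites)))
  effect <- c(1.5, 1.2, 1.0, 0, 1.3, 1.0, 0, 1.1, 0.9)
  lapply(seq_along(nm), function(i) {
    list(name = nm[i], causal = causal[i], effect = effect[i],
         noise_sd = 1, env_effect = 0.5)
  })
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_accessions >= 1, cfg$n_chromosomes >= 1,
    cfg$probes_per_chromosome >= 1, cfg$probe_length >= 1,
    cfg$n_populations >= 1, cfg$n_experiments >= 1,
    cfg$n_replicate_arrays >= 1
  )
  if (cfg$probe_spacing < 1) {
    stop("invalid config: probe_spacing must be >= 1", call. = FALSE)
  }
  if (cfg$snp_rate < 0 || cfg$snp_rate > 1) {
    stop("invalid config: snp_rate must be in [0, 1]", call. = FALSE)
  }
  if (cfg$prop_unique < 0 || cfg$prop_unique > 1) {
    stop("invalid config: prop_unique must be in [0, 1]", call. = FALSE)
  }
  for (d in c(cfg$deletion_specs, cfg$duplication_specs)) {
    if (d$n_probes < 1) {
      stop("invalid config: planted segment lengths must be >= 1 probe",
           call. = FALSE)
    }
    if (d$chrom > cfg$n_chromosomes ||
        d$start_probe + d$n_probes - 1L > cfg$probes_per_chromosome) {
      stop("invalid config: planted segment outside chromosome bounds",
           call. = FALSE)
    }
  }
  sw <- cfg$sweep_spec
  if (!is.null(sw)) {
    if (sw$carrier_fraction < 0 || sw$carrier_fraction > 1) {
      stop("invalid config: sweep carrier_fraction must be in [0, 1]",
           call. = FALSE)
    }
    if (sw$chrom > cfg$n_chromosomes ||
        sw$start_probe + sw$n_probes - 1L > cfg$probes_per_chromosome) {
      stop("invalid config: sweep region outside chromosome bounds",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Derive a stage-specific seed from the global seed
#'
#' Stages draw from independent streams so that each generator is
#' reproducible on its own. The derivation keeps seeds within 32-bit
#' integer range.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  offs <- c(probe_map = 11L, population = 23L, variants = 37L,
            intensities = 53L, phenotypes = 71L, network = 89L,
            annotation = 101L, genetic_map = 113L, scan = 131L,
            geography = 151L)
  o <- offs[[stage]]
  if (is.null(o)) stop("unknown stage: ", stage, call. = FALSE)
  as.integer((as.numeric(seed) * 7919 + o) %% .Machine$integer.max)
}
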