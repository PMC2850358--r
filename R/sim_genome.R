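#' Generate a tiling-array probe map
#'
#' Tiles each chromosome with fixed-length probes at a constant spacing.
#' Probe GC fractions are drawn from a Beta distribution and a configured
#' fraction of probes is flagged as having multiple genomic matches
#' (non-unique); only unique probes are eligible for SFP calls downstream.
#'
#' @param config a [sim_config()] object.
#' @return A `data.frame` with columns `probe_id`, `chrom`, `start`
#'   (0-based), `length`, `gc`, `unique`, ordered by chromosome then
#'   position. Row order defines the global probe index used throughout.
#' @export
#' @examples
#' pm <- generate_probe_map(sim_config(seed = 1, n_chromosomes = 1,
#'                                     probes_per_chromosome = 100))
#' nrow(pm)
generate_probe_map <- function(config) {
  validate_sim_config(config)
  n <- config$probes_per_chromosome
  set.seed(stage_seed(config$seed, "probe_map"))
  out <- do.call(rbind, lapply(seq_len(config$n_chromosomes), function(ch) {
    start <- (seq_len(n) - 1L) * config$probe_spacing
    data.frame(
      probe_id = sprintf("P%d_%05d", ch, seq_len(n)),
      chrom = paste0("Chr", ch),
      start = start,
      length = config$probe_length,
      gc = round(stats::rbeta(n, config$gc_shape1, config$gc_shape2), 4),
      unique = stats::runif(n) < config$prop_unique,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Chromosome lengths implied by a probe map
#' @param probes probe map data.frame.
#' @return named integer vector of chromosome end coordinates (bp).
#' @export
chromosome_lengths <- function(probes) {
  vapply(split(probes, probes$chrom),
         function(d) max(d$start + d$length), numeric(1))
}

#' Generate an admixed population sample
#'
#' Each accession receives admixture proportions (a Q-matrix row, summing to
#' 1), a haplotype built as a mosaic of population-specific founder
#' haplotypes, and geographic coordinates scattered around its primary
#' population's centre, so accessions of the same population are closer in
#' expectation.
#'
#' Allele frequencies follow a Balding-Nichols-style model: a global
#' per-probe polymorphism rate differentiated into population-specific
#' frequencies, founders drawn per population, and each accession copying
#' founder blocks of geometric length.
#'
#' @param config a [sim_config()] object.
#' @param probes probe map from [generate_probe_map()].
#' @param rate_mult optional per-probe multiplier on the polymorphism rate
#'   (see [family_rate_multiplier()]).
#' @return list with `genotypes` (accession x probe 0/1 matrix, 1 =
#'   non-reference allele in the probe footprint), `qmatrix` (accession x
#'   population), `geo` (data.frame accession, lat, lon), `founders`
#'   (internal founder haplotypes), `primary_pop`.
#' @export
generate_population <- function(config, probes, rate_mult = NULL) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "population"))
  n <- config$n_accessions
  K <- config$n_populations
  m <- nrow(probes)
  acc <- sprintf("Acc%02d", seq_len(n))

  # per-probe global polymorphism rate, then population differentiation
  p_probe <- rep(1 - (1 - config$snp_rate)^config$probe_length, m)
  if (!is.null(rate_mult)) p_probe <- pmin(p_probe * rate_mult, 0.95)
  fst <- 0.15
  a <- p_probe * (1 - fst) / fst
  b <- (1 - p_probe) * (1 - fst) / fst
  pop_freq <- matrix(stats::rbeta(K * m, rep(a, each = K), rep(b, each = K)),
                     nrow = K)

  founders_per_pop <- 3L
  founders <- lapply(seq_len(K), function(k) {
    matrix(stats::runif(founders_per_pop * m) < rep(pop_freq[k, ],
                                                    each = founders_per_pop),
           nrow = founders_per_pop) * 1L
  })

  primary <- rep(seq_len(K), length.out = n)
  alpha_base <- 0.2
  qmat <- do.call(rbind, lapply(primary, function(k) {
    al <- rep(alpha_base, K); al[k] <- 6
    g <- stats::rgamma(K, shape = al)
    g / sum(g)
  }))
  dimnames(qmat) <- list(acc, paste0("Q", seq_len(K)))

  # founder-mosaic haplotypes: geometric block lengths per chromosome
  chrom_index <- as.integer(factor(probes$chrom, levels = unique(probes$chrom)))
  G <- matrix(0L, nrow = n, ncol = m, dimnames = list(acc, probes$probe_id))
  for (i in seq_len(n)) {
    for (ch in unique(chrom_index)) {
      idx <- which(chrom_index == ch)
      pos <- 1L
      while (pos <= length(idx)) {
        len <- 1L + stats::rgeom(1, 1 / config$recomb_block_probes)
        block <- idx[pos:min(pos + len - 1L, length(idx))]
        k <- sample.int(K, 1, prob = qmat[i, ])
        f <- sample.int(founders_per_pop, 1)
        G[i, block] <- founders[[k]][f, block]
        pos <- pos + len
      }
    }
  }

  # population centres on a continental grid; scatter in km around centre
  centre_lat <- 45 + 6 * seq_len(K)
  centre_lon <- 5 + 9 * ((seq_len(K) - 1L) %% 4L)
  lat <- centre_lat[primary] + stats::rnorm(n, 0, config$geo_dispersion / 111)
  lon <- centre_lon[primary] + stats::rnorm(n, 0, config$geo_dispersion /
                                              (111 * cospi(centre_lat[primary] / 180)))
  geo <- data.frame(accession = acc, lat = lat, lon = lon,
                    stringsAsFactors = FALSE)

  list(genotypes = G, qmatrix = qmat, geo = geo,
       founders = founders, primary_pop = primary)
}

#' Plant variants and structural events into a simulated population
#'
#' Applies the configured deletions, duplications and selective sweep to
#' the founder-derived genotypes and assembles the truth set used to
#' calibrate SFP calling: per-accession polymorphic probes, per-probe SNP
#' detail (count and within-probe positions, which drive signal
#' attenuation), planted segment intervals and sweep carrier labels.
#'
#' Sweep carriers are the first `round(fraction * n)` accessions in
#' genotype order (round half up); over the sweep region every carrier is
#' given one common founder haplotype, so carriers are pairwise identical
#' across the region.
#'
#' @param pop population from [generate_population()].
#' @param probes probe map.
#' @param config a [sim_config()] object.
#' @return A `truth_set` list: `genotypes` (final 0/1 matrix),
#'   `snp_detail` (per polymorphic probe: n_snps, positions), `deletions`,
#'   `duplications` (data.frames accession/chrom/probe interval),
#'   `sweep_carriers` (character), `sweep_region` (global probe index
#'   range or NULL), `causal_markers` (per trait).
#' @export
plant_variants <- function(pop, probes, config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "variants"))
  G <- pop$genotypes
  n <- nrow(G)
  acc <- rownames(G)
  chrom_levels <- unique(probes$chrom)
  chrom_index <- as.integer(factor(probes$chrom, levels = chrom_levels))

  seg_df <- function(specs, kind) {
    if (length(specs) == 0) {
      return(data.frame(accession = character(), chrom = character(),
                        probe_from = integer(), probe_to = integer(),
                        kind = character(), stringsAsFactors = FALSE))
    }
    do.call(rbind, lapply(specs, function(s) {
      g0 <- which(chrom_index == s$chrom)[1] - 1L
      data.frame(accession = acc[s$accessions],
                 chrom = chrom_levels[s$chrom],
                 probe_from = g0 + s$start_probe,
                 probe_to = g0 + s$start_probe + s$n_probes - 1L,
                 kind = kind, stringsAsFactors = FALSE)
    }))
  }
  dels <- seg_df(config$deletion_specs, "deletion")
  dups <- seg_df(config$duplication_specs, "duplication")

  # a deletion and a duplication may not overlap within one accession
  if (nrow(dels) && nrow(dups)) {
    for (i in seq_len(nrow(dels))) for (j in seq_len(nrow(dups))) {
      if (dels$accession[i] == dups$accession[j] &&
          dels$probe_from[i] <= dups$probe_to[j] &&
          dups$probe_from[j] <= dels$probe_to[i]) {
        stop("invalid config: overlapping deletion and duplication in ",
             dels$accession[i], call. = FALSE)
      }
    }
  }

  sweep_region <- NULL
  sweep_carriers <- character()
  sw <- config$sweep_spec
  if (!is.null(sw)) {
    g0 <- which(chrom_index == sw$chrom)[1] - 1L
    sweep_region <- c(g0 + sw$start_probe, g0 + sw$start_probe + sw$n_probes - 1L)
    n_car <- as.integer(floor(sw$carrier_fraction * n + 0.5))  # round half up
    carriers <- seq_len(n_car)
    sweep_carriers <- acc[carriers]
    idx <- sweep_region[1]:sweep_region[2]
    hap <- pop$founders[[1]][1, idx]
    G[carriers, idx] <- rep(hap, each = length(carriers))
  }

  # per-probe SNP detail for every probe polymorphic in at least one
  # accession: SNP count and within-probe positions (1-based), shared by
  # all carriers of the non-reference allele
  poly_sites <- which(colSums(G) > 0)
  n_snps <- 1L + stats::rpois(length(poly_sites), 0.4)
  snp_pos <- lapply(seq_along(poly_sites), function(i) {
    sort(sample.int(config$probe_length, min(n_snps[i], config$probe_length)))
  })
  snp_detail <- data.frame(site = poly_sites,
                           n_snps = pmin(n_snps, config$probe_length))
  snp_detail$positions <- snp_pos

  # snap each trait's causal marker to the nearest site with intermediate
  # allele frequency so the planted effect is identifiable in the sample
  f <- colMeans(G)
  eligible <- which(f >= 0.15 & f <= 0.85)
  causal <- lapply(config$trait_specs, function(ts) {
    if (is.na(ts$causal) || ts$effect == 0) return(NA_integer_)
    if (!length(eligible)) return(NA_integer_)
    eligible[which.min(abs(eligible - ts$causal))]
  })
  names(causal) <- vapply(config$trait_specs, function(ts) ts$name, "")

  structure(list(genotypes = G, snp_detail = snp_detail,
                 deletions = dels, duplications = dups,
                 sweep_carriers = sweep_carriers,
                 sweep_region = sweep_region,
                 causal_markers = causal,
                 probes = probes),
            class = "truth_set")
}
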