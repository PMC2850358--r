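# Shared small simulated datasets, cached per test session.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, maker) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- maker()
  .sim_cache[[key]]
}

# mid-size noisy dataset used by calling/segment/enrichment tests
tiny_sim <- function() {
  cached_sim("tiny", function() {
    simulate_dataset(sim_config(seed = 11, n_accessions = 16,
                                n_chromosomes = 2,
                                probes_per_chromosome = 400))
  })
}

# noiseless, all-unique dataset for exact recovery checks
clean_sim <- function() {
  cached_sim("clean", function() {
    simulate_dataset(sim_config(seed = 12, n_accessions = 16,
                                n_chromosomes = 2,
                                probes_per_chromosome = 400,
                                prop_unique = 1, noise_sd = 0))
  })
}

# genotype + site table + fitted map for sweep tests
sweep_inputs <- function(sim) {
  g <- maf_filter(sim$truth$genotypes)
  pm <- sim$probes[match(colnames(g), sim$probes$probe_id), ]
  list(g = g,
       sites = data.frame(site = pm$probe_id, chrom = pm$chrom,
                          pos = pm$start, stringsAsFactors = FALSE),
       map = fit_genetic_map(sim$genetic_map))
}

# deterministic 4-accession x 12-marker toy (also shipped in extdata)
phs_toy <- function() {
  G <- rbind(
    Acc1 = c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L),
    Acc2 = c(0L, 0L, 1L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 1L, 0L),
    Acc3 = c(1L, 0L, 1L, 0L, 0L, 0L, 1L, 1L, 1L, 0L, 0L, 1L),
    Acc4 = c(1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L, 0L, 0L, 1L, 1L))
  colnames(G) <- sprintf("S%02d", 1:12)
  pos <- seq(0L, by = 1000L, length.out = 12L)
  sites <- data.frame(site = colnames(G), chrom = "Chr1", pos = pos,
                      stringsAsFactors = FALSE)
  markers <- data.frame(chrom = "Chr1", bp = pos, cm = pos * 4e-4)
  list(G = G, sites = sites, markers = markers,
       map = fit_genetic_map(markers, degree = 1),
       cm = pos * 4e-4)
}
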