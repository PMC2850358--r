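test_that("probe map tiles chromosomes deterministically", {
  cfg <- sim_config(seed = 4, n_chromosomes = 1, probes_per_chromosome = 100,
                    probe_spacing = 35)
  pm <- generate_probe_map(cfg)
  expect_equal(nrow(pm), 100)
  expect_equal(pm$start[100], 99 * 35)
  expect_true(all(pm$length == 25))
  expect_true(all(pm$gc >= 0 & pm$gc <= 1))
  expect_true(all(diff(pm$start) > 0))
  expect_identical(pm, generate_probe_map(cfg))
  expect_error(sim_config(probe_spacing = 0), "spacing")
})

test_that("admixture proportions are proper and degenerate cleanly", {
  cfg <- sim_config(seed = 4, n_accessions = 12, n_chromosomes = 1,
                    probes_per_chromosome = 120, n_populations = 4)
  pm <- generate_probe_map(cfg)
  pop <- generate_population(cfg, pm)
  expect_equal(ncol(pop$qmatrix), 4)
  expect_equal(rowSums(pop$qmatrix), rep(1, 12), tolerance = 1e-12,
               ignore_attr = TRUE)
  cfg1 <- sim_config(seed = 4, n_accessions = 6, n_chromosomes = 1,
                     probes_per_chromosome = 120, n_populations = 1)
  pop1 <- generate_population(cfg1, generate_probe_map(cfg1))
  expect_true(all(pop1$qmatrix == 1))
})

test_that("like-population accessions are geographically closer on average", {
  within <- between <- numeric()
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed, n_accessions = 16, n_chromosomes = 1,
                      probes_per_chromosome = 60)
    pop <- generate_population(cfg, generate_probe_map(cfg))
    d <- as.matrix(dist(cbind(pop$geo$lat, pop$geo$lon)))
    same <- outer(pop$primary_pop, pop$primary_pop, "==")
    diag(same) <- NA
    within <- c(within, mean(d[which(same)]))
    between <- c(between, mean(d[which(!same)]))
  }
  expect_lt(mean(within), mean(between))
})

test_that("planted variants are recorded faithfully", {
  cfg <- sim_config(seed = 7, n_accessions = 54, n_chromosomes = 1,
                    probes_per_chromosome = 400,
                    deletion_specs = list(list(accessions = 1L, chrom = 1L,
                                               start_probe = 50L,
                                               n_probes = 12L)),
                    duplication_specs = list(),
                    sweep_spec = list(chrom = 1L, start_probe = 200L,
                                      n_probes = 60L,
                                      carrier_fraction = 0.4))
  pm <- generate_probe_map(cfg)
  truth <- plant_variants(generate_population(cfg, pm), pm, cfg)
  expect_equal(truth$deletions$probe_from, 50L)
  expect_equal(truth$deletions$probe_to, 61L)
  # round-half-up carrier rule: 0.4 * 54 = 21.6 -> 22
  expect_equal(length(truth$sweep_carriers), 22L)
  idx <- truth$sweep_region[1]:truth$sweep_region[2]
  sub <- truth$genotypes[truth$sweep_carriers, idx]
  expect_true(all(apply(sub, 2, function(x) length(unique(x)) == 1)))
  # every truth SNP record points at an existing, polymorphic probe
  expect_true(all(truth$snp_detail$site %in% seq_len(nrow(pm))))
  expect_true(all(colSums(truth$genotypes)[truth$snp_detail$site] > 0))
})

test_that("overlapping deletion and duplication in one accession is rejected", {
  cfg <- sim_config(seed = 1, n_accessions = 6, n_chromosomes = 1,
                    probes_per_chromosome = 200,
                    deletion_specs = list(list(accessions = 2L, chrom = 1L,
                                               start_probe = 50L,
                                               n_probes = 20L)),
                    duplication_specs = list(list(accessions = 2L, chrom = 1L,
                                                  start_probe = 60L,
                                                  n_probes = 15L)))
  pm <- generate_probe_map(cfg)
  pop <- generate_population(cfg, pm)
  expect_error(plant_variants(pop, pm, cfg), "overlapping")
})

test_that("intensity model hits its noiseless expectations", {
  cfg <- sim_config(seed = 9, n_accessions = 6, n_chromosomes = 1,
                    probes_per_chromosome = 200, noise_sd = 0,
                    prop_unique = 1, dup_fold = 4,
                    duplication_specs = list(list(accessions = 1L, chrom = 1L,
                                                  start_probe = 150L,
                                                  n_probes = 12L)),
                    deletion_specs = list(list(accessions = 2L, chrom = 1L,
                                               start_probe = 100L,
                                               n_probes = 12L)),
                    sweep_spec = NULL)
  sim <- simulate_dataset(cfg)
  fc <- log2fc_matrix(sim$intensities)
  G <- sim$truth$genotypes
  # monomorphic, segment-free probes: log2FC exactly 0
  free <- which(colSums(G) == 0)
  free <- setdiff(free, 100:161)
  expect_equal(unname(fc[free, "Acc03"]), rep(0, length(free)))
  # deleted probes drop far below the SFP threshold
  expect_true(all(fc[100:111, "Acc02"] <= -1.5))
  # 4-fold duplication: log2FC exactly +2
  expect_equal(unname(fc[150:161, "Acc01"]), rep(2, 12))
})

test_that("centre-SNP polymorphic probes fall below -1.5 in >= 90% of cases", {
  sim <- tiny_sim()
  det <- sim$truth$snp_detail
  centre <- vapply(det$positions, function(p) any(abs(p - 13) <= 4),
                   logical(1))
  sites <- det$site[centre]
  fc <- log2fc_matrix(normalize_arrays(sim$intensities))
  G <- sim$truth$genotypes
  vals <- unlist(lapply(sites, function(s) fc[s, G[, s] == 1]))
  expect_gt(mean(vals <= -1.5), 0.9)
})

test_that("phenotypes follow the generative linear model", {
  # noiseless, single environment, no structure effect: group difference
  # equals the configured effect exactly
  cfg <- sim_config(seed = 5, n_accessions = 12, n_chromosomes = 1,
                    probes_per_chromosome = 200, n_experiments = 1,
                    trait_specs = list(list(name = "t", causal = 100L,
                                            effect = 1.7, noise_sd = 0,
                                            env_effect = 0, q_sd = 0)))
  sim <- simulate_dataset(cfg)
  g <- sim$truth$genotypes[, sim$truth$causal_markers$t]
  v <- sim$phenotypes$t[match(rownames(sim$truth$genotypes),
                              sim$phenotypes$accession)]
  expect_equal(mean(v[g == 1]) - mean(v[g == 0]), 1.7)

  # null trait: no correlation with its nominal marker
  r <- vapply(1:10, function(seed) {
    cfg <- sim_config(seed = seed, n_accessions = 54, n_chromosomes = 1,
                      probes_per_chromosome = 150,
                      trait_specs = list(list(name = "t", causal = 75L,
                                              effect = 0, noise_sd = 1,
                                              env_effect = 0, q_sd = 0)))
    sim <- simulate_dataset(cfg)
    g <- sim$truth$genotypes[, 75]
    if (length(unique(g)) < 2) return(0)
    v <- tapply(sim$phenotypes$t, sim$phenotypes$accession, mean)
    cor(v[rownames(sim$truth$genotypes)], g)
  }, numeric(1))
  expect_true(all(abs(r) < 0.3))

  # default config carries the nine study traits
  ph <- tiny_sim()$phenotypes
  expect_equal(setdiff(names(ph), c("accession", "experiment")),
               c("fresh_weight", "protein", "amino_acids", "sucrose",
                 "starch", "myo_inositol", "beta_alanine",
                 "threonic_acid", "erythritol"))
})

test_that("metabolic network is deterministic with currency compounds", {
  cfg <- sim_config(seed = 3, n_chromosomes = 1, probes_per_chromosome = 60)
  net <- generate_metabolic_network(cfg)
  expect_true(all(c("WATER", "ATP", "NADH") %in% net$currency))
  expect_identical(net, generate_metabolic_network(cfg))
  # a gene on reaction A -> B reaches B in one hop
  rx1 <- net$reactions[1, ]
  gene <- net$gene_map$gene[net$gene_map$reaction == rx1$reaction][1]
  prod <- setdiff(strsplit(rx1$products, ",")[[1]], net$currency)[1]
  expect_equal(min_metabolic_path(gene, prod, net), 1L)
})

test_that("simulated files round-trip losslessly", {
  sim <- cached_sim("roundtrip", function() {
    simulate_dataset(sim_config(seed = 21, n_accessions = 6,
                                n_chromosomes = 2,
                                probes_per_chromosome = 80))
  })
  out <- withr::local_tempdir()
  paths <- write_sim_data(sim, out)
  pm2 <- utils::read.delim(paths[["probe_map"]])
  expect_equal(pm2$start, sim$probes$start)
  g2 <- read_genotype_matrix(paths[["genotype_truth"]])
  expect_equal(unname(g2), unname(sim$truth$genotypes))
  im2 <- read_intensity_matrix(paths[["intensities"]])
  expect_equal(unname(im2$values), unname(sim$intensities$values),
               tolerance = 1e-8)
  expect_equal(im2$arrays$accession, sim$intensities$arrays$accession)
  ann2 <- read_annotation_gff3(paths[["annotation"]])
  expect_equal(ann2$start, sim$annotation$start)
  expect_equal(ann2$end, sim$annotation$end)
  expect_equal(ann2$class, sim$annotation$class)
  expect_equal(ann2$family, sim$annotation$family)
})
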