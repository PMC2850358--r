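test_that("genetic map fitting recovers exact linear maps and guards degree", {
  bp <- seq(0, 1e6, length.out = 20)
  markers <- data.frame(chrom = "Chr1", bp = bp, cm = bp * 4e-6)
  map <- fit_genetic_map(markers, degree = 1)
  expect_equal(map$Chr1$rmse, 0, tolerance = 1e-9)
  expect_equal(map_cm(map, "Chr1", 5e5), 2, tolerance = 1e-6)
  expect_error(fit_genetic_map(markers, degree = 0), "monoton")
  expect_error(fit_genetic_map(markers[1:3, ], degree = 3), "fit error")
  # monotone evaluation even for a noisy cubic fit
  set.seed(2)
  noisy <- data.frame(chrom = "Chr1", bp = bp,
                      cm = bp * 4e-6 + rnorm(20, 0, 0.3))
  m3 <- fit_genetic_map(noisy, degree = 3)
  ev <- map_cm(m3, "Chr1", seq(0, 1e6, length.out = 500))
  expect_true(all(diff(ev) >= -1e-12))
})

test_that("noisy cubic truth is recovered by a cubic fit", {
  slopes <- vapply(1:10, function(seed) {
    set.seed(seed)
    bp <- sort(runif(60, 0, 1e6))
    cm_true <- 2e-6 * bp + 3e-18 * bp^3
    markers <- data.frame(chrom = "Chr1", bp = bp,
                          cm = cm_true + rnorm(60, 0, 0.05))
    map <- fit_genetic_map(markers, degree = 3)
    pred <- map_cm(map, "Chr1", bp)
    sqrt(mean((pred - cm_true)^2))
  }, numeric(1))
  expect_lt(mean(slopes), 0.05)
})

test_that("sharing lengths follow the stated run convention", {
  toy <- list(
    G = rbind(A = c(0L, 0L, 0L, 0L), B = c(0L, 0L, 1L, 0L)),
    sites = data.frame(site = paste0("s", 1:4), chrom = "Chr1",
                       pos = c(0, 1000, 2000, 3000)),
    markers = data.frame(chrom = "Chr1", bp = c(0, 1000, 2000, 3000),
                         cm = c(0, 1, 2, 3)))
  colnames(toy$G) <- toy$sites$site
  map <- fit_genetic_map(toy$markers, degree = 1)
  # identity pattern (same, same, diff, same), x = marker 2:
  # run spans markers 1..2, stopped by the mismatch at marker 3
  expect_equal(sharing_length(toy$G, toy$sites, map, "A", "B", 2), 1)
  expect_equal(sharing_length(toy$G, toy$sites, map, "A", "B", 3), 0)
  expect_equal(sharing_length(toy$G, toy$sites, map, "A", "B", 4), 0)
  ident <- rbind(A = c(0L, 1L, 0L, 1L), B = c(0L, 1L, 0L, 1L))
  colnames(ident) <- toy$sites$site
  expect_equal(sharing_length(ident, toy$sites, map, "A", "B", 2), 3)
})

test_that("phs equals the brute-force enumeration oracle", {
  toy <- phs_toy()
  for (x in c(3L, 7L, 11L)) for (al in c(0L, 1L)) {
    want <- oracle_phs(toy$G, toy$cm, x, al)
    if (is.na(want)) next
    got <- phs(toy$G, toy$sites, toy$map, x, al)
    expect_equal(got$phs, want, tolerance = 1e-9,
                 info = paste("site", x, "allele", al))
  }
  # random small panels
  set.seed(8)
  for (rep in 1:4) {
    n <- sample(5:8, 1); m <- 20
    G <- matrix(rbinom(n * m, 1, 0.4), n, m,
                dimnames = list(paste0("a", 1:n), paste0("s", 1:m)))
    pos <- sort(sample(0:50000, m))
    sites <- data.frame(site = colnames(G), chrom = "Chr1", pos = pos)
    markers <- data.frame(chrom = "Chr1", bp = pos, cm = pos * 4e-5)
    map <- fit_genetic_map(markers, degree = 1)
    cm <- pos * 4e-5
    x <- sample(m, 1)
    for (al in 0:1) {
      if (sum(G[, x] == al) < 2) next
      want <- oracle_phs(G, cm, x, al)
      if (is.na(want)) next
      expect_equal(phs(G, sites, map, x, al)$phs, want, tolerance = 1e-6)
    }
  }
})

test_that("packaged toy fixture matches the in-code fixture", {
  gt <- read_genotype_matrix(system.file("extdata", "phs_toy_genotypes.tsv",
                                         package = "tilingsweep"))
  mk <- utils::read.delim(system.file("extdata", "phs_toy_markers.tsv",
                                      package = "tilingsweep"))
  toy <- phs_toy()
  expect_equal(unname(gt[rownames(toy$G), colnames(toy$G)]),
               unname(toy$G))
  expect_equal(mk$cm, toy$markers$cm)
})

test_that("standardisation centres on the class median with sample SD", {
  sc <- data.frame(site = sprintf("s%d", 1:5), chrom = "Chr1",
                   pos = 1:5 * 100, allele = 1L, carriers = 5L,
                   freq = 0.25, phs = c(1, 2, 3, 4, 5),
                   mean_share_cm = 1)
  st <- standardize_scores(sc, min_class = 1)
  expect_equal(st$standardized[3], 0)
  expect_equal(st$standardized[5], 2 / sd(1:5), tolerance = 1e-9)
  expect_equal(st$standardized[5], 1.265, tolerance = 1e-3)
  # location invariance
  sc2 <- sc; sc2$phs <- sc2$phs + 10
  expect_equal(standardize_scores(sc2, min_class = 1)$standardized,
               st$standardized)
  # zero-SD class collapses to 0 with a warning
  sc3 <- sc; sc3$phs <- 1
  expect_warning(st3 <- standardize_scores(sc3, min_class = 1), "zero SD")
  expect_equal(st3$standardized, rep(0, 5))
})

test_that("standardized scores have median 0 and SD 1 within classes", {
  set.seed(30)
  n <- 20; m <- 400
  G <- matrix(rbinom(n * m, 1, runif(m, 0.1, 0.9)), n, m, byrow = TRUE,
              dimnames = list(paste0("a", 1:n), paste0("s", 1:m)))
  pos <- sort(sample(0:(m * 40), m))
  sites <- data.frame(site = colnames(G), chrom = "Chr1", pos = pos)
  map <- fit_genetic_map(data.frame(chrom = "Chr1", bp = pos,
                                    cm = pos * 4e-5), degree = 1)
  gm <- maf_filter(G)
  sitesm <- sites[match(colnames(gm), sites$site), ]
  st <- standardize_scores(phs_scan(gm, sitesm, map))
  for (cl in unique(st$class_id)) {
    v <- st$standardized[st$class_id == cl]
    if (length(v) < 5) next
    expect_equal(median(v), 0, tolerance = 1e-9)
    expect_equal(sd(v), 1, tolerance = 0.2)
  }
})

test_that("LD pruning follows the r2 > 0.5, r > 0 rule and is idempotent", {
  g <- cbind(s1 = c(1, 1, 0, 0, 1, 0, 1, 0),
             s2 = c(1, 1, 0, 0, 1, 0, 1, 0),   # r = 1 with s1
             s3 = c(0, 0, 1, 1, 0, 1, 0, 1),   # r = -1 with s2
             s4 = c(1, 0, 1, 0, 1, 0, 1, 0))   # weak LD with s3
  rownames(g) <- paste0("a", 1:8)
  sc <- data.frame(site = colnames(g), chrom = "Chr1",
                   pos = c(100, 200, 300, 400), allele = 1L,
                   standardized = c(1.0, 2.0, 1.5, 0.5))
  pr <- ld_prune(sc, g)
  # s1 (lower scoring of the r=1 pair) removed; negative-r pair kept
  expect_setequal(pr$site, c("s2", "s3", "s4"))
  expect_equal(ld_prune(pr, g), pr)
  # r^2 below threshold: both kept
  g2 <- cbind(s1 = c(1, 1, 1, 0, 0, 0, 1, 0),
              s2 = c(1, 0, 1, 0, 1, 0, 0, 1))
  rownames(g2) <- paste0("a", 1:8)
  sc2 <- data.frame(site = c("s1", "s2"), chrom = "Chr1", pos = c(1, 2),
                    allele = 1L, standardized = c(1, 2))
  expect_equal(nrow(ld_prune(sc2, g2)), 2)
})

test_that("window scan applies the strict 45% rule and counts windows", {
  mk_scores <- function(n_out, n = 200) {
    # one chromosome, window of 100: outliers packed at the start
    data.frame(site = sprintf("s%03d", 1:n), chrom = "Chr1",
               pos = seq_len(n) * 100, allele = 1L,
               standardized = c(rep(10, n_out), seq(0, 1, length.out = n - n_out)))
  }
  # 46 outliers in the first window -> candidate; 45 -> not
  s46 <- mk_scores(46)
  r46 <- window_scan(s46, window = 100, offset = 5,
                     outlier_quantile = 46 / 200, min_proportion = 0.45)
  expect_gt(nrow(r46), 0)
  s45 <- mk_scores(45)
  r45 <- window_scan(s45, window = 100, offset = 5,
                     outlier_quantile = 45 / 200, min_proportion = 0.45)
  expect_equal(nrow(r45), 0)
  # window-count arithmetic: floor((3000 - 1000)/50) + 1 = 41
  big <- data.frame(site = sprintf("s%04d", 1:3000), chrom = "Chr1",
                    pos = seq_len(3000) * 35, allele = 1L,
                    standardized = rnorm(3000))
  r <- window_scan(big, window = 1000, offset = 50,
                   outlier_quantile = 0.005, min_proportion = 0.45)
  expect_equal(attr(r, "n_windows_total"), 41L)
  expect_equal(nrow(r), 0)     # 15 outliers can never fill 45% of 1000
  expect_error(window_scan(big[1:10, ], window = 100), "parameter")
})

test_that("focal SFP is the highest scorer inside the merged region", {
  sc <- data.frame(site = sprintf("s%03d", 1:200), chrom = "Chr1",
                   pos = seq_len(200) * 100, allele = rep(c(0L, 1L), 100),
                   standardized = c(rep(0, 40), rep(10, 70), 12, rep(10, 9),
                                    rep(0, 80)))
  r <- window_scan(sc, window = 100, offset = 5, outlier_quantile = 0.4,
                   min_proportion = 0.45)
  expect_equal(nrow(r), 1)
  expect_equal(r$focal_site, "s111")
  expect_equal(r$focal_pos, 11100)
  expect_true(r$from <= 4100 + 100 && r$to >= 12000)
})

test_that("average sharing interval spans the chromosome for clones", {
  G <- rbind(A = rep(1L, 10), B = rep(1L, 10), C = rep(0L, 10))
  colnames(G) <- paste0("s", 1:10)
  pos <- seq(0, 9000, by = 1000)
  sites <- data.frame(site = colnames(G), chrom = "Chr1", pos = pos)
  region <- data.frame(name = "SR1", chrom = "Chr1", from = 2000,
                       to = 7000, focal_site = "s5", focal_pos = 4000,
                       selected_allele = 1L)
  iv <- avg_sharing_interval(region, G, sites)
  expect_equal(iv$from, 0)
  expect_equal(iv$to, 9000)
  expect_equal(iv$length_bp, 9000)
  expect_equal(iv$n_pairs, 1)
})

test_that("geographic clustering flags co-located carriers, is seeded", {
  geo <- data.frame(accession = sprintf("a%02d", 1:20),
                    lat = c(rep(48, 5), runif(15, 35, 65)),
                    lon = c(rep(9, 5), runif(15, -5, 30)))
  r <- geographic_clustering(sprintf("a%02d", 1:5), geo,
                             n_shuffles = 200, seed = 42)
  expect_lt(r$p, 0.01)
  expect_equal(r$observed_mean_km, 0)
  r2 <- geographic_clustering(sprintf("a%02d", 1:5), geo,
                              n_shuffles = 200, seed = 42)
  expect_equal(r$p, r2$p)
  expect_warning(r1 <- geographic_clustering("a01", geo), "skipped")
  expect_true(is.na(r1$p))
})

test_that("geographic permutation p is roughly uniform under random labels", {
  set.seed(77)
  geo <- data.frame(accession = sprintf("a%02d", 1:24),
                    lat = runif(24, 35, 65), lon = runif(24, -5, 30))
  ps <- vapply(1:60, function(i) {
    geographic_clustering(sample(geo$accession, 8), geo,
                          n_shuffles = 60, seed = i)$p
  }, numeric(1))
  expect_gt(mean(ps <= 0.5), 0.3)
  expect_lt(mean(ps <= 0.5), 0.7)
  expect_lt(mean(ps <= 0.1), 0.3)
})

test_that("planted sweeps are detected and sweep-free genomes stay clean", {
  run1 <- function(seed, sweep) {
    cfg <- sim_config(seed = seed, n_accessions = 24, n_chromosomes = 2,
                      probes_per_chromosome = 1250,
                      recomb_block_probes = 20,
                      sweep_spec = if (sweep)
                        list(chrom = 1L, start_probe = 500L,
                             n_probes = 300L, carrier_fraction = 0.6)
                      else NULL)
    sim <- simulate_dataset(cfg)
    si <- sweep_inputs(sim)
    sc <- standardize_scores(phs_scan(si$g, si$sites, si$map))
    pruned <- ld_prune(site_best_scores(sc), si$g)
    reg <- window_scan(pruned, window = 100, offset = 5,
                       outlier_quantile = 0.08, min_proportion = 0.45)
    if (!sweep) return(nrow(reg) == 0)
    swb <- (sim$truth$sweep_region - 1) %% 1250 * 35
    nrow(reg) > 0 && any(reg$chrom == "Chr1" & reg$to >= swb[1] &
                           reg$from <= swb[2])
  }
  hits <- vapply(1:5, run1, logical(1), sweep = TRUE)
  expect_gte(sum(hits), 4)
  clean <- vapply(1:5, run1, logical(1), sweep = FALSE)
  expect_equal(sum(clean), 5)
})

test_that("sweep-trait association recovers a sweep-borne causal trait", {
  cfg <- sim_config(seed = 19, n_accessions = 24, n_chromosomes = 2,
                    probes_per_chromosome = 1250, recomb_block_probes = 20,
                    sweep_spec = list(chrom = 1L, start_probe = 500L,
                                      n_probes = 300L,
                                      carrier_fraction = 0.6),
                    trait_specs = list(list(name = "t1", causal = 650L,
                                            effect = 3.5, noise_sd = 1,
                                            env_effect = 0.5)))
  sim <- simulate_dataset(cfg)
  si <- sweep_inputs(sim)
  sc <- standardize_scores(phs_scan(si$g, si$sites, si$map))
  pruned <- ld_prune(site_best_scores(sc), si$g)
  reg <- window_scan(pruned, window = 100, offset = 5,
                     outlier_quantile = 0.08, min_proportion = 0.45)
  expect_gt(nrow(reg), 0)
  scan <- association_scan(si$g[, sample(colnames(si$g), 150)],
                           sim$phenotypes, sim$pop$qmatrix)
  sta <- sweep_trait_association(reg, si$g, sim$phenotypes,
                                 sim$pop$qmatrix, scan, si$sites)
  expect_equal(nrow(sta$focal), nrow(reg))
  expect_true(all(c("region", "trait", "fscore", "p_emp") %in%
                    names(sta$focal)))
  expect_true(!is.null(sta$shift))
})
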