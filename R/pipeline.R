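#' Pipeline stage parameters
#'
#' All analysis-stage defaults in one place: SFP threshold -1.5 log2
#' units, 10-probe segment runs, duplication gain threshold log2FC >= 2
#' (> 4-fold), MAF >= 5%, association threshold p = 1e-3, sweep windows
#' of 1000 SFPs at offset 50, top 0.5% outliers, > 45% window rule,
#' 10,000 geographic shuffles.
#'
#' @param sfp_threshold log2FC call threshold.
#' @param min_run minimum probes per deletion/duplication run.
#' @param dup_min_log2fc duplication log2FC threshold.
#' @param min_maf association/sweep MAF filter.
#' @param alpha association significance threshold (empirical p).
#' @param window,offset sweep-scan window size / step, SFPs.
#' @param outlier_quantile top fraction of standardized scores flagged.
#' @param min_proportion outlier proportion a candidate window must
#'   exceed.
#' @param n_shuffles geographic permutation count.
#' @param map_degree genetic-map polynomial degree.
#' @return named list of parameters.
#' @export
pipeline_params <- function(sfp_threshold = -1.5, min_run = 10L,
                            dup_min_log2fc = 2, min_maf = 0.05,
                            alpha = 1e-3, window = 1000L, offset = 50L,
                            outlier_quantile = 0.005,
                            min_proportion = 0.45,
                            n_shuffles = 10000L, map_degree = 3L) {
  as.list(environment())
}

#' Run the full pipeline
#'
#' Orchestrates simulate -> normalise/call SFPs -> call segments ->
#' feature/family enrichment -> GLM association -> PHS sweep scan, writes
#' every stage's table under `outdir` and returns a manifest. All
#' randomness derives from `config$seed`, so a rerun with the same config
#' reproduces identical outputs.
#'
#' @param config a [sim_config()].
#' @param outdir output directory.
#' @param params a [pipeline_params()] list.
#' @param stages subset of stages to run (dependency order enforced;
#'   later stages need earlier in-memory results, so a downstream stage
#'   without its upstream raises a dependency error).
#' @return A manifest list: `params`, `seed`, `stages` (per-stage row
#'   counts), `files`, `results` (in-memory stage outputs).
#' @export
run_pipeline <- function(config, outdir,
                         params = pipeline_params(),
                         stages = c("simulate", "call_sfp", "call_segments",
                                    "enrich", "associate", "sweep_scan",
                                    "report")) {
  all_stages <- c("simulate", "call_sfp", "call_segments", "enrich",
                  "associate", "sweep_scan", "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  manifest <- list(seed = config$seed, params = params,
                   stages = list(), files = character())
  need <- function(what, stage) {
    if (is.null(res[[what]])) {
      stop("dependency error: stage '", stage, "' needs output of '",
           what, "'", call. = FALSE)
    }
  }
  emit <- function(x, name) {
    path <- file.path(outdir, paste0(name, ".tsv"))
    write_tsv(x, path)
    manifest$files <<- c(manifest$files, path)
  }
  done <- function(stage, n) manifest$stages[[stage]] <<- list(rows = n)

  if ("simulate" %in% stages) {
    res$sim <- simulate_dataset(config)
    paths <- write_sim_data(res$sim, file.path(outdir, "sim"))
    manifest$files <- c(manifest$files, unname(paths))
    done("simulate", nrow(res$sim$probes))
  }
  if ("call_sfp" %in% stages) {
    need("sim", "call_sfp")
    norm <- normalize_arrays(res$sim$intensities)
    fc <- log2fc_matrix(norm)
    res$calls <- call_sfps(fc, res$sim$probes, params$sfp_threshold)
    res$log2fc <- fc
    g <- sfp_genotypes(res$calls)
    emit(cbind(site = colnames(g), as.data.frame(t(g))), "sfp_genotypes")
    cal <- calibrate_threshold(fc, res$sim$truth$genotypes, res$sim$probes)
    res$calibration <- cal
    emit(as.data.frame(cal), "calibration")
    done("call_sfp", sum(res$calls$called))
  }
  if ("call_segments" %in% stages) {
    need("calls", "call_segments")
    dels <- call_deletions(res$calls, min_run = params$min_run)
    dups <- call_duplications(res$log2fc, res$sim$probes,
                              min_run = params$min_run,
                              min_log2fc = params$dup_min_log2fc)
    res$segments <- rbind(dels, dups)
    res$segment_summary <- summarize_segments(res$segments)
    emit(res$segments, "segments")
    done("call_segments", nrow(res$segments))
  }
  if ("enrich" %in% stages) {
    need("calls", "enrich")
    sites <- sfp_site_table(res$calls)
    genome_bp <- sum(chromosome_lengths(res$sim$probes))
    res$enrichment <- feature_enrichment_table(sites, res$sim$annotation,
                                               genome_bp)
    res$family_report <- gene_family_report(sites, res$segments %||%
                                              data.frame(),
                                            res$sim$annotation, genome_bp)
    emit(res$enrichment, "enrichment")
    emit(res$family_report, "family_report")
    done("enrich", nrow(res$enrichment))
  }
  if ("associate" %in% stages) {
    need("calls", "associate")
    g <- maf_filter(sfp_genotypes(res$calls), params$min_maf)
    res$assoc_genotypes <- g
    res$scan <- association_scan(g, res$sim$phenotypes,
                                 res$sim$pop$qmatrix)
    n_sig <- sum(res$scan$p_emp <= params$alpha)
    res$fdr_percent <- if (n_sig > 0) {
      estimate_fdr(ncol(g), length(unique(res$scan$trait)), params$alpha,
                   n_sig)
    } else NA_real_
    emit(res$scan, "associations")
    done("associate", nrow(res$scan))
  }
  if ("sweep_scan" %in% stages) {
    need("calls", "sweep_scan")
    g <- res$assoc_genotypes %||%
      maf_filter(sfp_genotypes(res$calls), params$min_maf)
    sites <- sfp_site_table(res$calls)
    sites <- sites[match(colnames(g), sites$site), ]
    gmap <- fit_genetic_map(res$sim$genetic_map, degree = params$map_degree)
    sc <- phs_scan(g, sites, gmap)
    sc <- standardize_scores(sc)
    best <- site_best_scores(sc)
    pruned <- ld_prune(best, g)
    res$phs_scores <- pruned
    regions <- window_scan(pruned, params$window, params$offset,
                           params$outlier_quantile, params$min_proportion)
    if (nrow(regions)) {
      ints <- lapply(seq_len(nrow(regions)), function(r) {
        avg_sharing_interval(regions[r, ], g, sites)
      })
      regions$share_from <- vapply(ints, `[[`, numeric(1), "from")
      regions$share_to <- vapply(ints, `[[`, numeric(1), "to")
      regions$share_length <- vapply(ints, `[[`, numeric(1), "length_bp")
      regions$geo_p <- vapply(seq_len(nrow(regions)), function(r) {
        carr <- rownames(g)[g[, regions$focal_site[r]] ==
                              regions$selected_allele[r]]
        geographic_clustering(carr, res$sim$pop$geo,
                              n_shuffles = params$n_shuffles,
                              seed = stage_seed(config$seed, "geography"))$p
      }, numeric(1))
    }
    res$regions <- regions
    emit(pruned, "phs_scores")
    emit(regions, "sweep_regions")
    if (nrow(regions) && !is.null(res$scan)) {
      res$sweep_assoc <- sweep_trait_association(regions, g,
        res$sim$phenotypes, res$sim$pop$qmatrix, res$scan, sites)
      emit(res$sweep_assoc$focal, "sweep_associations")
    }
    done("sweep_scan", nrow(regions))
  }
  if ("report" %in% stages) {
    need("sim", "report")
    txt <- summary_report(manifest, res)
    path <- file.path(outdir, "report.txt")
    writeLines(txt, path)
    manifest$files <- c(manifest$files, path)
    done("report", length(txt))
  }
  manifest$results <- res
  jsonlite::write_json(
    list(seed = config$seed, params = params,
         stages = manifest$stages,
         files = basename(manifest$files)),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Site table (chrom/pos) of the unique probes in a call set
#' @param calls an `sfp_call_set`.
#' @return data.frame `site`, `chrom`, `pos` (probe start, 0-based).
#' @export
sfp_site_table <- function(calls) {
  p <- calls$probes[calls$probes$unique, , drop = FALSE]
  data.frame(site = p$probe_id, chrom = p$chrom, pos = p$start,
             stringsAsFactors = FALSE)
}

#' Human-readable pipeline report
#'
#' Tables mirroring the analysis's reporting shapes: SFP counts per
#' accession, segment counts, enrichment rows, association counts per
#' trait with the expected-random FDR estimate, and the sweep-region
#' table (name, chromosome, focal position, from, to, length of average
#' haplotype sharing). Regeneration from the same results is idempotent.
#'
#' @param manifest manifest from [run_pipeline()].
#' @param res the pipeline's `results` list.
#' @return character vector of report lines.
#' @export
summary_report <- function(manifest, res) {
  out <- c("tilingsweep pipeline report",
           paste0("seed: ", manifest$seed), "")
  fmt <- function(df) c(paste(names(df), collapse = "\t"),
                        apply(df, 1, paste, collapse = "\t"))
  if (!is.null(res$calls)) {
    n_per_acc <- colSums(res$calls$called)
    out <- c(out, "== SFPs per accession ==",
             fmt(data.frame(accession = names(n_per_acc), sfps = n_per_acc)),
             "")
  }
  if (!is.null(res$segment_summary)) {
    out <- c(out, "== Segments ==", fmt(res$segment_summary$overall), "")
  }
  if (!is.null(res$enrichment)) {
    out <- c(out, "== Feature enrichment ==",
             fmt(res$enrichment[, c("class", "observed", "expected",
                                    "statistic", "p", "direction")]), "")
  }
  if (!is.null(res$scan)) {
    alpha <- manifest$params$alpha
    sig <- res$scan[res$scan$p_emp <= alpha, , drop = FALSE]
    counts <- table(factor(sig$trait, levels = unique(res$scan$trait)))
    out <- c(out, "== Associations ==",
             fmt(data.frame(trait = names(counts),
                            significant = as.integer(counts))),
             if (nrow(sig) == 0) "0 significant associations" else
               paste0(nrow(sig), " significant associations at p <= ",
                      alpha),
             if (!is.null(res$fdr_percent) && !is.na(res$fdr_percent))
               sprintf("estimated FDR: %.1f%%", res$fdr_percent), "")
  }
  if (!is.null(res$regions)) {
    if (nrow(res$regions)) {
      tab <- data.frame(name = res$regions$name, chr = res$regions$chrom,
                        `focal position` = res$regions$focal_pos,
                        from = res$regions$from, to = res$regions$to,
                        `length of avg haplotype sharing` =
                          round(res$regions$share_length),
                        check.names = FALSE)
      out <- c(out, "== Sweep regions ==", fmt(tab), "")
    } else {
      out <- c(out, "== Sweep regions ==", "0 sweep candidates", "")
    }
  }
  out
}
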