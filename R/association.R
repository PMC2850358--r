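#' Minor allele frequency filter
#'
#' Removes sites whose minor allele frequency (frequency of the rarer
#' allele at a biallelic 0/1 site) falls below `min_maf`; monomorphic
#' sites are always removed when `min_maf > 0`.
#'
#' @param genotypes accession x site 0/1 matrix.
#' @param min_maf minimum MAF in `[0, 0.5]`.
#' @return the filtered genotype matrix (columns dropped).
#' @export
maf_filter <- function(genotypes, min_maf = 0.05) {
  stopifnot(min_maf >= 0, min_maf <= 0.5)
  f <- colMeans(genotypes)
  maf <- pmin(f, 1 - f)
  keep <- maf >= min_maf & maf > 0
  genotypes[, keep, drop = FALSE]
}

#' Minor allele frequencies of a genotype matrix
#' @param genotypes accession x site 0/1 matrix.
#' @return numeric vector of per-site MAF.
#' @export
site_maf <- function(genotypes) {
  f <- colMeans(genotypes)
  pmin(f, 1 - f)
}

#' Fit the marker-trait general linear model
#'
#' Ordinary least squares of `trait ~ marker + environment + Q`, where Q
#' holds admixture proportions as population-structure covariates (the
#' last Q column is dropped because rows sum to one). The marker F-score
#' is the partial F comparing the full model against the model without
#' the marker term. Least-squares means for the two genotype classes are
#' model-adjusted means: predictions at marker 0/1 with the environment
#' factor balanced and Q fixed at its sample means.
#'
#' @param trait numeric response, one value per record.
#' @param marker 0/1 genotype per record (accession-expanded).
#' @param q optional accession-expanded Q matrix (records x populations).
#' @param env optional factor of experiment/environment per record.
#' @return A `glm_fit` list: `fscore`, `p_param` (parametric p),
#'   `lsmeans` (named: ref, sfp), `effect` (sfp - ref), `df_residual`,
#'   `model` (the full [stats::lm] fit).
#' @export
fit_glm <- function(trait, marker, q = NULL, env = NULL) {
  d <- data.frame(v = trait, M = marker)
  rhs <- "M"
  if (!is.null(env) && length(unique(env)) > 1) {
    d$Env <- factor(env)
    rhs <- c(rhs, "Env")
  }
  if (!is.null(q)) {
    q <- as.matrix(q)
    qq <- q[, -ncol(q), drop = FALSE]          # rows sum to 1: drop last
    colnames(qq) <- paste0("Q", seq_len(ncol(qq)))
    d <- cbind(d, qq)
    rhs <- c(rhs, colnames(qq))
  }
  if (length(unique(marker)) < 2) {
    stop("singular design: marker is constant", call. = FALSE)
  }
  full <- stats::lm(stats::reformulate(rhs, response = "v"), data = d)
  if (any(is.na(stats::coef(full)))) {
    stop("singular design: collinear columns ",
         paste(names(stats::coef(full))[is.na(stats::coef(full))],
               collapse = ", "), call. = FALSE)
  }
  rhs_red <- setdiff(rhs, "M")
  red_formula <- if (length(rhs_red)) {
    stats::reformulate(rhs_red, response = "v")
  } else v ~ 1
  red <- stats::lm(red_formula, data = d)
  an <- stats::anova(red, full)
  fscore <- an$F[2]
  p_param <- an$`Pr(>F)`[2]

  # lsmeans: balanced environment, Q at sample means
  grid <- d[c(1, 1), , drop = FALSE]
  grid$M <- c(0, 1)
  for (nm in setdiff(names(d), c("v", "M", "Env"))) grid[[nm]] <- mean(d[[nm]])
  if ("Env" %in% names(d)) {
    lv <- levels(d$Env)
    preds <- vapply(lv, function(e) {
      g <- grid; g$Env <- factor(e, levels = lv)
      stats::predict(full, newdata = g)
    }, numeric(2))
    ls <- rowMeans(preds)
  } else {
    ls <- stats::predict(full, newdata = grid)
  }
  names(ls) <- c("ref", "sfp")
  structure(list(fscore = fscore, p_param = p_param, lsmeans = ls,
                 effect = unname(ls["sfp"] - ls["ref"]),
                 df_residual = stats::df.residual(full), model = full),
            class = "glm_fit")
}

#' Genome scan: fit the GLM at every site for every trait
#'
#' Expands per-accession genotypes and Q rows to the phenotype records and
#' fits [fit_glm()] per (site, trait). Empirical p-values are then
#' computed by [empirical_pvalues()] pooling all F-scores of the scan.
#'
#' @param genotypes accession x site 0/1 matrix (MAF-filtered).
#' @param phenotypes data.frame `accession`, `experiment`, trait columns.
#' @param qmatrix accession x population matrix (rownames = accessions).
#' @param traits trait columns to scan (default: all).
#' @param pool "all" pools the empirical distribution across traits and
#'   sites (default), "per_trait" pools within trait.
#' @return data.frame: `site`, `trait`, `fscore`, `p_emp`, `lsmean_ref`,
#'   `lsmean_sfp`, `effect`.
#' @export
association_scan <- function(genotypes, phenotypes, qmatrix = NULL,
                             traits = NULL, pool = c("all", "per_trait")) {
  pool <- match.arg(pool)
  traits <- traits %||% setdiff(names(phenotypes), c("accession", "experiment"))
  idx <- match(phenotypes$accession, rownames(genotypes))
  if (any(is.na(idx))) stop("phenotype accession missing from genotypes",
                            call. = FALSE)
  qx <- if (!is.null(qmatrix)) qmatrix[idx, , drop = FALSE]
  env <- phenotypes$experiment
  rows <- list()
  for (tr in traits) {
    v <- phenotypes[[tr]]
    for (s in colnames(genotypes)) {
      m <- genotypes[idx, s]
      fit <- fit_glm(v, m, q = qx, env = env)
      rows[[length(rows) + 1L]] <- data.frame(
        site = s, trait = tr, fscore = fit$fscore,
        lsmean_ref = fit$lsmeans[["ref"]], lsmean_sfp = fit$lsmeans[["sfp"]],
        effect = fit$effect, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (pool == "all") {
    out$p_emp <- empirical_pvalues(out$fscore)
  } else {
    out$p_emp <- stats::ave(out$fscore, out$trait, FUN = empirical_pvalues)
  }
  rownames(out) <- NULL
  out
}

#' Empirical p-values from a pooled F-score distribution
#'
#' The scan's own F-scores form the empirical null: the p-value of a
#' score is the fraction of all scores at least as large.
#'
#' @param fscores numeric vector of F-scores.
#' @return numeric vector of empirical p-values in `(0, 1]`.
#' @export
empirical_pvalues <- function(fscores) {
  if (!length(fscores)) stop("need at least one score", call. = FALSE)
  n <- length(fscores)
  # count of scores >= each score via descending rank
  (n + 1 - rank(fscores, ties.method = "min")) / n
}

#' Expected-random FDR estimate for a significance threshold
#'
#' With `n_sites x n_traits` tests at level `alpha`, the expected number
#' of random associations is `n_sites * n_traits * alpha`; the FDR
#' estimate is that expectation as a percentage of the observed
#' significant count, capped at 100.
#'
#' @param n_sites number of tested sites.
#' @param n_traits number of traits.
#' @param alpha significance threshold on the empirical p.
#' @param n_significant number of associations observed at `alpha`.
#' @return FDR estimate in percent.
#' @export
#' @examples
#' estimate_fdr(612249, 9, 1e-3, 12189)  # ~45
estimate_fdr <- function(n_sites, n_traits, alpha, n_significant) {
  if (n_significant <= 0) stop("n_significant must be > 0", call. = FALSE)
  expected <- n_sites * n_traits * alpha
  fdr <- 100 * expected / n_significant
  if (fdr > 100) {
    warning("expected random count exceeds observed; FDR capped at 100%")
    fdr <- 100
  }
  fdr
}

#' Pathway over-representation among association scores
#'
#' For each tested pathway, a one-sided Mann-Whitney U test compares the
#' F-scores of SFPs in the pathway's genes against the F-scores of SFPs
#' in all remaining metabolic genes (alternative: pathway scores larger).
#' P-values are Benjamini-Hochberg adjusted across the tested pathways.
#'
#' @param fits association data.frame with `site`, `fscore` (one trait).
#' @param site_genes named character: metabolic gene id per site (NA =
#'   not metabolic); names are site ids.
#' @param network a `metabolic_network` (supplies gene -> pathway).
#' @param tested_pathways pathway ids to test (a curated short list keeps
#'   the multiple-testing burden low).
#' @param alpha significance level on the adjusted p.
#' @return data.frame: `pathway`, `n_in`, `n_out`, `U`, `auc`, `p`,
#'   `p_adj`, `significant`.
#' @export
pathway_overrepresentation <- function(fits, site_genes, network,
                                       tested_pathways, alpha = 0.01) {
  gene_pwy <- unique(network$gene_map[, c("gene", "pathway")])
  g <- site_genes[fits$site]
  metab <- !is.na(g)
  rows <- lapply(tested_pathways, function(pw) {
    genes_in <- gene_pwy$gene[gene_pwy$pathway == pw]
    inset <- metab & g %in% genes_in
    outset <- metab & !(g %in% genes_in)
    if (!any(inset) || !any(outset)) {
      warning("pathway ", pw, ": empty comparison group, skipped")
      return(NULL)
    }
    ht <- stats::wilcox.test(fits$fscore[inset], fits$fscore[outset],
                             alternative = "greater", exact = FALSE)
    data.frame(pathway = pw, n_in = sum(inset), n_out = sum(outset),
               U = unname(ht$statistic),
               auc = unname(ht$statistic) / (sum(inset) * sum(outset)),
               p = ht$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj <= alpha
  out
}

#' Score shift of a gene set against its complement
#'
#' Two-sided Mann-Whitney U test of the F-scores of SFPs inside a gene
#' set (e.g. all metabolic genes) against the remaining SFPs.
#'
#' @param fits association data.frame with `site`, `fscore`.
#' @param in_set logical per row of `fits`.
#' @return list with `U`, `p`, `n_in`, `n_out`.
#' @export
geneset_score_shift <- function(fits, in_set) {
  if (!any(in_set) || all(in_set)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ht <- stats::wilcox.test(fits$fscore[in_set], fits$fscore[!in_set],
                           exact = FALSE)
  p <- ht$p.value
  if (is.nan(p)) p <- 1          # complete ties carry no evidence
  list(U = unname(ht$statistic), p = p,
       n_in = sum(in_set), n_out = sum(!in_set))
}

#' Minimum metabolic path from a gene to a metabolite
#'
#' Breadth-first search on the undirected bipartite reaction-compound
#' graph, starting from the gene's annotated reactions, with currency
#' compounds (water, ATP, NADH, ...) removed as traversal nodes so they
#' cannot act as shortcuts. The distance is the number of reactions on
#' the shortest chain: a gene whose reaction produces (or consumes) the
#' metabolite is at distance 1.
#'
#' @param gene gene id annotated in the network.
#' @param metabolite compound id.
#' @param network a `metabolic_network`.
#' @return integer hop count, or `Inf` when the metabolite is unreachable
#'   without traversing currency compounds.
#' @export
min_metabolic_path <- function(gene, metabolite, network) {
  rxns <- network$gene_map$reaction[network$gene_map$gene == gene]
  if (!length(rxns)) stop("unknown gene: ", gene, call. = FALSE)
  if (!(metabolite %in% c(network$compounds, network$currency))) {
    stop("unknown metabolite: ", metabolite, call. = FALSE)
  }
  if (metabolite %in% network$currency) return(Inf)
  g <- network_graph(network, drop_currency = TRUE)
  vs <- igraph::V(g)$name
  rxns <- intersect(rxns, vs)
  if (!length(rxns) || !(metabolite %in% vs)) return(Inf)
  d <- igraph::distances(g, v = rxns, to = metabolite)
  edge_d <- min(d)
  if (!is.finite(edge_d)) return(Inf)
  # reaction-compound alternation: edges 2k-1 from a reaction to a
  # compound correspond to k reactions on the chain
  as.integer((edge_d + 1) / 2)
}

#' Correlation of association signal with metabolic-gene density
#'
#' Splits each chromosome into fixed-width windows, sums F-scores of
#' sites in each window and the bp covered by metabolic genes, and
#' reports the per-chromosome Spearman correlation of the two window
#' profiles.
#'
#' @param fits association data.frame with `site`, `fscore` (summed over
#'   traits upstream if desired).
#' @param site_pos data.frame `site`, `chrom`, `pos`.
#' @param annotation feature annotation (`metabolic_gene` column flags
#'   metabolic genes).
#' @param window window width, bp.
#' @return data.frame `chrom`, `n_windows`, `rho`, `p` (NA when a profile
#'   is constant).
#' @export
density_fscore_correlation <- function(fits, site_pos, annotation, window) {
  d <- merge(fits, site_pos, by = "site")
  met <- annotation[!is.na(annotation$metabolic_gene), , drop = FALSE]
  out <- lapply(split(d, d$chrom), function(dc) {
    ch <- dc$chrom[1]
    brk <- seq(0, max(dc$pos) + window, by = window)
    if (length(brk) < 4) stop("need >= 3 windows per chromosome", call. = FALSE)
    wf <- tapply(dc$fscore, cut(dc$pos, brk, right = FALSE), sum,
                 default = 0)
    mg <- GenomicRanges::reduce(GenomicRanges::GRanges(met$chrom[met$chrom == ch],
            IRanges::IRanges(met$start[met$chrom == ch] + 1L,
                             met$end[met$chrom == ch])))
    dens <- vapply(seq_len(length(brk) - 1L), function(i) {
      win <- GenomicRanges::GRanges(ch, IRanges::IRanges(brk[i] + 1L, brk[i + 1]))
      sum(GenomicRanges::width(suppressWarnings(
        GenomicRanges::intersect(mg, win))))
    }, numeric(1))
    if (stats::sd(wf) == 0 || stats::sd(dens) == 0) {
      return(data.frame(chrom = ch, n_windows = length(dens),
                        rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(as.numeric(wf), dens,
                                           method = "spearman"))
    data.frame(chrom = ch, n_windows = length(dens),
               rho = unname(ct$estimate), p = ct$p.value)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
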