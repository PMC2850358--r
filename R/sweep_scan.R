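#' LD-prune PHS scores
#'
#' Nearby SFPs in strong positive linkage disequilibrium carry redundant
#' haplotype-sharing signal. Among each pair of neighbouring retained
#' sites (adjacent in position order on a chromosome) with `r^2 > r2_max`
#' and `r > 0`, the lower-scoring site is removed; the rule is applied
#' iteratively until no such neighbouring pair remains, which makes the
#' operation idempotent.
#'
#' @param scores per-site scores from [site_best_scores()] (columns
#'   `site`, `chrom`, `pos`, `standardized`).
#' @param genotypes accession x site 0/1 matrix.
#' @param r2_max r-squared threshold (strict inequality).
#' @return the retained rows of `scores`.
#' @export
ld_prune <- function(scores, genotypes, r2_max = 0.5) {
  keep <- split(seq_len(nrow(scores)), scores$chrom)
  out <- unlist(lapply(keep, function(ix) {
    ix <- ix[order(scores$pos[ix])]
    repeat {
      if (length(ix) < 2) break
      g <- genotypes[, scores$site[ix], drop = FALSE]
      drop_i <- integer()
      for (k in seq_len(length(ix) - 1L)) {
        r <- suppressWarnings(stats::cor(g[, k], g[, k + 1L]))
        if (is.na(r)) next
        if (r > 0 && r^2 > r2_max) {
          lower <- if (scores$standardized[ix[k]] <=
                       scores$standardized[ix[k + 1L]]) k else k + 1L
          drop_i <- c(drop_i, lower)
          break              # re-evaluate neighbours after each removal
        }
      }
      if (!length(drop_i)) break
      ix <- ix[-drop_i]
    }
    ix
  }), use.names = FALSE)
  res <- scores[sort(out), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Sliding-window sweep-candidate scan
#'
#' Flags the top `outlier_quantile` of standardized scores genome-wide as
#' outliers, slides a window of `window` SFPs with an `offset`-SFP step
#' along each chromosome, and marks windows whose outlier proportion is
#' strictly greater than `min_proportion` as sweep candidates.
#' Overlapping candidate windows merge into one region whose bounds are
#' the first and last SFP of the merged windows; the focal SFP is the
#' highest-scoring SFP in the region.
#'
#' @param scores pruned per-site scores (`site`, `chrom`, `pos`,
#'   `allele`, `standardized`), position-sorted within chromosome.
#' @param window window size, SFPs.
#' @param offset step between window starts, SFPs.
#' @param outlier_quantile upper tail defining outliers (0.005 = top
#'   0.5%).
#' @param min_proportion candidate rule: outlier proportion must exceed
#'   this (strictly).
#' @return data.frame of regions: `name`, `chrom`, `from`, `to` (bp),
#'   `focal_site`, `focal_pos`, `selected_allele`, `n_sfps`,
#'   `n_windows`; the total number of windows examined is attached as
#'   attribute `n_windows_total`.
#' @export
window_scan <- function(scores, window = 1000L, offset = 50L,
                        outlier_quantile = 0.005, min_proportion = 0.45) {
  if (window > nrow(scores)) {
    stop("parameter error: window exceeds number of SFPs", call. = FALSE)
  }
  cut <- stats::quantile(scores$standardized, 1 - outlier_quantile,
                         names = FALSE)
  outlier <- scores$standardized >= cut
  n_windows_total <- 0L
  regions <- list()
  for (ch in unique(scores$chrom)) {
    ix <- which(scores$chrom == ch)
    ix <- ix[order(scores$pos[ix])]
    nc <- length(ix)
    if (nc < window) next
    starts <- seq(1L, nc - window + 1L, by = offset)
    n_windows_total <- n_windows_total + length(starts)
    prop <- vapply(starts, function(s) {
      mean(outlier[ix[s:(s + window - 1L)]])
    }, numeric(1))
    cand <- prop > min_proportion
    if (!any(cand)) next
    # merge overlapping candidate windows (index intervals)
    iv <- cbind(starts[cand], starts[cand] + window - 1L)
    merged <- list(iv[1, ])
    for (r in seq_len(nrow(iv))[-1]) {
      last <- merged[[length(merged)]]
      if (iv[r, 1] <= last[2] + 1L) {
        merged[[length(merged)]] <- c(last[1], max(last[2], iv[r, 2]))
      } else merged[[length(merged) + 1L]] <- iv[r, ]
    }
    for (mr in merged) {
      rix <- ix[mr[1]:mr[2]]
      focal <- rix[which.max(scores$standardized[rix])]
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch, from = min(scores$pos[rix]), to = max(scores$pos[rix]),
        focal_site = scores$site[focal], focal_pos = scores$pos[focal],
        selected_allele = scores$allele[focal],
        n_sfps = length(rix),
        n_windows = sum(iv[, 1] >= mr[1] & iv[, 2] <= mr[2]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(regions)) {
    out <- data.frame(name = character(), chrom = character(),
                      from = numeric(), to = numeric(),
                      focal_site = character(), focal_pos = numeric(),
                      selected_allele = integer(), n_sfps = integer(),
                      n_windows = integer(), stringsAsFactors = FALSE)
    attr(out, "n_windows_total") <- n_windows_total
    return(out)
  }
  out <- do.call(rbind, regions)
  out <- cbind(name = paste0("SR", seq_len(nrow(out))), out)
  out$name <- as.character(out$name)
  attr(out, "n_windows_total") <- n_windows_total
  out
}

#' Average haplotype-sharing interval around a focal SFP
#'
#' Over all pairs of carriers of the selected allele at the focal SFP,
#' the shared run of identical markers through the focal site is
#' converted back to physical coordinates; the reported interval is the
#' mean left bound to the mean right bound, and the length their
#' difference.
#'
#' @param region one row of the [window_scan()] output.
#' @param genotypes accession x site matrix.
#' @param sites site table aligned with genotype columns.
#' @return list `from`, `to`, `length_bp`, `n_pairs`.
#' @export
avg_sharing_interval <- function(region, genotypes, sites) {
  x <- match(region$focal_site, colnames(genotypes))
  ch <- sites$chrom[x]
  idx <- which(sites$chrom == ch)
  t <- match(x, idx)
  carriers <- which(genotypes[, x] == region$selected_allele)
  if (length(carriers) < 2) stop("fewer than 2 carriers", call. = FALSE)
  pos <- sites$pos[idx]
  lefts <- rights <- numeric(0)
  for (a in seq_along(carriers)[-length(carriers)]) {
    for (b in seq.int(a + 1L, length(carriers))) {
      bds <- pair_share_bounds(genotypes[carriers[a], idx],
                               genotypes[carriers[b], idx])
      if (bds$discord[t]) next
      lefts <- c(lefts, pos[bds$lb[t]])
      rights <- c(rights, pos[bds$rb[t]])
    }
  }
  from <- mean(lefts); to <- mean(rights)
  list(from = from, to = to, length_bp = to - from,
       n_pairs = length(lefts))
}

#' Geographic clustering of sweep-allele carriers
#'
#' Tests whether carriers of the selected allele are geographic
#' neighbours: observed great-circle (haversine) pairwise distances among
#' carriers are compared against the pooled distances of `n_shuffles`
#' random reassignments of the carrier labels across accessions, with a
#' one-sided Mann-Whitney U test (alternative: observed distances
#' smaller).
#'
#' @param carriers accession ids carrying the selected allele.
#' @param geo data.frame `accession`, `lat`, `lon`.
#' @param n_shuffles number of label permutations.
#' @param seed integer seed (deterministic result).
#' @return list `p`, `U`, `observed_mean_km`, `null_mean_km`,
#'   `n_carriers`.
#' @export
geographic_clustering <- function(carriers, geo, n_shuffles = 10000L,
                                  seed = 1L) {
  carriers <- intersect(carriers, geo$accession)
  k <- length(carriers)
  if (k < 2) {
    warning("fewer than 2 carriers; test skipped")
    return(list(p = NA_real_, U = NA_real_, observed_mean_km = NA_real_,
                null_mean_km = NA_real_, n_carriers = k))
  }
  coords <- as.matrix(geo[, c("lon", "lat")])
  rownames(coords) <- geo$accession
  pdist <- function(ids) {
    d <- geosphere::distm(coords[ids, , drop = FALSE],
                          fun = geosphere::distHaversine) / 1000
    d[upper.tri(d)]
  }
  obs <- pdist(carriers)
  set.seed(seed)
  null <- unlist(lapply(seq_len(n_shuffles), function(i) {
    pdist(sample(geo$accession, k))
  }))
  ht <- stats::wilcox.test(obs, null, alternative = "less", exact = FALSE)
  list(p = ht$p.value, U = unname(ht$statistic),
       observed_mean_km = mean(obs), null_mean_km = mean(null),
       n_carriers = k)
}

#' Sweep-trait association
#'
#' Refits the association GLM at the focal SFP of every sweep region for
#' every trait, with empirical p-values taken from the genome scan's
#' pooled F distribution when supplied. Additionally tests, per trait,
#' whether F-scores of markers inside sweep regions run higher than those
#' outside (one-sided Mann-Whitney U).
#'
#' @param regions [window_scan()] output.
#' @param genotypes accession x site matrix.
#' @param phenotypes phenotype records (`accession`, `experiment`,
#'   traits).
#' @param qmatrix accession x population matrix.
#' @param scan optional full [association_scan()] result used for the
#'   empirical null and the inside/outside comparison.
#' @param sites site table (needed for inside/outside classification).
#' @return list `focal` (data.frame region x trait) and `shift`
#'   (data.frame per trait, or NULL without `scan`).
#' @export
sweep_trait_association <- function(regions, genotypes, phenotypes,
                                    qmatrix = NULL, scan = NULL,
                                    sites = NULL) {
  traits <- setdiff(names(phenotypes), c("accession", "experiment"))
  idx <- match(phenotypes$accession, rownames(genotypes))
  qx <- if (!is.null(qmatrix)) qmatrix[idx, , drop = FALSE]
  rows <- list()
  for (r in seq_len(nrow(regions))) {
    s <- regions$focal_site[r]
    for (tr in traits) {
      fit <- fit_glm(phenotypes[[tr]], genotypes[idx, s], q = qx,
                     env = phenotypes$experiment)
      p_emp <- if (!is.null(scan)) {
        (sum(scan$fscore >= fit$fscore) + 1) / (length(scan$fscore) + 1)
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        region = regions$name[r], trait = tr, site = s,
        fscore = fit$fscore, p_emp = p_emp,
        lsmean_ref = fit$lsmeans[["ref"]],
        lsmean_sfp = fit$lsmeans[["sfp"]], stringsAsFactors = FALSE)
    }
  }
  focal <- do.call(rbind, rows)

  shift <- NULL
  if (!is.null(scan) && !is.null(sites) && nrow(regions)) {
    inside_site <- unique(unlist(lapply(seq_len(nrow(regions)), function(r) {
      sites$site[sites$chrom == regions$chrom[r] &
                 sites$pos >= regions$from[r] & sites$pos <= regions$to[r]]
    })))
    shift <- do.call(rbind, lapply(split(scan, scan$trait), function(d) {
      ins <- d$site %in% inside_site
      if (!any(ins) || all(ins)) return(NULL)
      ht <- stats::wilcox.test(d$fscore[ins], d$fscore[!ins],
                               alternative = "greater", exact = FALSE)
      data.frame(trait = d$trait[1], n_inside = sum(ins),
                 n_outside = sum(!ins), p = ht$p.value,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(shift)) rownames(shift) <- NULL
  }
  list(focal = focal, shift = shift)
}
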