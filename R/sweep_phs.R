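#' Fit a physical-to-genetic map
#'
#' Least-squares polynomial (default cubic) per chromosome from a marker
#' table with known physical (bp) and genetic (cM) positions. Because a
#' raw polynomial need not be monotone, evaluation goes through an
#' isotonic post-adjustment: the polynomial is evaluated on a dense grid,
#' monotonised with [stats::isoreg()], and queried by linear
#' interpolation.
#'
#' @param markers data.frame `chrom`, `bp`, `cm`.
#' @param degree polynomial degree (>= 1; a degree-0 map is constant and
#'   rejected by the monotonicity guard).
#' @param grid_n grid resolution for the isotonic adjustment.
#' @return A `genetic_map`: per chromosome the coefficients, the monotone
#'   evaluation grid and the marker RMSE after adjustment.
#' @export
fit_genetic_map <- function(markers, degree = 3L, grid_n = 512L) {
  if (degree < 1) {
    stop("monotonicity guard: a degree-0 map is constant", call. = FALSE)
  }
  maps <- lapply(split(markers, markers$chrom), function(d) {
    if (nrow(d) < degree + 1) {
      stop("fit error: need >= degree+1 markers on ", d$chrom[1],
           call. = FALSE)
    }
    fit <- stats::lm(cm ~ stats::poly(bp, degree, raw = TRUE), data = d)
    gx <- seq(min(d$bp), max(d$bp), length.out = grid_n)
    gy <- stats::predict(fit, newdata = data.frame(bp = gx))
    iso <- stats::isoreg(gx, gy)
    gy <- pmax(iso$yf, 0)
    pred <- stats::approx(gx, gy, xout = d$bp, rule = 2)$y
    list(coef = stats::coef(fit), grid_x = gx, grid_y = gy,
         rmse = sqrt(mean((pred - d$cm)^2)))
  })
  structure(maps, class = "genetic_map")
}

#' Evaluate a genetic map
#'
#' @param map a `genetic_map`.
#' @param chrom chromosome name (scalar).
#' @param bp physical positions.
#' @return genetic positions, cM (clamped to the fitted span).
#' @export
map_cm <- function(map, chrom, bp) {
  m <- map[[chrom]]
  if (is.null(m)) stop("no map for chromosome ", chrom, call. = FALSE)
  stats::approx(m$grid_x, m$grid_y, xout = bp, rule = 2)$y
}

# For a pair of haplotypes over one chromosome: index of the left/rightmost
# marker of the shared run through each site (0 width at discordant sites).
pair_share_bounds <- function(gi, gj) {
  m <- length(gi)
  mm <- which(gi != gj)
  t <- seq_len(m)
  if (!length(mm)) {
    return(list(lb = rep(1L, m), rb = rep(m, m), discord = rep(FALSE, m)))
  }
  li <- findInterval(t, mm)                      # mismatches at or before t
  at_mm <- t %in% mm
  lprev <- ifelse(li >= 1, mm[pmax(li, 1)], 0L)
  lprev[li < 1] <- 0L
  lprev[at_mm] <- NA_integer_
  rnxt <- ifelse(li < length(mm), mm[pmin(li + 1L, length(mm))], m + 1L)
  rnxt[li >= length(mm)] <- m + 1L
  rnxt[at_mm] <- NA_integer_
  list(lb = lprev + 1L, rb = rnxt - 1L, discord = at_mm)
}

#' Haplotype-sharing length between two accessions at a site
#'
#' The genetic-map length of the run of identical markers containing site
#' `x`: from the last identical marker scanning left (stopped by, and not
#' including, the first discordant marker) to the symmetric bound on the
#' right; chromosome ends truncate the run at the terminal marker. If the
#' pair is discordant at `x` itself the sharing is 0.
#'
#' @param genotypes accession x site 0/1 matrix.
#' @param sites data.frame `site`, `chrom`, `pos` aligned with genotype
#'   columns.
#' @param map a `genetic_map`.
#' @param i,j accession ids (rownames) or indices; must differ.
#' @param x site id (column name) or index.
#' @return sharing length in cM.
#' @export
sharing_length <- function(genotypes, sites, map, i, j, x) {
  if (is.character(x)) x <- match(x, colnames(genotypes))
  stopifnot(!identical(i, j))
  ch <- sites$chrom[x]
  idx <- which(sites$chrom == ch)
  gi <- genotypes[i, idx]; gj <- genotypes[j, idx]
  b <- pair_share_bounds(gi, gj)
  t <- match(x, idx)
  if (b$discord[t]) return(0)
  cm <- map_cm(map, ch, sites$pos[idx])
  cm[b$rb[t]] - cm[b$lb[t]]
}

#' Pairwise haplotype sharing (PHS) scan
#'
#' For every pair of accessions and every site, the shared-haplotype
#' length `z_ijx` (in cM) is standardised by the pair's genome-wide mean
#' and standard deviation, `Z_ijx = (z_ijx - zbar_ij) / sigma_ij`, which
#' corrects for overall pairwise similarity (population structure). The
#' raw PHS of an allele at a site is the mean of `Z_ijx` over carrier
#' pairs minus, in the default difference form, the mean over all pairs;
#' `form = "carrier"` uses the carrier-pair term alone. The allele whose
#' carriers share the longer haplotype on average is recorded as the
#' putatively selected allele.
#'
#' Pairs with zero genome-wide sharing variance are excluded with a
#' warning. Genome-wide moments are taken over every `grid_step`-th site.
#'
#' @param genotypes accession x site 0/1 matrix (MAF-filtered upstream).
#' @param sites data.frame `site`, `chrom`, `pos` aligned with columns.
#' @param map a `genetic_map`.
#' @param min_carriers minimum carriers per scored allele.
#' @param form "difference" (default) or "carrier".
#' @param grid_step stride of the genome-wide moment grid.
#' @return data.frame: `site`, `chrom`, `pos`, `allele` (0/1), `carriers`,
#'   `freq`, `phs`, `mean_share_cm`.
#' @export
phs_scan <- function(genotypes, sites, map, min_carriers = 2L,
                     form = c("difference", "carrier"), grid_step = 1L) {
  form <- match.arg(form)
  n <- nrow(genotypes); m <- ncol(genotypes)
  stopifnot(m == nrow(sites))
  chroms <- unique(sites$chrom)
  idx_by_chrom <- lapply(chroms, function(ch) which(sites$chrom == ch))
  cm_by_chrom <- lapply(chroms, function(ch) {
    idx <- which(sites$chrom == ch)
    map_cm(map, ch, sites$pos[idx])
  })
  grid <- seq(1L, m, by = grid_step)

  S_all <- numeric(m); n_all <- 0L
  S1 <- C1 <- S0 <- C0 <- numeric(m)
  ZS1 <- ZS0 <- numeric(m)        # raw sharing sums per allele
  dropped <- 0L
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    z <- numeric(m)
    for (k in seq_along(chroms)) {
      idx <- idx_by_chrom[[k]]
      b <- pair_share_bounds(genotypes[i, idx], genotypes[j, idx])
      cm <- cm_by_chrom[[k]]
      zi <- numeric(length(idx))
      ok <- !b$discord
      zi[ok] <- cm[b$rb[ok]] - cm[b$lb[ok]]
      z[idx] <- zi
    }
    zbar <- mean(z[grid]); sz <- stats::sd(z[grid])
    if (!is.finite(sz) || sz == 0) { dropped <- dropped + 1L; next }
    Z <- (z - zbar) / sz
    S_all <- S_all + Z; n_all <- n_all + 1L
    gi <- genotypes[i, ]; gj <- genotypes[j, ]
    i1 <- gi * gj; i0 <- (1 - gi) * (1 - gj)
    S1 <- S1 + Z * i1; C1 <- C1 + i1
    S0 <- S0 + Z * i0; C0 <- C0 + i0
    ZS1 <- ZS1 + z * i1; ZS0 <- ZS0 + z * i0
  }
  if (dropped) warning(dropped, " pair(s) excluded: zero sharing variance")
  if (n_all == 0) stop("no usable accession pairs", call. = FALSE)

  carriers1 <- colSums(genotypes)
  carriers0 <- n - carriers1
  base <- if (form == "difference") S_all / n_all else numeric(m)
  rows <- function(allele, S, C, ZS, carr) {
    ok <- C >= choose(min_carriers, 2) & carr >= min_carriers
    data.frame(site = colnames(genotypes)[ok], chrom = sites$chrom[ok],
               pos = sites$pos[ok], allele = allele,
               carriers = carr[ok], freq = carr[ok] / n,
               phs = S[ok] / C[ok] - base[ok],
               mean_share_cm = ZS[ok] / C[ok],
               stringsAsFactors = FALSE)
  }
  out <- rbind(rows(1L, S1, C1, ZS1, carriers1),
               rows(0L, S0, C0, ZS0, carriers0))
  out <- out[order(match(out$chrom, chroms), out$pos, out$allele), ]
  rownames(out) <- NULL
  out
}

#' PHS of one allele at one site
#'
#' Convenience wrapper over [phs_scan()] returning the single requested
#' score.
#'
#' @inheritParams phs_scan
#' @param x site id or index.
#' @param allele 0 or 1.
#' @return one-row data.frame as in [phs_scan()].
#' @export
phs <- function(genotypes, sites, map, x, allele,
                form = c("difference", "carrier")) {
  if (!is.character(x)) x <- colnames(genotypes)[x]
  res <- phs_scan(genotypes, sites, map, form = match.arg(form))
  out <- res[res$site == x & res$allele == allele, , drop = FALSE]
  if (!nrow(out)) stop("allele carried by < 2 accessions at ", x,
                       call. = FALSE)
  out
}

#' Standardise PHS scores within allele-frequency classes
#'
#' `standardized = (PHS - median_f) / SD_f`, computed among all allele
#' scores of the same frequency class (the median resists the extreme
#' scores a sweep produces). Classes are exact carrier counts when every
#' count class holds at least `min_class` scores; otherwise frequencies
#' are binned at width `bin_width`. SD is the sample (n-1) standard
#' deviation; a zero-SD class gets standardized scores of 0 with a
#' warning.
#'
#' @param scores data.frame from [phs_scan()].
#' @param min_class minimum class occupancy for exact-count classes.
#' @param bin_width frequency bin width of the fallback binning.
#' @return `scores` with added `class_id` and `standardized` columns.
#' @export
standardize_scores <- function(scores, min_class = 20L, bin_width = 0.05) {
  counts <- table(scores$carriers)
  if (all(counts >= min_class)) {
    cls <- as.character(scores$carriers)
  } else {
    cls <- as.character(cut(scores$freq,
                            breaks = seq(0, 1 + bin_width, by = bin_width),
                            right = FALSE))
  }
  scores$class_id <- cls
  scores$standardized <- NA_real_
  for (cl in unique(cls)) {
    ix <- cls == cl
    if (sum(ix) < 2) {
      warning("frequency class ", cl, " has < 2 scores; standardized to 0")
      scores$standardized[ix] <- 0
      next
    }
    s <- stats::sd(scores$phs[ix])
    if (s == 0) {
      warning("frequency class ", cl, " has zero SD; standardized to 0")
      scores$standardized[ix] <- 0
    } else {
      scores$standardized[ix] <- (scores$phs[ix] -
                                    stats::median(scores$phs[ix])) / s
    }
  }
  scores
}

#' Best-allele PHS score per site
#'
#' Collapses the two allele scores of each site to the larger
#' standardized score; the winning allele (the one with the longer shared
#' haplotype among carriers) is recorded as the putatively selected
#' allele.
#'
#' @param scores standardized scores from [standardize_scores()].
#' @return one row per site, sorted by chromosome and position.
#' @export
site_best_scores <- function(scores) {
  out <- do.call(rbind, lapply(split(scores, scores$site), function(d) {
    d[which.max(d$standardized), , drop = FALSE]
  }))
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
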