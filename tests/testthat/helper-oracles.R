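# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive every quantity from first principles with
# naive loops, sharing no code with the package.

# Partial F for the marker term by explicit normal equations
oracle_ols_fscore <- function(y, X_full, X_red) {
  ssr <- function(X) {
    b <- solve(t(X) %*% X, t(X) %*% y)
    r <- y - X %*% b
    sum(r^2)
  }
  ssr_f <- ssr(X_full)
  ssr_r <- ssr(X_red)
  q <- ncol(X_full) - ncol(X_red)
  df_res <- length(y) - ncol(X_full)
  ((ssr_r - ssr_f) / q) / (ssr_f / df_res)
}

# Sharing length (cM) between two haplotype vectors at marker index x,
# by stepwise expansion
oracle_sharing <- function(gi, gj, cm, x) {
  if (gi[x] != gj[x]) return(0)
  l <- x
  while (l > 1 && gi[l - 1] == gj[l - 1]) l <- l - 1
  r <- x
  while (r < length(gi) && gi[r + 1] == gj[r + 1]) r <- r + 1
  cm[r] - cm[l]
}

# Raw PHS (difference form) for `allele` at site x by full enumeration;
# G is accessions x sites over ONE chromosome, cm the site genetic
# positions. Returns NA if any pair has zero sharing SD.
oracle_phs <- function(G, cm, x, allele) {
  n <- nrow(G)
  m <- ncol(G)
  pairs <- utils::combn(n, 2)
  Zx <- numeric(ncol(pairs))
  carrier_pair <- logical(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    z <- vapply(seq_len(m), function(s) oracle_sharing(G[i, ], G[j, ], cm, s),
                numeric(1))
    if (stats::sd(z) == 0) return(NA_real_)
    Zx[p] <- (z[x] - mean(z)) / stats::sd(z)
    carrier_pair[p] <- G[i, x] == allele && G[j, x] == allele
  }
  if (!any(carrier_pair)) return(NA_real_)
  mean(Zx[carrier_pair]) - mean(Zx)
}

# Exhaustive minimum reaction path: depth-first over reaction chains,
# never passing through a currency compound
oracle_min_path <- function(network, gene, metabolite) {
  rx <- network$reactions
  subs <- lapply(strsplit(rx$substrates, ","), setdiff, network$currency)
  prods <- lapply(strsplit(rx$products, ","), setdiff, network$currency)
  touch <- mapply(function(s, p) unique(c(s, p)), subs, prods,
                  SIMPLIFY = FALSE)
  start <- which(rx$reaction %in%
                   network$gene_map$reaction[network$gene_map$gene == gene])
  best <- Inf
  recurse <- function(r, depth, seen) {
    if (depth >= best) return()
    if (metabolite %in% touch[[r]]) { best <<- depth; return() }
    for (cmp in touch[[r]]) {
      nxt <- which(vapply(touch, function(tc) cmp %in% tc, logical(1)))
      for (r2 in setdiff(nxt, seen)) recurse(r2, depth + 1L, c(seen, r2))
    }
  }
  for (r in start) recurse(r, 1L, r)
  best
}

# All-pairs site/feature overlap scan
oracle_site_overlap <- function(sites, annotation) {
  out <- list()
  for (s in seq_len(nrow(sites))) {
    hit <- FALSE
    for (a in seq_len(nrow(annotation))) {
      if (sites$chrom[s] == annotation$chrom[a] &&
          sites$pos[s] >= annotation$start[a] &&
          sites$pos[s] < annotation$end[a]) {
        out[[length(out) + 1L]] <- data.frame(site_index = s,
                                              class = annotation$class[a])
        hit <- TRUE
      }
    }
    if (!hit) out[[length(out) + 1L]] <- data.frame(site_index = s,
                                                    class = "intergenic")
  }
  do.call(rbind, out)
}

# descending-rank empirical p oracle
oracle_empirical_p <- function(f) {
  vapply(f, function(x) sum(f >= x) / length(f), numeric(1))
}
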