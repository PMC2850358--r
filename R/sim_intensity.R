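#' Simulate probe hybridisation intensities
#'
#' Draws reference-accession log2 signals from a Gaussian (log-normal raw
#' signal) and derives non-reference signals by multiplicative attenuation:
#' each SNP in a probe subtracts `atten_peak * w(pos) * g(gc)` log2 units,
#' where `w` is a triangular weight peaking at the probe centre (mismatches
#' near probe ends barely destabilise the duplex) and `g` is a mild linear
#' GC modulation (higher-GC probes lose proportionally more signal).
#' Multiple SNPs in one probe compound additively on the log2 scale.
#' Deleted probes drop to a constant background `background_delta` log2
#' units below the reference signal; duplicated probes gain
#' `log2(dup_fold)`. Independent Gaussian noise (sd `noise_sd`, log2 scale)
#' is added per array.
#'
#' @param truth a `truth_set` from [plant_variants()].
#' @param probes probe map.
#' @param config a [sim_config()] object.
#' @param noise_sd override of the configured noise (0 gives noiseless
#'   data, useful for recovery tests).
#' @return An `intensity_matrix`: list with `values` (probe x array log2
#'   signal matrix), `arrays` (data.frame array_id, accession),
#'   `reference` (accession id "Col-0"), `probe_id`.
#' @export
simulate_intensities <- function(truth, probes, config,
                                 noise_sd = config$noise_sd) {
  set.seed(stage_seed(config$seed, "intensities"))
  G <- truth$genotypes
  n <- nrow(G)
  m <- ncol(G)
  acc <- rownames(G)
  stopifnot(m == nrow(probes))

  base <- stats::rnorm(m, mean = 10, sd = 0.8)

  # per-site attenuation (log2 units) implied by the planted SNP detail
  atten <- numeric(m)
  if (nrow(truth$snp_detail)) {
    centre <- (config$probe_length + 1) / 2
    gcs <- probes$gc[truth$snp_detail$site]
    atten[truth$snp_detail$site] <- mapply(function(pos, gc) {
      w <- 1 - abs(pos - centre) / centre
      g <- 1 + config$atten_gc_slope * (gc - 0.5) / 0.5
      sum(config$atten_peak * w * g)
    }, truth$snp_detail$positions, gcs)
  }

  # expected accession x probe log2 signal before noise
  mu <- matrix(rep(base, each = n), nrow = n) - G * rep(atten, each = n)
  # segment states override per-SNP attenuation: deleted probes sit at a
  # constant background, duplicated probes gain reference-like copies
  seg_apply <- function(segs, delta) {
    for (i in seq_len(nrow(segs))) {
      a <- match(segs$accession[i], acc)
      idx <- segs$probe_from[i]:segs$probe_to[i]
      mu[a, idx] <<- base[idx] + delta
    }
  }
  seg_apply(truth$deletions, -config$background_delta)
  seg_apply(truth$duplications, log2(config$dup_fold))

  r <- config$n_replicate_arrays
  array_acc <- c(rep("Col-0", r), rep(acc, each = r))
  array_id <- paste0(array_acc, "_A", unlist(lapply(table(factor(array_acc,
               levels = unique(array_acc))), seq_len)))
  vals <- matrix(NA_real_, nrow = m, ncol = length(array_id),
                 dimnames = list(probes$probe_id, array_id))
  for (j in seq_along(array_id)) {
    a <- array_acc[j]
    mu_j <- if (a == "Col-0") base else mu[match(a, acc), ]
    vals[, j] <- mu_j + stats::rnorm(m, 0, noise_sd)
  }

  structure(list(values = vals,
                 arrays = data.frame(array_id = array_id,
                                     accession = array_acc,
                                     stringsAsFactors = FALSE),
                 reference = "Col-0",
                 probe_id = probes$probe_id),
            class = "intensity_matrix")
}
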