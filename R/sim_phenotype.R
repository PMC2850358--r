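#' Simulate quantitative trait values
#'
#' Generates per-accession, per-experiment trait values from the additive
#' linear model the association stage fits: trait = intercept + marker
#' effect x causal genotype + environment effect + admixture loadings +
#' Gaussian error. Multiple experiments per accession make downstream
#' least-squares means non-trivial.
#'
#' Each trait spec supplies `causal` (global probe index, `NA` for a null
#' trait), `effect` (trait units per non-reference allele), `noise_sd`,
#' `env_effect` (additive shift per successive experiment) and optionally
#' `q_sd` (sd of per-population admixture loadings; default 0.5, set 0 to
#' remove structure confounding).
#'
#' @param truth a `truth_set`.
#' @param qmatrix accession x population admixture matrix.
#' @param config a [sim_config()] object.
#' @return data.frame with `accession`, `experiment` and one column per
#'   trait.
#' @export
simulate_phenotypes <- function(truth, qmatrix, config) {
  set.seed(stage_seed(config$seed, "phenotypes"))
  G <- truth$genotypes
  acc <- rownames(G)
  n <- length(acc)
  ne <- config$n_experiments
  out <- data.frame(accession = rep(acc, times = ne),
                    experiment = rep(paste0("E", seq_len(ne)), each = n),
                    stringsAsFactors = FALSE)
  for (ts in config$trait_specs) {
    q_sd <- ts$q_sd %||% 0.5
    gamma <- stats::rnorm(ncol(qmatrix), 0, q_sd)
    causal <- truth$causal_markers[[ts$name]]
    g <- if (is.na(causal)) rep(0, n) else G[, causal]
    mu_acc <- 10 + ts$effect * g + as.numeric(qmatrix %*% gamma)
    env <- ts$env_effect * (rep(seq_len(ne), each = n) - 1)
    out[[ts$name]] <- rep(mu_acc, times = ne) + env +
      stats::rnorm(n * ne, 0, ts$noise_sd)
  }
  out
}

#' Least-squares means of traits over experiments
#'
#' Collapses a per-experiment phenotype table to one value per accession
#' and trait by fitting `trait ~ accession + experiment` and extracting the
#' accession means adjusted to a balanced experiment mix (for balanced
#' complete designs this equals the arithmetic mean over experiments).
#'
#' @param phenotypes data.frame from [simulate_phenotypes()] (or the same
#'   layout).
#' @return data.frame, one row per accession, one column per trait.
#' @export
phenotype_lsmeans <- function(phenotypes) {
  traits <- setdiff(names(phenotypes), c("accession", "experiment"))
  acc <- sort(unique(phenotypes$accession))
  out <- data.frame(accession = acc, stringsAsFactors = FALSE)
  for (tr in traits) {
    d <- phenotypes[!is.na(phenotypes[[tr]]), ]
    fit <- stats::lm(stats::reformulate(c("0 + accession", "experiment"),
                                        response = tr), data = d)
    co <- stats::coef(fit)
    base <- co[paste0("accession", acc)]
    envco <- co[grep("^experiment", names(co))]
    adj <- if (length(envco)) sum(envco, 0) / (length(envco) + 1) else 0
    out[[tr]] <- as.numeric(base + adj)
  }
  out
}
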