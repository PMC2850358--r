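#' Simulate a metabolic reaction network
#'
#' Builds a bipartite reaction-compound graph with gene-to-reaction
#' annotation and pathway labels, emulating a plant metabolic reactions
#' database. A linear backbone chain guarantees that finite paths exist
#' between most gene/compound pairs; extra random reactions add branching.
#' A designated currency-metabolite list (water, ATP, NADH and friends) is
#' attached; currency compounds additionally appear as co-substrates and
#' co-products of random reactions so that ignoring them matters.
#'
#' @param config a [sim_config()] object.
#' @param n_compounds,n_reactions,n_genes,n_pathways network size knobs.
#' @return A `metabolic_network`: list with `reactions` (data.frame
#'   reaction, substrates, products as comma-joined ids), `gene_map`
#'   (data.frame gene, reaction, pathway), `currency` (character vector),
#'   `compounds`.
#' @export
generate_metabolic_network <- function(config, n_compounds = 40L,
                                       n_reactions = 60L, n_genes = 80L,
                                       n_pathways = 10L) {
  set.seed(stage_seed(config$seed, "network"))
  currency <- c("WATER", "CO2", "O2", "PROTON", "ATP", "ADP", "NADH", "NAD")
  cmp <- sprintf("C%03d", seq_len(n_compounds))

  # backbone chain C1 -> C2 -> ... keeps the graph connected
  n_chain <- n_compounds - 1L
  rxn_id <- sprintf("R%03d", seq_len(n_reactions))
  subs <- prods <- vector("list", n_reactions)
  for (i in seq_len(n_chain)) {
    subs[[i]] <- cmp[i]
    prods[[i]] <- cmp[i + 1L]
  }
  for (i in seq.int(n_chain + 1L, n_reactions)) {
    pick <- sample(cmp, 2L)
    subs[[i]] <- pick[1]
    prods[[i]] <- pick[2]
  }
  # sprinkle currency co-factors on ~half the reactions
  with_cur <- sample.int(n_reactions, ceiling(n_reactions / 2))
  for (i in with_cur) {
    pair <- sample(list(c("ATP", "ADP"), c("NADH", "NAD"),
                        c("WATER", "PROTON"), c("O2", "CO2")), 1)[[1]]
    subs[[i]] <- c(subs[[i]], pair[1])
    prods[[i]] <- c(prods[[i]], pair[2])
  }

  reactions <- data.frame(
    reaction = rxn_id,
    substrates = vapply(subs, paste, "", collapse = ","),
    products = vapply(prods, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )

  # pathway labels follow contiguous reaction blocks; genes annotate
  # reactions (several genes may share one reaction)
  pathway_of_rxn <- paste0("PWY", sprintf("%02d", ceiling(
    seq_len(n_reactions) / (n_reactions / n_pathways))))
  gene <- sprintf("G%03d", seq_len(n_genes))
  rxn_of_gene <- if (n_genes <= n_reactions) rxn_id[seq_len(n_genes)] else
    c(rxn_id, sample(rxn_id, n_genes - n_reactions, replace = TRUE))
  gene_map <- data.frame(gene = gene, reaction = rxn_of_gene,
                         pathway = pathway_of_rxn[match(rxn_of_gene, rxn_id)],
                         stringsAsFactors = FALSE)

  structure(list(reactions = reactions, gene_map = gene_map,
                 currency = currency, compounds = cmp),
            class = "metabolic_network")
}

#' Bipartite igraph view of a metabolic network
#'
#' Expands the reaction table into an undirected bipartite reaction-compound
#' graph, dropping currency compounds as traversal nodes.
#'
#' @param network a `metabolic_network`.
#' @param drop_currency remove currency compounds before building the graph.
#' @return an [igraph::graph] with a vertex attribute `type` ("reaction" or
#'   "compound").
#' @export
network_graph <- function(network, drop_currency = TRUE) {
  rx <- network$reactions
  edges <- do.call(rbind, lapply(seq_len(nrow(rx)), function(i) {
    cps <- unique(c(strsplit(rx$substrates[i], ",")[[1]],
                    strsplit(rx$products[i], ",")[[1]]))
    if (drop_currency) cps <- setdiff(cps, network$currency)
    if (!length(cps)) return(NULL)
    cbind(rx$reaction[i], cps)
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::V(g)$type <- ifelse(igraph::V(g)$name %in% rx$reaction,
                              "reaction", "compound")
  g
}
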