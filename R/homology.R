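#' Homolog filtering configuration
#'
#' Bundles the thresholds applied to candidate homolog hits. Score and
#' identity thresholds are inclusive minima. Domain filtering has three
#' modes: \code{"none"} (score/identity only), \code{"simple"} (a
#' candidate must contain the \code{domain_threshold_T} most frequent
#' domains among the candidate set) and \code{"detailed"} (a candidate
#' must contain at least one of \code{required_domains}).
#'
#' @param sw_min minimum Smith-Waterman score (default 500).
#' @param identity_min minimum identity fraction in [0, 1] (default 0.5).
#' @param domain_mode one of \code{"none"}, \code{"simple"},
#'   \code{"detailed"}.
#' @param domain_threshold_T non-negative integer, simple-mode threshold
#'   (default 0, i.e. no domain requirement).
#' @param required_domains character vector of domain ids for detailed
#'   mode (empty keeps all).
#' @param max_dist optional maximum taxonomic distance (lineage levels
#'   below the reference terminal, \code{N - lca_depth}) for nearest-
#'   ortholog selection; \code{NULL} disables the cap.
#' @param whitelist optional organism codes to which ortholog selection
#'   is restricted; \code{NULL} disables the restriction.
#' @return A list of class \code{filter_config}.
#' @export
filter_config <- function(sw_min = 500, identity_min = 0.5,
                          domain_mode = c("none", "simple", "detailed"),
                          domain_threshold_T = 0L,
                          required_domains = character(0),
                          max_dist = NULL, whitelist = NULL) {
  domain_mode <- match.arg(domain_mode)
  if (sw_min < 0) stop("sw_min must be >= 0")
  if (identity_min < 0 || identity_min > 1)
    stop("identity_min must lie in [0, 1]")
  if (domain_threshold_T < 0) stop("domain_threshold_T must be >= 0")
  structure(list(sw_min = sw_min, identity_min = identity_min,
                 domain_mode = domain_mode,
                 domain_threshold_T = as.integer(domain_threshold_T),
                 required_domains = required_domains,
                 max_dist = max_dist, whitelist = whitelist),
            class = "filter_config")
}

#' Filter homology hits by score and identity
#'
#' Retains exactly the hits with \code{sw_score >= sw_min} and
#' \code{identity >= identity_min} (both inclusive); row order is
#' preserved. Raising either threshold never adds a hit.
#'
#' @param hits hit data frame (\code{query_gene}, \code{subject_gene},
#'   \code{sw_score}, \code{identity}).
#' @param cfg a [filter_config()].
#' @return The retained subset of \code{hits}.
#' @export
filter_hits <- function(hits, cfg) {
  keep <- hits$sw_score >= cfg$sw_min & hits$identity >= cfg$identity_min
  hits[keep, , drop = FALSE]
}

#' Rank domains by prevalence among candidate homologs
#'
#' Orders domain ids by descending number of candidate genes annotated
#' with them; ties are broken lexicographically so the ranking is
#' deterministic.
#'
#' @param candidate_genes character vector of gene ids.
#' @param domains domain annotation data frame (\code{gene_id},
#'   \code{domain_id}).
#' @return Character vector of domain ids, most prevalent first.
#' @export
rank_domains <- function(candidate_genes, domains) {
  d <- domains[domains$gene_id %in% candidate_genes, , drop = FALSE]
  d <- unique(d)
  if (nrow(d) == 0) return(character(0))
  counts <- table(d$domain_id)
  ord <- order(-as.integer(counts), names(counts))
  names(counts)[ord]
}

#' Simple domain filter: require the T most prevalent domains
#'
#' Keeps the candidates whose domain annotation contains every one of
#' the first \code{T} domains of \code{ranking}. \code{T = 0} keeps all
#' candidates; \code{T} beyond the ranking length requires the whole
#' ranking.
#'
#' @param candidate_genes character vector of gene ids.
#' @param ranking ordered domain ids, e.g. from [rank_domains()].
#' @param T non-negative integer.
#' @param domains domain annotation data frame.
#' @return The retained gene ids (order of \code{candidate_genes}).
#' @export
domain_filter_simple <- function(candidate_genes, ranking, T, domains) {
  if (T < 0) stop("T must be >= 0")
  need <- ranking[seq_len(min(T, length(ranking)))]
  if (length(need) == 0) return(candidate_genes)
  keep <- vapply(candidate_genes, function(g) {
    have <- domains$domain_id[domains$gene_id == g]
    all(need %in% have)
  }, TRUE)
  candidate_genes[keep]
}

#' Detailed domain filter: require any of a user-chosen domain set
#'
#' Keeps the candidates annotated with at least one of the required
#' domains; a candidate containing none of them is dropped. An empty
#' required set keeps all candidates.
#'
#' @param candidate_genes character vector of gene ids.
#' @param required_domains character vector of domain ids.
#' @param domains domain annotation data frame.
#' @return The retained gene ids (order of \code{candidate_genes}).
#' @export
domain_filter_detailed <- function(candidate_genes, required_domains,
                                   domains) {
  if (length(required_domains) == 0) return(candidate_genes)
  keep <- vapply(candidate_genes, function(g) {
    have <- domains$domain_id[domains$gene_id == g]
    length(intersect(have, required_domains)) > 0
  }, TRUE)
  candidate_genes[keep]
}

apply_domain_mode <- function(candidate_genes, cfg, domains) {
  switch(cfg$domain_mode,
    none = candidate_genes,
    simple = domain_filter_simple(candidate_genes,
                                  rank_domains(candidate_genes, domains),
                                  cfg$domain_threshold_T, domains),
    detailed = domain_filter_detailed(candidate_genes,
                                      cfg$required_domains, domains))
}

#' Cluster network genes into homology groups
#'
#' Builds an undirected similarity graph over the network's gene nodes:
#' genes a and b are linked when any hit surviving [filter_hits()] (and
#' the configured domain mode) connects them in either direction.
#' Clusters are the connected components; a gene with no qualifying link
#' is a singleton.
#'
#' @param network a [gene_network()].
#' @param ds a \code{datastore}.
#' @param cfg a [filter_config()].
#' @return A list of class \code{cluster_assignment}: \code{membership}
#'   (named integer, gene id to cluster label) and \code{clusters} (list
#'   of gene-id character vectors).
#' @export
cluster_network_genes <- function(network, ds, cfg) {
  gn <- gene_nodes(network)
  genes <- gn$gene_id
  bad <- setdiff(genes, ds$genes$gene_id)
  if (length(bad) > 0)
    stop("network gene(s) absent from datastore: ",
         paste(bad, collapse = ","))
  h <- filter_hits(ds$hits, cfg)
  h <- h[h$query_gene %in% genes & h$subject_gene %in% genes, , drop = FALSE]
  if (cfg$domain_mode != "none" && nrow(h) > 0) {
    involved <- unique(c(h$query_gene, h$subject_gene))
    kept <- apply_domain_mode(involved, cfg, ds$domains)
    h <- h[h$query_gene %in% kept & h$subject_gene %in% kept, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = h$query_gene, to = h$subject_gene),
    directed = FALSE,
    vertices = data.frame(name = unique(genes)))
  comp <- igraph::components(g)
  membership <- comp$membership[unique(genes)]
  clusters <- split(names(membership), membership)
  names(clusters) <- NULL
  structure(list(membership = membership, clusters = clusters),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat("<cluster_assignment> ", length(x$clusters), " cluster(s) over ",
      length(x$membership), " gene(s); sizes: ",
      paste(sort(sizes, decreasing = TRUE), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Collapse homology clusters into merged network nodes
#'
#' Each cluster of gene nodes becomes one merged node carrying the
#' member list in its label; edges are rewired to the merged nodes,
#' duplicates are merged, and self-loops arising from intra-cluster
#' edges are dropped. Compound and map nodes are unchanged.
#'
#' @param network a [gene_network()].
#' @param clustering a [cluster_network_genes()] result covering every
#'   gene node.
#' @return A new [gene_network()] whose gene nodes are the clusters.
#' @export
collapse_clusters <- function(network, clustering) {
  gn <- gene_nodes(network)
  miss <- setdiff(gn$gene_id, names(clustering$membership))
  if (length(miss) > 0)
    stop("cluster assignment does not cover gene(s): ",
         paste(miss, collapse = ","))
  # map node_id -> collapsed node_id
  gene2cluster <- clustering$membership
  node_map <- stats::setNames(network$nodes$node_id, network$nodes$node_id)
  cl_nodes <- lapply(seq_along(clustering$clusters), function(i) {
    members <- sort(clustering$clusters[[i]])
    id <- paste0("cluster_", i)
    list(id = id, members = members)
  })
  for (cl in cl_nodes) {
    member_nodes <- gn$node_id[gn$gene_id %in% cl$members]
    node_map[member_nodes] <- cl$id
  }
  keep <- network$nodes$type != "gene"
  nodes <- network$nodes[keep, , drop = FALSE]
  cl_df <- data.frame(
    node_id = vapply(cl_nodes, `[[`, "", "id"),
    type = "gene",
    gene_id = vapply(cl_nodes, function(cl) cl$members[1], ""),
    label = vapply(cl_nodes, function(cl)
      paste(cl$members, collapse = "+"), ""),
    stringsAsFactors = FALSE)
  nodes <- rbind(cl_df, nodes)
  e <- network$edges
  e$from <- unname(node_map[e$from])
  e$to <- unname(node_map[e$to])
  e <- e[e$from != e$to, , drop = FALSE]
  # undirected duplicate merge: canonical endpoint order
  a <- pmin(e$from, e$to); b <- pmax(e$from, e$to)
  dup <- duplicated(paste(a, b, sep = "\r"))
  e <- data.frame(from = a, to = b, interaction = e$interaction,
                  stringsAsFactors = FALSE)[!dup, , drop = FALSE]
  rownames(e) <- NULL
  gene_network(nodes, e)
}
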