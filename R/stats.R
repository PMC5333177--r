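#' Gene Set PAI: mean age index over a gene set
#'
#' \deqn{\mathrm{Gene\ Set\ PAI} = \sum_{genes} PAI / N}
#' where N is the number of genes. 0 when all genes are as old as the
#' root, N_lineage when all are organism-specific.
#'
#' @param pai_values numeric vector of per-gene PAI values (non-empty).
#' @return The arithmetic mean.
#' @export
gene_set_pai <- function(pai_values) {
  if (length(pai_values) == 0) stop("empty PAI vector")
  mean(pai_values)
}

#' Network PAI: degree-weighted age statistic
#'
#' \deqn{\mathrm{Network\ PAI} = \sum_{gene\ nodes} (PAI \cdot d) / (2N)}
#' where d is the node degree in the full network (edges to compound and
#' map nodes included) and N is the number of gene nodes. Unlike Gene
#' Set PAI this weights hub genes by their connectivity; it is the
#' literal printed formula and is not bounded by the maximum PAI on
#' dense networks.
#'
#' @param network a [gene_network()].
#' @param pai named numeric vector of PAI values keyed by gene node id
#'   (every gene node must be present).
#' @return The statistic.
#' @export
network_pai <- function(network, pai) {
  gn <- gene_nodes(network)
  if (nrow(gn) == 0) stop("network has no gene nodes")
  miss <- setdiff(gn$node_id, names(pai))
  if (length(miss) > 0)
    stop("missing PAI for gene node(s): ", paste(miss, collapse = ","))
  d <- node_degrees(network)
  sum(pai[gn$node_id] * d[gn$node_id]) / (2 * nrow(gn))
}

#' Summary age statistics for an analysed network
#'
#' Reports Gene Set PAI, Network PAI, and the taxa at the extreme and
#' median ages: oldest = taxon at the minimum PAI, youngest = taxon at
#' the maximum, median = taxon at the median PAI (for an even count the
#' lower middle value is used so the result is an attained depth with a
#' taxon name). Also totals the orthologs supporting the calls.
#'
#' @param network a [gene_network()].
#' @param pai_results list of [compute_pai()] results keyed or ordered
#'   by gene node; names must be gene node ids.
#' @param tree a [build_taxonomy()] result.
#' @param ref_org reference organism code.
#' @return A list of class \code{pai_summary}.
#' @export
pai_summary <- function(network, pai_results, tree, ref_org) {
  if (length(pai_results) == 0) stop("no PAI results")
  pais <- vapply(pai_results, `[[`, 0L, "pai")
  med <- lower_median(pais)
  structure(list(
    gene_set_pai = gene_set_pai(pais),
    network_pai = network_pai(network, pais),
    oldest_taxon = taxon_name_at(tree, ref_org, min(pais)),
    youngest_taxon = taxon_name_at(tree, ref_org, max(pais)),
    median_taxon = taxon_name_at(tree, ref_org, med),
    median_pai = med,
    total_orthologs = sum(vapply(pai_results, `[[`, 0L, "n_orthologs")),
    n_genes = length(pais)),
    class = "pai_summary")
}

lower_median <- function(x) sort(x)[ceiling(length(x) / 2)]

#' @export
print.pai_summary <- function(x, ...) {
  cat("Gene set PAI = ", signif(x$gene_set_pai, 4),
      "; Network PAI = ", signif(x$network_pai, 4), "\n",
      "Median taxon = ", x$median_taxon,
      "; Oldest taxon = ", x$oldest_taxon,
      "; Youngest taxon = ", x$youngest_taxon, "\n",
      "Total orthologs analyzed: ", x$total_orthologs, "\n", sep = "")
  invisible(x)
}

#' Phylogenetic presence/absence profile
#'
#' Builds the gene-by-organism profile: cell (i, j) is \code{"+"} when
#' organism j carries at least one ortholog of gene i, else \code{"-"}.
#' Only organisms with at least one ortholog of any profiled gene get a
#' row; rows are sorted by organism code, columns follow the gene order
#' given.
#'
#' @param network_genes character vector of gene ids (column order).
#' @param ortholog_map named list: gene id to character vector of
#'   organism codes carrying an ortholog.
#' @return Character matrix with organisms as rows and genes as columns.
#' @export
phylogenetic_profile <- function(network_genes, ortholog_map) {
  orgs <- sort(unique(unlist(ortholog_map[network_genes])))
  m <- matrix("-", nrow = length(orgs), ncol = length(network_genes),
              dimnames = list(orgs, network_genes))
  for (g in network_genes) {
    present <- intersect(ortholog_map[[g]], orgs)
    m[present, g] <- "+"
  }
  m
}
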