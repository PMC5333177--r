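#' Construct a gene network
#'
#' A gene network has typed nodes (\code{gene}, \code{compound} or
#' \code{map}) and undirected edges. Gene nodes carry the id of the
#' underlying gene; compound and map nodes model pathway metabolites and
#' cross-references and take part in topology only.
#'
#' @param nodes data frame with columns \code{node_id}, \code{type},
#'   \code{gene_id} (empty string for non-gene nodes), \code{label}.
#' @param edges data frame with columns \code{from}, \code{to} and
#'   optionally \code{interaction}.
#' @return An object of class \code{gene_network}.
#' @export
gene_network <- function(nodes, edges) {
  if (is.null(edges$interaction)) edges$interaction <- rep("", nrow(edges))
  if (anyDuplicated(nodes$node_id)) stop("duplicated node_id")
  if (!all(nodes$type %in% c("gene", "compound", "map")))
    stop("node type must be one of gene/compound/map")
  bad <- setdiff(unique(c(edges$from, edges$to)), nodes$node_id)
  if (length(bad) > 0)
    stop("edge endpoint(s) not in node table: ", paste(bad, collapse = ","))
  if (any(nodes$type == "gene" & !nzchar(nodes$gene_id)))
    stop("gene nodes must carry a gene_id")
  structure(list(nodes = nodes, edges = edges), class = "gene_network")
}

#' Read a gene network from nodes/edges TSV files
#'
#' @param path directory containing \code{nodes.tsv} (node_id, type,
#'   gene_id, label) and \code{edges.tsv} (from, to, interaction).
#' @return A [gene_network()] object.
#' @export
read_network <- function(path) {
  for (f in c("nodes.tsv", "edges.tsv"))
    if (!file.exists(file.path(path, f)))
      stop("network directory is missing ", f)
  nodes <- read_tsv_table(file.path(path, "nodes.tsv"),
                          c("node_id", "type", "gene_id", "label"))
  edges <- read_tsv_table(file.path(path, "edges.tsv"),
                          c("from", "to", "interaction"))
  gene_network(nodes, edges)
}

#' Write a gene network as nodes/edges TSV files
#'
#' @param network a [gene_network()].
#' @param path output directory (created if needed).
#' @return \code{path}, invisibly.
#' @export
write_network <- function(network, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_tsv_table(network$nodes[c("node_id", "type", "gene_id", "label")],
                  file.path(path, "nodes.tsv"))
  write_tsv_table(network$edges[c("from", "to", "interaction")],
                  file.path(path, "edges.tsv"))
  invisible(path)
}

#' @export
print.gene_network <- function(x, ...) {
  tt <- table(factor(x$nodes$type, levels = c("gene", "compound", "map")))
  cat("<gene_network> ", nrow(x$nodes), " nodes (",
      tt[["gene"]], " gene, ", tt[["compound"]], " compound, ",
      tt[["map"]], " map), ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

gene_nodes <- function(network) {
  network$nodes[network$nodes$type == "gene", , drop = FALSE]
}

#' Node degrees of a gene network
#'
#' Degree counts every incident edge in the full network, whatever the
#' type of the neighbour; gene-compound-gene wiring is how pathway
#' diagrams encode gene connectivity, so compound edges contribute.
#'
#' @param network a [gene_network()].
#' @return Named integer vector over all node ids.
#' @export
node_degrees <- function(network) {
  d <- stats::setNames(integer(nrow(network$nodes)), network$nodes$node_id)
  ends <- c(network$edges$from, network$edges$to)
  tt <- table(ends)
  d[names(tt)] <- as.integer(tt)
  d
}
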