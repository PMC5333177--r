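#' Build a taxonomy tree from organism lineages
#'
#' Merges the root-to-terminal lineage of every organism into a single
#' prefix tree. Node depth is the number of edges from the root (root =
#' 0), so an organism whose lineage lists \code{N + 1} taxa sits at
#' terminal depth \code{N}. Taxon names must be used consistently: two
#' lineages implying different parents for the same taxon name are a
#' construction error.
#'
#' @param organisms the \code{organisms} data frame of a [read_datastore()]
#'   result (columns \code{org_code} and \code{lineage_split}), or a data
#'   frame with \code{org_code} and semicolon-joined \code{lineage}.
#' @return An object of class \code{taxonomy}: list with \code{parent}
#'   (named character, root maps to \code{NA}), \code{depth} (named
#'   integer), \code{org_taxon} (org code to terminal taxon), and
#'   \code{org_lineage} (org code to character vector of taxa).
#' @export
build_taxonomy <- function(organisms) {
  if (is.null(organisms$lineage_split))
    organisms$lineage_split <- lapply(strsplit(organisms$lineage, ";",
                                               fixed = TRUE), trimws)
  parent <- character(0)
  depth <- integer(0)
  org_taxon <- character(0)
  org_lineage <- list()
  for (i in seq_len(nrow(organisms))) {
    lin <- organisms$lineage_split[[i]]
    if (length(lin) == 0) stop("empty lineage for ", organisms$org_code[i])
    for (k in seq_along(lin)) {
      tx <- lin[k]
      par <- if (k == 1L) NA_character_ else lin[k - 1L]
      if (tx %in% names(parent)) {
        have <- parent[[tx]]
        if (!identical(have, par) && !(is.na(have) && is.na(par)))
          stop("conflicting parents for taxon '", tx, "': '",
               have, "' vs '", par, "'")
      } else {
        parent[[tx]] <- par
        depth[[tx]] <- k - 1L
      }
    }
    org_taxon[[organisms$org_code[i]]] <- lin[length(lin)]
    org_lineage[[organisms$org_code[i]]] <- lin
  }
  structure(list(parent = parent, depth = depth,
                 org_taxon = org_taxon, org_lineage = org_lineage),
            class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  root <- names(x$parent)[is.na(x$parent)]
  cat("<taxonomy> ", length(x$parent), " taxa, ",
      length(x$org_taxon), " organisms, root '", root, "'\n", sep = "")
  invisible(x)
}

org_check <- function(tree, org) {
  if (!org %in% names(tree$org_taxon))
    stop("unknown organism: ", org)
}

#' Depth of the last common ancestor of two organisms
#'
#' Returns the depth (root = 0) of the deepest taxon shared by the
#' lineages of the two organisms. An organism's LCA depth with itself is
#' its terminal depth.
#'
#' @param tree a [build_taxonomy()] result.
#' @param org_a,org_b organism codes attached to the tree.
#' @return Integer depth.
#' @export
lca_depth <- function(tree, org_a, org_b) {
  org_check(tree, org_a)
  org_check(tree, org_b)
  la <- tree$org_lineage[[org_a]]
  lb <- tree$org_lineage[[org_b]]
  n <- min(length(la), length(lb))
  same <- la[seq_len(n)] == lb[seq_len(n)]
  if (!same[1]) stop("lineages of ", org_a, " and ", org_b,
                     " share no root")
  # longest common prefix; lineages are root-to-terminal paths
  k <- if (all(same)) n else which(!same)[1] - 1L
  k - 1L
}

#' Phylostratigraphic age index (PAI) of a gene
#'
#' The PAI of a reference-organism gene is the depth, on the reference
#' lineage, of the last common ancestor covering the reference organism
#' and every organism carrying an ortholog: equivalently the minimum over
#' ortholog-bearing organisms of their pairwise LCA depth with the
#' reference. PAI 0 is the shared root ("Cellular Organisms", the oldest
#' genes); PAI N, the reference terminal depth, marks genes with no
#' ortholog outside the reference organism (the youngest). Ortholog
#' entries equal to \code{ref_org} are ignored: paralogs do not age a
#' gene.
#'
#' @param tree a [build_taxonomy()] result.
#' @param ref_org reference organism code.
#' @param ortholog_orgs character vector of organism codes with at least
#'   one ortholog of the gene (may be empty).
#' @param gene_id optional gene id carried through to the result.
#' @return A list of class \code{pai_result}: \code{gene_id}, \code{pai},
#'   \code{taxon_name} (taxon at that depth on the reference lineage),
#'   \code{ortholog_orgs}, \code{n_orthologs}.
#' @export
compute_pai <- function(tree, ref_org, ortholog_orgs, gene_id = NA_character_) {
  org_check(tree, ref_org)
  others <- setdiff(unique(ortholog_orgs), ref_org)
  for (o in others) org_check(tree, o)
  n_ref <- length(tree$org_lineage[[ref_org]]) - 1L
  pai <- if (length(others) == 0) n_ref
         else min(vapply(others, function(o) lca_depth(tree, ref_org, o), 0L))
  structure(list(gene_id = gene_id, pai = as.integer(pai),
                 taxon_name = taxon_name_at(tree, ref_org, pai),
                 ortholog_orgs = sort(others),
                 n_orthologs = length(others)),
            class = "pai_result")
}

#' @export
print.pai_result <- function(x, ...) {
  cat("PAI ", x$pai, " (", x$taxon_name, ") for gene ", x$gene_id,
      "; ", x$n_orthologs, " ortholog organism(s)\n", sep = "")
  invisible(x)
}

#' Taxon name at a given depth on an organism's lineage
#'
#' @param tree a [build_taxonomy()] result.
#' @param ref_org organism code.
#' @param depth integer in \code{[0, N]} where N is the organism's
#'   terminal depth.
#' @return Taxon name (character scalar).
#' @export
taxon_name_at <- function(tree, ref_org, depth) {
  org_check(tree, ref_org)
  lin <- tree$org_lineage[[ref_org]]
  if (depth < 0 || depth > length(lin) - 1L)
    stop("depth ", depth, " outside [0, ", length(lin) - 1L, "] for ",
         ref_org)
  lin[[depth + 1L]]
}
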