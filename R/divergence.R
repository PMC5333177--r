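#' Select the nearest ortholog of a reference gene
#'
#' Among candidate ortholog genes, picks the one from the taxonomically
#' closest species: the organism with the deepest last common ancestor
#' with the reference. An optional whitelist restricts the organisms
#' considered, and an optional maximum taxonomic distance (measured as
#' \code{N - lca_depth}, the number of reference-lineage levels below
#' the divergence node) caps how far away the ortholog may be. Ties are
#' broken by organism code then gene id, so the choice is deterministic.
#'
#' @param tree a [build_taxonomy()] result.
#' @param ref_org reference organism code.
#' @param ortholog_genes data frame with columns \code{gene_id} and
#'   \code{org_code} (genes in the reference organism are ignored).
#' @param max_dist optional non-negative integer distance cap.
#' @param whitelist optional character vector of organism codes.
#' @return The selected gene id, or \code{NA_character_} when no
#'   candidate survives the restrictions.
#' @export
select_nearest_ortholog <- function(tree, ref_org, ortholog_genes,
                                    max_dist = NULL, whitelist = NULL) {
  og <- ortholog_genes[ortholog_genes$org_code != ref_org, , drop = FALSE]
  if (!is.null(whitelist))
    og <- og[og$org_code %in% whitelist, , drop = FALSE]
  if (nrow(og) == 0) return(NA_character_)
  n_ref <- length(tree$org_lineage[[ref_org]]) - 1L
  og$lca <- vapply(og$org_code, function(o) lca_depth(tree, ref_org, o), 0L)
  if (!is.null(max_dist))
    og <- og[n_ref - og$lca <= max_dist, , drop = FALSE]
  if (nrow(og) == 0) return(NA_character_)
  og <- og[order(-og$lca, og$org_code, og$gene_id), , drop = FALSE]
  og$gene_id[1]
}

#' Divergence index (Ka/Ks) of a gene against its nearest ortholog
#'
#' Orchestrates the full divergence pipeline: nearest-ortholog selection
#' ([select_nearest_ortholog()]), global protein alignment
#' ([global_align()]), codon threading ([codon_align()]) and NG86
#' counting ([kaks_ng86()]). The divergence index DI = Ka/Ks is reported
#' when defined; values below 1 suggest purifying and above 1
#' diversifying selection.
#'
#' @param gene_id reference gene id (must have both nt and aa sequences
#'   in the datastore).
#' @param ds a \code{datastore}.
#' @param tree a [build_taxonomy()] result.
#' @param ortholog_genes candidate ortholog genes as for
#'   [select_nearest_ortholog()] (normally the genes surviving homology
#'   filtering for this gene).
#' @param cfg a [filter_config()] supplying \code{max_dist} and
#'   \code{whitelist}.
#' @param align_params list of [global_align()] arguments
#'   (\code{matrix}, \code{gap_open}, \code{gap_extend}).
#' @return A list of class \code{di_result}: \code{gene_id},
#'   \code{ortholog_gene_id}, \code{ortholog_org}, \code{ka}, \code{ks},
#'   \code{di}, \code{status} (\code{ok}, \code{undefined_ks_zero},
#'   \code{saturated} or \code{no_ortholog}), \code{method}
#'   (\code{"NG86"}).
#' @export
compute_di <- function(gene_id, ds, tree, ortholog_genes,
                       cfg = filter_config(), align_params = list()) {
  res <- function(orth = NA_character_, ka = NA_real_, ks = NA_real_,
                  di = NA_real_, status) {
    org <- if (is.na(orth)) NA_character_
           else ds$genes$org_code[ds$genes$gene_id == orth]
    structure(list(gene_id = gene_id, ortholog_gene_id = orth,
                   ortholog_org = org, ka = ka, ks = ks, di = di,
                   status = status, method = "NG86"),
              class = "di_result")
  }
  orth <- select_nearest_ortholog(tree,
                                  ds$genes$org_code[ds$genes$gene_id == gene_id],
                                  ortholog_genes,
                                  max_dist = cfg$max_dist,
                                  whitelist = cfg$whitelist)
  if (is.na(orth)) return(res(status = "no_ortholog"))
  for (g in c(gene_id, orth)) {
    if (!g %in% names(ds$aa_seqs) || !g %in% names(ds$nt_seqs))
      stop("gene ", g, " lacks nucleotide or protein sequence")
  }
  pa <- do.call(global_align,
                c(list(a = ds$aa_seqs[[gene_id]], b = ds$aa_seqs[[orth]]),
                  align_params))
  ca <- codon_align(pa, ds$nt_seqs[[gene_id]], ds$nt_seqs[[orth]])
  kk <- kaks_ng86(ca)
  di <- if (kk$status == "ok") kk$ka / kk$ks else NA_real_
  res(orth, ka = kk$ka, ks = kk$ks, di = di, status = kk$status)
}

#' @export
print.di_result <- function(x, ...) {
  cat("DI for ", x$gene_id, ": ", sep = "")
  if (x$status == "no_ortholog") {
    cat("no ortholog available\n")
  } else {
    cat("vs ", x$ortholog_gene_id, " (", x$ortholog_org, "): Ka = ",
        signif(x$ka, 4), ", Ks = ", signif(x$ks, 4), ", Ka/Ks = ",
        signif(x$di, 4), " [", x$status, "]\n", sep = "")
  }
  invisible(x)
}
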