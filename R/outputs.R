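#' Write the tabular outputs of an analysis
#'
#' Writes the flat-file results of an [evo_analysis()] to a directory:
#' \code{pai.tsv} (gene_id, pai, taxon_name, n_orthologs, ortholog_orgs
#' semicolon-joined), \code{di.tsv} (when divergence was computed),
#' \code{clusters.tsv} (gene_id, cluster_label), \code{summary.tsv},
#' \code{profile.tsv} (the +/- matrix with gene columns),
#' \code{colors.tsv} (node_id, hex color) and \code{layout.tsv}
#' (node_id, x, y).
#'
#' @param fit an [evo_analysis()] result.
#' @param outdir output directory (created if needed).
#' @return \code{outdir}, invisibly.
#' @export
write_analysis_outputs <- function(fit, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pai <- data.frame(
    gene_id = vapply(fit$pai, `[[`, "", "gene_id"),
    pai = vapply(fit$pai, `[[`, 0L, "pai"),
    taxon_name = vapply(fit$pai, `[[`, "", "taxon_name"),
    n_orthologs = vapply(fit$pai, `[[`, 0L, "n_orthologs"),
    ortholog_orgs = vapply(fit$pai, function(p)
      paste(p$ortholog_orgs, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  write_tsv_table(pai, file.path(outdir, "pai.tsv"))

  if (length(fit$di) > 0) {
    di <- data.frame(
      gene_id = vapply(fit$di, `[[`, "", "gene_id"),
      ortholog_gene = vapply(fit$di, `[[`, "", "ortholog_gene_id"),
      ortholog_org = vapply(fit$di, `[[`, "", "ortholog_org"),
      ka = vapply(fit$di, `[[`, 0, "ka"),
      ks = vapply(fit$di, `[[`, 0, "ks"),
      di = vapply(fit$di, `[[`, 0, "di"),
      status = vapply(fit$di, `[[`, "", "status"),
      method = vapply(fit$di, `[[`, "", "method"),
      stringsAsFactors = FALSE)
    write_tsv_table(di, file.path(outdir, "di.tsv"))
  }

  cl <- data.frame(gene_id = names(fit$clustering$membership),
                   cluster_label = unname(fit$clustering$membership),
                   stringsAsFactors = FALSE)
  write_tsv_table(cl, file.path(outdir, "clusters.tsv"))

  s <- fit$summary
  write_tsv_table(data.frame(
    statistic = c("gene_set_pai", "network_pai", "median_taxon",
                  "oldest_taxon", "youngest_taxon", "total_orthologs",
                  "n_genes"),
    value = c(s$gene_set_pai, s$network_pai, s$median_taxon,
              s$oldest_taxon, s$youngest_taxon, s$total_orthologs,
              s$n_genes), stringsAsFactors = FALSE),
    file.path(outdir, "summary.tsv"))

  prof <- data.frame(org_code = rownames(fit$profile), fit$profile,
                     check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_table(prof, file.path(outdir, "profile.tsv"))

  write_tsv_table(data.frame(node_id = names(fit$colors),
                             color = unname(fit$colors),
                             stringsAsFactors = FALSE),
                  file.path(outdir, "colors.tsv"))
  write_tsv_table(fit$layout[c("node_id", "x", "y")],
                  file.path(outdir, "layout.tsv"))
  invisible(outdir)
}
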