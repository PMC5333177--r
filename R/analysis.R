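#' Evolutionary analysis of a gene network
#'
#' Runs the full pipeline for one network against a homology datastore:
#' filters candidate homologs by Smith-Waterman score, identity and
#' domain composition; computes the phylostratigraphic age index (PAI)
#' of every gene node from the taxonomy of ortholog-bearing organisms;
#' clusters network genes into homology groups; optionally estimates the
#' divergence index (Ka/Ks against the nearest ortholog, NG86); and
#' derives network-level statistics, the phylogenetic profile, node
#' colors and the PAI-ring layout.
#'
#' @param network a [gene_network()] whose gene nodes belong to
#'   \code{ref_org}.
#' @param ds a \code{datastore} from [read_datastore()] or
#'   [simulate_datastore()].
#' @param ref_org reference organism code.
#' @param cfg a [filter_config()].
#' @param di logical: compute divergence indices (requires sequences in
#'   the datastore for the genes involved)?
#' @param align_params alignment parameter overrides passed to
#'   [global_align()].
#' @param color_scheme scheme for PAI node colors, see [color_scale()].
#' @return An object of class \code{evo_analysis}; see
#'   [summary.evo_analysis()], [plot.evo_analysis()],
#'   [as.data.frame.evo_analysis()].
#' @examples
#' sim <- simulate_datastore(sim_config(seed = 1, n_genes = 8))
#' fit <- evo_analysis(sim$network, sim$datastore, sim$ref_org)
#' summary(fit)
#' head(as.data.frame(fit))
#' @export
evo_analysis <- function(network, ds, ref_org, cfg = filter_config(),
                         di = TRUE, align_params = list(),
                         color_scheme = "heatmap") {
  if (!ref_org %in% ds$organisms$org_code)
    stop("unknown reference organism: ", ref_org)
  tree <- build_taxonomy(ds$organisms)
  gn <- gene_nodes(network)
  bad <- setdiff(gn$gene_id, ds$genes$gene_id)
  if (length(bad) > 0)
    stop("network gene(s) absent from datastore: ",
         paste(bad, collapse = ","))

  fh <- filter_hits(ds$hits, cfg)
  org_of <- stats::setNames(ds$genes$org_code, ds$genes$gene_id)

  pai_results <- list()
  di_results <- list()
  ortholog_map <- list()
  for (i in seq_len(nrow(gn))) {
    g <- gn$gene_id[i]
    cand <- homolog_candidates(g, fh)
    cand <- apply_domain_mode(cand, cfg, ds$domains)
    orth_df <- data.frame(gene_id = cand,
                          org_code = unname(org_of[cand]),
                          stringsAsFactors = FALSE)
    orth_df <- orth_df[orth_df$org_code != ref_org, , drop = FALSE]
    ortholog_map[[g]] <- unique(orth_df$org_code)
    pai_results[[gn$node_id[i]]] <-
      compute_pai(tree, ref_org, orth_df$org_code, gene_id = g)
    if (di) {
      di_results[[gn$node_id[i]]] <-
        compute_di(g, ds, tree, orth_df, cfg, align_params)
    }
  }

  clustering <- cluster_network_genes(network, ds, cfg)
  summ <- pai_summary(network, pai_results, tree, ref_org)
  pai_vec <- vapply(pai_results, `[[`, 0L, "pai")
  colors <- color_scale(pai_vec, color_scheme)
  layout <- layout_rings(network, pai_vec)

  structure(list(network = network, ref_org = ref_org, cfg = cfg,
                 tree = tree, pai = pai_results, di = di_results,
                 clustering = clustering, summary = summ,
                 ortholog_map = ortholog_map,
                 profile = phylogenetic_profile(gn$gene_id, ortholog_map),
                 colors = colors, layout = layout),
            class = "evo_analysis")
}

homolog_candidates <- function(gene_id, hits) {
  unique(c(hits$subject_gene[hits$query_gene == gene_id],
           hits$query_gene[hits$subject_gene == gene_id]))
}

#' @export
print.evo_analysis <- function(x, ...) {
  cat("<evo_analysis> reference organism ", x$ref_org, "\n", sep = "")
  print(x$network)
  cat("thresholds: SW >= ", x$cfg$sw_min, ", identity >= ",
      x$cfg$identity_min, ", domain mode ", x$cfg$domain_mode, "\n",
      sep = "")
  print(x$summary)
  cat(length(x$clustering$clusters), "homology cluster(s)\n")
  invisible(x)
}

#' Summarize an evolutionary network analysis
#'
#' @param object an [evo_analysis()] result.
#' @param ... unused.
#' @return The \code{pai_summary} of the analysis.
#' @export
summary.evo_analysis <- function(object, ...) object$summary

#' Per-gene results of an evolutionary network analysis
#'
#' @param x an [evo_analysis()] result.
#' @param ... unused.
#' @return Data frame with one row per gene node: \code{node_id},
#'   \code{gene_id}, \code{pai}, \code{taxon_name}, \code{n_orthologs},
#'   \code{cluster}, and when divergence was computed \code{ortholog_gene},
#'   \code{ka}, \code{ks}, \code{di}, \code{di_status}.
#' @export
as.data.frame.evo_analysis <- function(x, ...) {
  ids <- names(x$pai)
  out <- data.frame(
    node_id = ids,
    gene_id = vapply(x$pai, `[[`, "", "gene_id"),
    pai = vapply(x$pai, `[[`, 0L, "pai"),
    taxon_name = vapply(x$pai, `[[`, "", "taxon_name"),
    n_orthologs = vapply(x$pai, `[[`, 0L, "n_orthologs"),
    stringsAsFactors = FALSE)
  out$cluster <- unname(x$clustering$membership[out$gene_id])
  if (length(x$di) > 0) {
    out$ortholog_gene <- vapply(x$di[ids], `[[`, "", "ortholog_gene_id")
    out$ka <- vapply(x$di[ids], `[[`, 0, "ka")
    out$ks <- vapply(x$di[ids], `[[`, 0, "ks")
    out$di <- vapply(x$di[ids], `[[`, 0, "di")
    out$di_status <- vapply(x$di[ids], `[[`, "", "status")
  }
  rownames(out) <- NULL
  out
}

#' Plot an evolutionary network analysis
#'
#' \code{type = "hist"} draws the PAI histogram (one bar per integer age
#' level); \code{type = "rings"} draws the network with the PAI-ring
#' layout and the analysis node colors.
#'
#' @param x an [evo_analysis()] result.
#' @param type \code{"hist"} or \code{"rings"}.
#' @param ... passed to the underlying base graphics call.
#' @return \code{x}, invisibly.
#' @export
plot.evo_analysis <- function(x, type = c("hist", "rings"), ...) {
  type <- match.arg(type)
  pai <- vapply(x$pai, `[[`, 0L, "pai")
  if (type == "hist") {
    counts <- pai_histogram(pai)
    graphics::barplot(counts, xlab = "PAI", ylab = "genes",
                      main = "PAI distribution",
                      col = color_scale(as.numeric(names(counts))), ...)
  } else {
    lay <- x$layout
    graphics::plot(lay$x, lay$y, asp = 1, xlab = "", ylab = "",
                   pch = 21, cex = 2,
                   bg = ifelse(lay$node_id %in% names(x$colors),
                               x$colors[lay$node_id], "grey80"),
                   main = "PAI ring layout", ...)
    for (i in seq_len(nrow(x$network$edges))) {
      p <- lay[match(c(x$network$edges$from[i], x$network$edges$to[i]),
                     lay$node_id), ]
      graphics::segments(p$x[1], p$y[1], p$x[2], p$y[2], col = "grey70")
    }
  }
  invisible(x)
}

# one bin per integer PAI level from 0 to max observed
pai_histogram <- function(pai) {
  lv <- 0:max(pai)
  counts <- vapply(lv, function(v) sum(pai == v), 0L)
  stats::setNames(counts, lv)
}
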