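#' Identity-threshold sweep of the age analysis
#'
#' Re-runs ortholog detection and the PAI statistics at each identity
#' threshold of a grid, holding every other filter setting fixed. As the
#' threshold rises orthologs can only be lost, so each gene's PAI — and
#' hence Gene Set PAI — is non-decreasing along an increasing grid.
#'
#' @param network a [gene_network()].
#' @param ds a \code{datastore}.
#' @param ref_org reference organism code.
#' @param identity_grid numeric vector of identity thresholds in [0, 1].
#' @param cfg a [filter_config()]; its \code{identity_min} is replaced
#'   by each grid value in turn.
#' @return An object of class \code{sweep_result}: \code{grid} data
#'   frame (\code{sw_min}, \code{identity_min}, \code{domain_T},
#'   \code{gene_set_pai}, \code{network_pai}) and \code{pai_matrix}
#'   (genes x thresholds).
#' @export
threshold_sweep <- function(network, ds, ref_org, identity_grid,
                            cfg = filter_config()) {
  if (length(identity_grid) == 0) stop("empty identity grid")
  if (any(identity_grid < 0 | identity_grid > 1))
    stop("identity thresholds must lie in [0, 1]")
  rows <- list()
  mats <- list()
  for (idm in identity_grid) {
    cfg_i <- cfg
    cfg_i$identity_min <- idm
    fit <- evo_analysis(network, ds, ref_org, cfg_i, di = FALSE)
    pai <- vapply(fit$pai, `[[`, 0L, "pai")
    rows[[length(rows) + 1]] <- data.frame(
      sw_min = cfg$sw_min, identity_min = idm,
      domain_T = cfg$domain_threshold_T,
      gene_set_pai = fit$summary$gene_set_pai,
      network_pai = fit$summary$network_pai)
    mats[[length(mats) + 1]] <- pai
  }
  pm <- do.call(cbind, mats)
  colnames(pm) <- as.character(identity_grid)
  structure(list(grid = do.call(rbind, rows), pai_matrix = pm,
                 ref_org = ref_org),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> ", nrow(x$grid), " threshold setting(s)\n", sep = "")
  print(x$grid, row.names = FALSE)
  invisible(x)
}
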