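#' Render a static HTML report for one or more analysed networks
#'
#' Writes an HTML bundle: a global index page with the sweep curve (when
#' a sweep is supplied) and links to one page per network; each network
#' page carries the summary statistics block, the PAI histogram (one bin
#' per integer age level), the per-gene table sorted by divergence index
#' descending with undefined DI last, and the phylogenetic profile.
#' Every plot has a sibling plain-text data file so the numbers behind
#' each figure can be re-used, and all links are relative so the bundle
#' is portable. No JavaScript is used.
#'
#' @param results named list of [evo_analysis()] objects (one per
#'   network; names become page titles).
#' @param outdir output directory (created; must be writable).
#' @param sweeps optional named list of [threshold_sweep()] results
#'   parallel to \code{results}.
#' @param timestamps logical; set \code{FALSE} to omit the generation
#'   time so that re-rendering identical results is byte-identical.
#' @return Path of the index page, invisibly.
#' @export
render_report <- function(results, outdir, sweeps = NULL,
                          timestamps = TRUE) {
  if (is.null(names(results)) || any(!nzchar(names(results))))
    names(results) <- paste0("network_", seq_along(results))
  ok <- dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create report directory: ", outdir)
  probe <- file.path(outdir, ".write_probe")
  if (!isTRUE(file.create(probe, showWarnings = FALSE)))
    stop("report directory is not writable: ", outdir)
  unlink(probe)
  imgdir <- file.path(outdir, "img")
  dir.create(imgdir, showWarnings = FALSE)

  stamp <- if (timestamps)
    paste0("<p class='stamp'>generated ", format(Sys.time()), "</p>")
  else ""

  pages <- character(0)
  for (nm in names(results)) {
    pages[nm] <- render_network_page(nm, results[[nm]],
                                     if (!is.null(sweeps)) sweeps[[nm]],
                                     outdir, imgdir, stamp)
  }

  idx <- file.path(outdir, "index.html")
  body <- c("<h1>Gene network evolutionary analysis</h1>", stamp,
            "<h2>Networks</h2>", "<ul>")
  for (nm in names(results)) {
    s <- results[[nm]]$summary
    body <- c(body, sprintf(
      "<li><a href='%s'>%s</a>: gene set PAI = %s, network PAI = %s, %d genes</li>",
      basename(pages[nm]), html_escape(nm),
      fmt_num(s$gene_set_pai), fmt_num(s$network_pai), s$n_genes))
  }
  body <- c(body, "</ul>")
  writeLines(html_page("Evolutionary analysis report", body), idx)
  invisible(idx)
}

render_network_page <- function(name, fit, sweep, outdir, imgdir, stamp) {
  s <- fit$summary
  slug <- gsub("[^A-Za-z0-9_.-]", "_", name)
  page <- file.path(outdir, paste0(slug, ".html"))

  pai <- vapply(fit$pai, `[[`, 0L, "pai")
  counts <- pai_histogram(pai)
  hist_png <- file.path(imgdir, paste0(slug, "_pai_hist.png"))
  hist_txt <- paste0(hist_png, ".txt")
  grDevices::png(hist_png, width = 640, height = 420)
  graphics::barplot(counts, xlab = "PAI", ylab = "genes",
                    main = paste("PAI distribution:", name))
  grDevices::dev.off()
  write_tsv_table(data.frame(pai = names(counts),
                             n_genes = as.integer(counts)), hist_txt)

  sweep_html <- ""
  if (!is.null(sweep)) {
    sw_png <- file.path(imgdir, paste0(slug, "_sweep.png"))
    sw_txt <- paste0(sw_png, ".txt")
    grDevices::png(sw_png, width = 640, height = 420)
    graphics::plot(sweep$grid$identity_min, sweep$grid$gene_set_pai,
                   type = "b", xlab = "identity threshold",
                   ylab = "gene set PAI",
                   main = paste("Threshold sweep:", name))
    grDevices::dev.off()
    write_tsv_table(sweep$grid, sw_txt)
    sweep_html <- c("<h2>Identity threshold sweep</h2>",
                    sprintf("<img src='img/%s'/>", basename(sw_png)),
                    sprintf("<p><a href='img/%s'>plot data</a></p>",
                            basename(sw_txt)))
  }

  tab <- as.data.frame(fit)
  if ("di" %in% names(tab)) {
    ord <- order(!is.finite(tab$di), -ifelse(is.finite(tab$di), tab$di, 0))
    tab <- tab[ord, , drop = FALSE]
  }
  gene_table <- df_to_html_table(tab)

  prof <- fit$profile
  prof_html <- if (nrow(prof) > 0) {
    pf <- data.frame(org_code = rownames(prof), prof, check.names = FALSE)
    df_to_html_table(pf)
  } else "<p>no organism carries an ortholog of any network gene</p>"

  body <- c(sprintf("<h1>%s</h1>", html_escape(name)), stamp,
            "<p><a href='index.html'>back to report index</a></p>",
            "<h2>Summary statistics</h2>",
            "<ul>",
            sprintf("<li>Gene set PAI = %s</li>", fmt_num(s$gene_set_pai)),
            sprintf("<li>Network PAI = %s</li>", fmt_num(s$network_pai)),
            sprintf("<li>Median taxon = %s</li>", html_escape(s$median_taxon)),
            sprintf("<li>Oldest taxon = %s</li>", html_escape(s$oldest_taxon)),
            sprintf("<li>Youngest taxon = %s</li>",
                    html_escape(s$youngest_taxon)),
            sprintf("<li>Total orthologs analyzed = %d</li>",
                    s$total_orthologs),
            "</ul>",
            "<h2>PAI distribution</h2>",
            sprintf("<img src='img/%s'/>", basename(hist_png)),
            sprintf("<p><a href='img/%s'>plot data</a></p>",
                    basename(hist_txt)),
            sweep_html,
            "<h2>Genes (sorted by DI, undefined last)</h2>", gene_table,
            "<h2>Phylogenetic profile</h2>", prof_html)
  writeLines(html_page(name, body), page)
  page
}

fmt_num <- function(x) formatC(x, digits = 6, format = "g")

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_page <- function(title, body) {
  c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'/>",
    sprintf("<title>%s</title>", html_escape(title)),
    "<style>body{font-family:sans-serif;margin:2em}",
    "table{border-collapse:collapse}",
    "td,th{border:1px solid #999;padding:2px 6px}",
    ".stamp{color:#777;font-size:small}</style>",
    "</head><body>", body, "</body></html>")
}

df_to_html_table <- function(df) {
  fmt_cell <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "", fmt_num(x)) else html_escape(as.character(x))
  }
  cells <- vapply(df, function(col) as.character(fmt_cell(col)),
                  character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  head_row <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                    collapse = ""), "</tr>")
  body_rows <- apply(cells, 1, function(r)
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>"))
  paste0("<table>", head_row, paste(body_rows, collapse = ""), "</table>")
}
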