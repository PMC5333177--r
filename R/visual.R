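#' Map gene values to colors
#'
#' Min-max normalizes the values to [0, 1] and interpolates a color
#' scheme: \code{"heatmap"} runs blue - cyan - green - yellow - red
#' through anchors at 0, 0.25, 0.5, 0.75, 1 (old genes blue, young genes
#' red); \code{"blue_white_red"} runs blue - white - red with white at
#' 0.5. Constant input maps every gene to the 0.5 anchor.
#'
#' @param values named numeric vector (gene or node id to value).
#' @param scheme \code{"heatmap"} or \code{"blue_white_red"}.
#' @return Named character vector of hex colors (\code{"#RRGGBB"}).
#' @export
color_scale <- function(values, scheme = c("heatmap", "blue_white_red")) {
  scheme <- match.arg(scheme)
  if (length(values) == 0) stop("no values to color")
  rng <- range(values)
  t <- if (rng[1] == rng[2]) rep(0.5, length(values))
       else (values - rng[1]) / (rng[2] - rng[1])
  anchors <- switch(scheme,
    heatmap = list(pos = c(0, .25, .5, .75, 1),
                   col = rbind(c(0, 0, 255), c(0, 255, 255), c(0, 255, 0),
                               c(255, 255, 0), c(255, 0, 0))),
    blue_white_red = list(pos = c(0, .5, 1),
                          col = rbind(c(0, 0, 255), c(255, 255, 255),
                                      c(255, 0, 0))))
  rgb_mat <- vapply(t, function(ti) {
    i <- findInterval(ti, anchors$pos, rightmost.closed = TRUE)
    p0 <- anchors$pos[i]; p1 <- anchors$pos[i + 1]
    w <- (ti - p0) / (p1 - p0)
    round((1 - w) * anchors$col[i, ] + w * anchors$col[i + 1, ])
  }, numeric(3))
  out <- grDevices::rgb(rgb_mat[1, ], rgb_mat[2, ], rgb_mat[3, ],
                        maxColorValue = 255)
  stats::setNames(out, names(values))
}

#' Concentric-ring layout by age index
#'
#' Places gene nodes on concentric circles, one circle per distinct PAI
#' value: distinct values sorted ascending take radii
#' \code{r0 * (1 + rank)} (rank 0 innermost), and genes sharing a PAI
#' are spaced evenly around their circle. Radius rank rather than raw
#' PAI keeps sparse age sets readable. Compound and map nodes are placed
#' on separate outermost circles, one per type.
#'
#' @param network a [gene_network()].
#' @param pai named numeric vector of PAI values keyed by gene node id.
#' @param r0 base radius (default 1).
#' @return Data frame with columns \code{node_id}, \code{x}, \code{y},
#'   \code{radius}.
#' @export
layout_rings <- function(network, pai, r0 = 1) {
  gn <- gene_nodes(network)
  miss <- setdiff(gn$node_id, names(pai))
  if (length(miss) > 0)
    stop("missing PAI for gene node(s): ", paste(miss, collapse = ","))
  levels_sorted <- sort(unique(unname(pai[gn$node_id])))
  ring_of <- match(pai[gn$node_id], levels_sorted)  # 1-based rank
  rows <- list()
  place <- function(ids, radius) {
    n <- length(ids)
    ang <- 2 * pi * (seq_len(n) - 1) / n
    data.frame(node_id = ids, x = radius * cos(ang), y = radius * sin(ang),
               radius = radius, stringsAsFactors = FALSE)
  }
  for (k in seq_along(levels_sorted)) {
    ids <- gn$node_id[ring_of == k]
    rows[[length(rows) + 1]] <- place(sort(ids), r0 * (1 + (k - 1)))
  }
  next_radius <- r0 * (1 + length(levels_sorted))
  for (tp in c("compound", "map")) {
    ids <- network$nodes$node_id[network$nodes$type == tp]
    if (length(ids) > 0) {
      rows[[length(rows) + 1]] <- place(sort(ids), next_radius)
      next_radius <- next_radius + r0
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
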