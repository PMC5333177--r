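#' Nei-Gojobori (1986) Ka/Ks estimation on a codon alignment
#'
#' Counts synonymous and nonsynonymous sites and differences with the
#' NG86 method and applies the Jukes-Cantor correction.
#'
#' Sites: each codon contributes, per position, the fraction of its three
#' single-nucleotide neighbours that are synonymous (changes to stop
#' codons count as nonsynonymous); totals are averaged over the two
#' sequences. Differences: codon pairs differing at k positions are
#' scored by averaging the synonymous/nonsynonymous step counts over all
#' k! minimal substitution pathways with equal weight. Columns containing
#' a gap codon or a stop codon are excluded.
#'
#' Correction: \code{d = -(3/4) * log(1 - (4/3) * p)} for \code{p = pN}
#' and \code{pS}. Status is \code{"saturated"} when either proportion
#' reaches 3/4 (the correction diverges), \code{"undefined_ks_zero"} when
#' no synonymous difference is observed (Ka/Ks undefined), otherwise
#' \code{"ok"}.
#'
#' @param ca a [codon_align()] result.
#' @return A list of class \code{kaks_result}: \code{ka}, \code{ks},
#'   \code{pn}, \code{ps}, \code{n_sites}, \code{s_sites}, \code{nd},
#'   \code{sd}, \code{n_codons} (countable columns), \code{status}.
#' @references Nei M, Gojobori T (1986) Mol Biol Evol 3(5):418-426.
#' @export
kaks_ng86 <- function(ca) {
  stopifnot(inherits(ca, "codon_alignment"))
  a <- ca$codons_a
  b <- ca$codons_b
  is_stop <- function(x) !is.na(GENETIC_CODE_TABLE[x]) &
    GENETIC_CODE_TABLE[x] == "*"
  countable <- a != "---" & b != "---" & !is_stop(a) & !is_stop(b)
  a <- a[countable]; b <- b[countable]
  if (length(a) == 0) stop("no countable codon columns in alignment")

  s_a <- sum(syn_site_fraction(a))
  s_b <- sum(syn_site_fraction(b))
  s_sites <- (s_a + s_b) / 2
  n_sites <- 3 * length(a) - s_sites

  dd <- pair_differences(a, b)
  sd <- dd[["sd"]]; nd <- dd[["nd"]]

  ps <- if (s_sites > 0) sd / s_sites else 0
  pn <- if (n_sites > 0) nd / n_sites else 0
  jc <- function(p) -3 / 4 * log(1 - 4 / 3 * p)

  status <- if (ps >= 3 / 4 || pn >= 3 / 4) "saturated"
            else if (sd == 0) "undefined_ks_zero"
            else "ok"
  ka <- if (pn < 3 / 4) jc(pn) else NA_real_
  ks <- if (ps < 3 / 4) jc(ps) else NA_real_
  structure(list(ka = ka, ks = ks, pn = pn, ps = ps,
                 n_sites = n_sites, s_sites = s_sites, nd = nd, sd = sd,
                 n_codons = length(a), status = status),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat("NG86: Ka = ", signif(x$ka, 6), " (", x$nd, "/", signif(x$n_sites, 6),
      "), Ks = ", signif(x$ks, 6), " (", x$sd, "/", signif(x$s_sites, 6),
      "), status ", x$status, "\n", sep = "")
  invisible(x)
}

# per-codon synonymous site fraction: sum over positions of
# (#synonymous single-nt neighbours)/3; stop neighbours are nonsynonymous
syn_site_fraction <- function(codons) {
  unname(ng86_site_table()[codons])
}

pair_differences <- function(a, b) {
  tab <- ng86_diff_table()
  keys <- paste0(a, b)
  sd <- sum(tab$sd[match(keys, tab$key)])
  nd <- sum(tab$nd[match(keys, tab$key)])
  c(sd = sd, nd = nd)
}

.ng86_cache <- new.env(parent = emptyenv())

ng86_site_table <- function() {
  if (!is.null(.ng86_cache$sites)) return(.ng86_cache$sites)
  codons <- names(GENETIC_CODE_TABLE)
  bases <- c("T", "C", "A", "G")
  s <- vapply(codons, function(cd) {
    aa <- GENETIC_CODE_TABLE[[cd]]
    tot <- 0
    for (pos in 1:3) {
      for (bb in setdiff(bases, substr(cd, pos, pos))) {
        nb <- cd
        substr(nb, pos, pos) <- bb
        if (GENETIC_CODE_TABLE[[nb]] == aa) tot <- tot + 1 / 3
      }
    }
    tot
  }, 0)
  .ng86_cache$sites <- s
  s
}

# averaged (Sd, Nd) for every ordered codon pair; k! equal-weight paths
ng86_diff_table <- function() {
  if (!is.null(.ng86_cache$diff)) return(.ng86_cache$diff)
  codons <- names(GENETIC_CODE_TABLE)
  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  n <- length(codons)
  key <- character(n * n); sd <- numeric(n * n); nd <- numeric(n * n)
  idx <- 0L
  for (c1 in codons) {
    s1 <- strsplit(c1, "")[[1]]
    for (c2 in codons) {
      idx <- idx + 1L
      key[idx] <- paste0(c1, c2)
      if (c1 == c2) next
      s2 <- strsplit(c2, "")[[1]]
      pos <- which(s1 != s2)
      ways <- perms[[as.character(length(pos))]]
      tot_s <- 0; tot_n <- 0
      for (ord in ways) {
        cur <- s1
        for (p in pos[ord]) {
          prev_aa <- GENETIC_CODE_TABLE[[paste(cur, collapse = "")]]
          cur[p] <- s2[p]
          new_aa <- GENETIC_CODE_TABLE[[paste(cur, collapse = "")]]
          if (new_aa == prev_aa) tot_s <- tot_s + 1 else tot_n <- tot_n + 1
        }
      }
      sd[idx] <- tot_s / length(ways)
      nd[idx] <- tot_n / length(ways)
    }
  }
  .ng86_cache$diff <- list(key = key, sd = sd, nd = nd)
  .ng86_cache$diff
}
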