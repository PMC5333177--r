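# Shared fixtures and independent oracles. Oracles here are written from
# first principles (brute force / enumeration) and never call the package
# code paths they check.

# Human-like taxonomy with the canonical depth anchors:
# root=0, Eukaryota=1, Vertebrata=5, Mammalia=7, Hominidae=13, Homo=14.
# Bonobo diverges below Hominidae (LCA with human = 13), opossum below
# Mammalia (LCA = 7), mouse below Euarchontoglires (LCA = 10), fly below
# Metazoa (LCA = 3).
human_like_organisms <- function() {
  hsa <- c("Cellular Organisms", "Eukaryota", "Opisthokonta", "Metazoa",
           "Chordata", "Vertebrata", "Tetrapoda", "Mammalia", "Theria",
           "Eutheria", "Euarchontoglires", "Primates", "Haplorrhini",
           "Hominidae", "Homo")
  pps <- c(hsa[1:14], "Pan paniscus")
  mdo <- c(hsa[1:8], "Metatheria", "Didelphimorphia", "Didelphidae",
           "Monodelphis")
  mmu <- c(hsa[1:11], "Glires", "Rodentia", "Mus")
  dme <- c(hsa[1:4], "Arthropoda", "Insecta", "Drosophila")
  data.frame(
    org_code = c("hsa", "pps", "mdo", "mmu", "dme"),
    name = c("human", "bonobo", "opossum", "mouse", "fly"),
    lineage = vapply(list(hsa, pps, mdo, mmu, dme), paste, "",
                     collapse = ";"),
    stringsAsFactors = FALSE)
}

human_like_tree <- function() build_taxonomy(human_like_organisms())

# A small hand-built datastore over the human-like taxonomy: three human
# network genes with orthologs at different depths plus paralog links.
toy_datastore <- function() {
  org <- human_like_organisms()
  genes <- data.frame(
    gene_id = c("hsa:1", "hsa:2", "hsa:3",
                "pps:1", "pps:2", "mdo:1", "mmu:3", "dme:1"),
    org_code = c("hsa", "hsa", "hsa", "pps", "pps", "mdo", "mmu", "dme"),
    label = c("A", "B", "C", "A'", "B'", "A''", "C'", "A'''"),
    annotation = "",
    stringsAsFactors = FALSE)
  hits <- data.frame(
    query_gene = c("hsa:1", "hsa:1", "hsa:1", "hsa:2", "hsa:3", "hsa:1"),
    subject_gene = c("pps:1", "mdo:1", "dme:1", "pps:2", "mmu:3", "hsa:2"),
    sw_score = c(1500, 900, 600, 1200, 800, 700),
    identity = c(0.95, 0.7, 0.55, 0.9, 0.65, 0.6),
    stringsAsFactors = FALSE)
  domains <- data.frame(
    gene_id = c("hsa:1", "pps:1", "mdo:1", "dme:1", "hsa:2", "pps:2",
                "hsa:3", "mmu:3"),
    domain_id = c("PF_A", "PF_A", "PF_A", "PF_B", "PF_A", "PF_A",
                  "PF_C", "PF_C"),
    stringsAsFactors = FALSE)
  new_datastore(org, genes, hits, domains)
}

toy_network <- function() {
  nodes <- data.frame(
    node_id = c("n1", "n2", "n3", "c1"),
    type = c("gene", "gene", "gene", "compound"),
    gene_id = c("hsa:1", "hsa:2", "hsa:3", ""),
    label = c("A", "B", "C", "cpd"),
    stringsAsFactors = FALSE)
  edges <- data.frame(from = c("n1", "n2", "n3"),
                      to = c("n2", "c1", "c1"),
                      interaction = "",
                      stringsAsFactors = FALSE)
  gene_network(nodes, edges)
}

# ---- independent oracles ---------------------------------------------------

# exhaustive global-alignment score: enumerates every alignment as a path
# of match / gap-in-b / gap-in-a moves with affine run-aware scoring
nw_enum_score <- function(a, b, mat, open = 11, ext = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  best <- -Inf
  rec <- function(i, j, last, sc) {
    if (i > na && j > nb) {
      if (sc > best) best <<- sc
      return(invisible(NULL))
    }
    if (i <= na && j <= nb)
      rec(i + 1L, j + 1L, "m", sc + mat[ca[i], cb[j]])
    if (i <= na)
      rec(i + 1L, j, "ga", sc - ext - if (identical(last, "ga")) 0 else open)
    if (j <= nb)
      rec(i, j + 1L, "gb", sc - ext - if (identical(last, "gb")) 0 else open)
  }
  rec(1L, 1L, "none", 0)
  best
}

# NG86 from first principles on two gap/stop-free codon vectors, using the
# genetic code shipped with Biostrings
ng86_oracle <- function(cod_a, cod_b) {
  gc_map <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  syn_frac <- function(cd) {
    s <- 0
    for (p in 1:3) {
      ref <- substr(cd, p, p)
      for (bb in bases[bases != ref]) {
        alt <- cd
        substr(alt, p, p) <- bb
        if (gc_map[[alt]] == gc_map[[cd]]) s <- s + 1 / 3
      }
    }
    s
  }
  all_perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (k in seq_along(v))
      for (rest in all_perms(v[-k]))
        out[[length(out) + 1]] <- c(v[k], rest)
    out
  }
  diff_counts <- function(c1, c2) {
    if (c1 == c2) return(c(0, 0))
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    paths <- all_perms(pos)
    tot <- c(0, 0)
    for (path in paths) {
      cur <- c1
      for (p in path) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (gc_map[[nxt]] == gc_map[[cur]]) tot[1] <- tot[1] + 1
        else tot[2] <- tot[2] + 1
        cur <- nxt
      }
    }
    tot / length(paths)
  }
  s_sites <- (sum(vapply(cod_a, syn_frac, 0)) +
              sum(vapply(cod_b, syn_frac, 0))) / 2
  n_sites <- 3 * length(cod_a) - s_sites
  sd <- 0; nd <- 0
  for (k in seq_along(cod_a)) {
    d <- diff_counts(cod_a[k], cod_b[k])
    sd <- sd + d[1]; nd <- nd + d[2]
  }
  ps <- if (s_sites > 0) sd / s_sites else 0
  pn <- if (n_sites > 0) nd / n_sites else 0
  jc <- function(p) if (p < 3 / 4) -3 / 4 * log(1 - 4 / 3 * p) else NA_real_
  list(s_sites = s_sites, n_sites = n_sites, sd = sd, nd = nd,
       ps = ps, pn = pn, ka = jc(pn), ks = jc(ps))
}

# connected components by breadth-first search over an edge list
components_oracle <- function(vertices, edge_a, edge_b) {
  comp <- stats::setNames(rep(NA_integer_, length(vertices)), vertices)
  cur <- 0L
  for (v in vertices) {
    if (!is.na(comp[[v]])) next
    cur <- cur + 1L
    queue <- v
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[[u]])) next
      comp[[u]] <- cur
      nb <- c(edge_b[edge_a == u], edge_a[edge_b == u])
      queue <- c(queue, setdiff(nb, names(comp)[!is.na(comp)]))
    }
  }
  comp
}

# random protein / codon helpers for property tests
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")
SENSE_CODONS <- names(Biostrings::GENETIC_CODE)[
  Biostrings::GENETIC_CODE != "*"]
random_codons <- function(n) sample(SENSE_CODONS, n, replace = TRUE)

empty_domains_df <- function() {
  data.frame(gene_id = character(0), domain_id = character(0),
             stringsAsFactors = FALSE)
}

unrowname <- function(d) { rownames(d) <- NULL; d }

codon_alignment_from <- function(cod_a, cod_b) {
  structure(list(codons_a = cod_a, codons_b = cod_b),
            class = "codon_alignment")
}
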