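#' Configuration for the synthetic-data generator
#'
#' The generator plants known ground truth so the whole pipeline can be
#' validated offline: each reference gene is given a birth level b and
#' receives orthologs only inside the clade at depth b of the reference
#' lineage (always including one organism diverging exactly at that
#' boundary), so its true PAI equals b; ortholog sequences are mutated
#' copies of the reference CDS with planted synonymous and nonsynonymous
#' substitution counts, so the true Ka and Ks are known.
#'
#' @param seed integer seed; the generator is fully deterministic per
#'   seed (R's default Mersenne-Twister stream).
#' @param lineage_depth terminal depth N of the reference lineage
#'   (default 14, the human-like depth).
#' @param branching organisms diverging at each lineage level (default 2).
#' @param n_genes number of reference genes (default 20).
#' @param birth_levels optional integer vector in [0, N] fixing each
#'   gene's birth level; sampled uniformly when \code{NULL}.
#' @param ortholog_density probability that an eligible (non-boundary)
#'   organism carries an ortholog (default 1, i.e. full sampling).
#' @param codon_length CDS length in codons (default 300).
#' @param target_ka,target_ks planted nonsynonymous / synonymous
#'   divergence per site (defaults 0.05 and 0.15: a moderately conserved
#'   ortholog pair under purifying selection, Ka/Ks about 1/3).
#' @param network_density probability of an edge between two gene nodes
#'   (default 0.15).
#' @param paralog_pairs optional 2-column matrix of reference gene
#'   indices to connect with within-organism homology hits (planted
#'   clusters); none by default.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1, lineage_depth = 14, branching = 2,
                       n_genes = 20, birth_levels = NULL,
                       ortholog_density = 1, codon_length = 300,
                       target_ka = 0.05, target_ks = 0.15,
                       network_density = 0.15, paralog_pairs = NULL) {
  stopifnot(lineage_depth >= 1, branching >= 1, n_genes >= 1,
            ortholog_density > 0, ortholog_density <= 1,
            codon_length >= 1, target_ka >= 0, target_ks >= 0,
            network_density > 0, network_density <= 1)
  if (!is.null(birth_levels))
    stopifnot(length(birth_levels) == n_genes,
              all(birth_levels >= 0), all(birth_levels <= lineage_depth))
  structure(list(seed = as.integer(seed), lineage_depth = lineage_depth,
                 branching = branching, n_genes = n_genes,
                 birth_levels = birth_levels,
                 ortholog_density = ortholog_density,
                 codon_length = codon_length, target_ka = target_ka,
                 target_ks = target_ks, network_density = network_density,
                 paralog_pairs = paralog_pairs),
            class = "sim_config")
}

#' Generate a synthetic organisms table
#'
#' Builds a reference organism (\code{"ref"}) with a lineage of depth N
#' rooted at "Cellular Organisms", plus \code{branching} organisms
#' diverging immediately below every level d in 0..N-1, so that every
#' possible LCA depth with the reference is attainable.
#'
#' @param cfg a [sim_config()].
#' @return Data frame with columns \code{org_code}, \code{name},
#'   \code{lineage} (semicolon-joined).
#' @export
make_taxonomy <- function(cfg) {
  n <- cfg$lineage_depth
  ref_lineage <- c("Cellular Organisms",
                   sprintf("clade_%02d", seq_len(n)))
  rows <- list(data.frame(org_code = "ref", name = "reference organism",
                          lineage = paste(ref_lineage, collapse = ";"),
                          stringsAsFactors = FALSE))
  for (d in 0:(n - 1)) {
    for (j in seq_len(cfg$branching)) {
      code <- sprintf("o%02d%s", d, letters[j])
      lin <- c(ref_lineage[seq_len(d + 1)],
               sprintf("offshoot_%02d_%s", d, letters[j]),
               sprintf("species_%02d_%s", d, letters[j]))
      rows[[length(rows) + 1]] <- data.frame(
        org_code = code,
        name = sprintf("synthetic organism (diverged at depth %d)", d),
        lineage = paste(lin, collapse = ";"), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate synthetic genes, hits, domains and sequences
#'
#' For each reference gene with birth level b, plants ortholog genes in
#' organisms whose LCA depth with the reference is at least b: the
#' boundary organism (LCA exactly b) is always included so the true PAI
#' is exactly b, and other eligible organisms are included with
#' probability \code{ortholog_density}. Hit scores and identities are
#' drawn above the default thresholds (SW in [600, 2000], identity in
#' [0.6, 0.99]). Each gene family is annotated with its own domain, and
#' ortholog sequences are mutated copies of the reference CDS with the
#' configured target divergence.
#'
#' @param cfg a [sim_config()].
#' @param organisms a [make_taxonomy()] table.
#' @return A list: \code{genes}, \code{hits}, \code{domains} data
#'   frames, \code{nt_seqs}, \code{aa_seqs}, and \code{truth} (gene_id,
#'   birth_level, ortholog organisms).
#' @export
make_gene_set <- function(cfg, organisms) {
  n <- cfg$lineage_depth
  div_depth <- rep(n, nrow(organisms))
  off <- organisms$org_code != "ref"
  div_depth[off] <- as.integer(substr(organisms$org_code[off], 2, 3))
  names(div_depth) <- organisms$org_code
  births <- cfg$birth_levels
  if (is.null(births)) births <- sample(0:n, cfg$n_genes, replace = TRUE)

  genes <- list(); hits <- list(); domains <- list()
  nt <- character(0); aa <- character(0)
  truth <- list()
  for (i in seq_len(cfg$n_genes)) {
    g <- sprintf("ref:g%03d", i)
    b <- births[i]
    genes[[length(genes) + 1]] <- data.frame(
      gene_id = g, org_code = "ref",
      label = sprintf("G%03d", i), annotation = sprintf("birth level %d", b),
      stringsAsFactors = FALSE)
    dom <- sprintf("dom_fam%03d", i)
    domains[[length(domains) + 1]] <- data.frame(gene_id = g,
                                                 domain_id = dom,
                                                 stringsAsFactors = FALSE)
    anc <- random_cds(cfg$codon_length)
    nt[g] <- anc
    aa[g] <- paste(translate_codons(codon_split(anc)), collapse = "")

    others <- organisms$org_code[organisms$org_code != "ref"]
    eligible <- others[div_depth[others] >= b]
    boundary <- eligible[div_depth[eligible] == b]
    chosen <- character(0)
    if (length(boundary) > 0) chosen <- boundary[1]
    rest <- setdiff(eligible, chosen)
    if (length(rest) > 0)
      chosen <- c(chosen, rest[stats::runif(length(rest)) <=
                                 cfg$ortholog_density])
    for (o in chosen) {
      og <- sprintf("%s:g%03d", o, i)
      genes[[length(genes) + 1]] <- data.frame(
        gene_id = og, org_code = o,
        label = sprintf("G%03d", i), annotation = "planted ortholog",
        stringsAsFactors = FALSE)
      domains[[length(domains) + 1]] <- data.frame(gene_id = og,
                                                   domain_id = dom,
                                                   stringsAsFactors = FALSE)
      mut <- mutate_cds(anc, cfg$target_ka, cfg$target_ks)
      nt[og] <- mut$nt
      aa[og] <- mut$aa
      hits[[length(hits) + 1]] <- data.frame(
        query_gene = g, subject_gene = og,
        sw_score = stats::runif(1, 600, 2000),
        identity = stats::runif(1, 0.6, 0.99), stringsAsFactors = FALSE)
    }
    truth[[length(truth) + 1]] <- data.frame(
      gene_id = g, birth_level = b,
      n_planted_orthologs = length(chosen),
      ortholog_orgs = paste(sort(chosen), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (!is.null(cfg$paralog_pairs)) {
    for (r in seq_len(nrow(cfg$paralog_pairs))) {
      a <- sprintf("ref:g%03d", cfg$paralog_pairs[r, 1])
      bb <- sprintf("ref:g%03d", cfg$paralog_pairs[r, 2])
      hits[[length(hits) + 1]] <- data.frame(
        query_gene = a, subject_gene = bb,
        sw_score = stats::runif(1, 600, 2000),
        identity = stats::runif(1, 0.6, 0.99), stringsAsFactors = FALSE)
    }
  }
  list(genes = do.call(rbind, genes),
       hits = if (length(hits) > 0) do.call(rbind, hits) else empty_hits(),
       domains = do.call(rbind, domains),
       nt_seqs = nt, aa_seqs = aa,
       truth = do.call(rbind, truth))
}

#' Generate a diverged codon-sequence pair with known substitution counts
#'
#' Draws a random ancestral CDS and mutates a copy by planting
#' independent synonymous and nonsynonymous single-nucleotide changes at
#' distinct codons: \code{round(target_ks * S)} synonymous and
#' \code{round(target_ka * N)} nonsynonymous changes, where S and N are
#' the NG86 site counts of the ancestral sequence. No stop codons are
#' ever introduced. The planted values are returned both as raw counts
#' and as Jukes-Cantor-corrected per-site rates.
#'
#' @param cfg a [sim_config()] (uses \code{codon_length},
#'   \code{target_ka}, \code{target_ks}).
#' @return A list: \code{nt_a}, \code{aa_a}, \code{nt_b}, \code{aa_b},
#'   \code{n_syn}, \code{n_nonsyn}, \code{planted_ks}, \code{planted_ka}
#'   (corrected rates on the ancestral site counts).
#' @export
make_codon_pair <- function(cfg) {
  anc <- random_cds(cfg$codon_length)
  mut <- mutate_cds(anc, cfg$target_ka, cfg$target_ks)
  list(nt_a = anc,
       aa_a = paste(translate_codons(codon_split(anc)), collapse = ""),
       nt_b = mut$nt, aa_b = mut$aa,
       n_syn = mut$n_syn, n_nonsyn = mut$n_nonsyn,
       planted_ks = mut$planted_ks, planted_ka = mut$planted_ka)
}

#' Generate a complete synthetic analysis input
#'
#' Assembles a validated datastore, a gene network over the reference
#' genes (with a few compound nodes, edges drawn at the configured
#' density) and the ground-truth table, all deterministically from the
#' seed.
#'
#' @param cfg a [sim_config()].
#' @return A list: \code{datastore}, \code{network}, \code{ref_org}
#'   (\code{"ref"}), \code{truth}, \code{config}.
#' @export
simulate_datastore <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  organisms <- make_taxonomy(cfg)
  gs <- make_gene_set(cfg, organisms)
  ds <- new_datastore(organisms, gs$genes, gs$hits, gs$domains,
                      gs$nt_seqs, gs$aa_seqs)
  bad <- validate_datastore(ds)
  if (length(bad) > 0)
    stop("internal error: generated datastore invalid: ",
         paste(bad, collapse = "; "))

  ref_genes <- gs$truth$gene_id
  nodes <- data.frame(node_id = paste0("n_", ref_genes), type = "gene",
                      gene_id = ref_genes,
                      label = sub("^ref:", "", ref_genes),
                      stringsAsFactors = FALSE)
  n_comp <- max(1L, round(cfg$n_genes / 10))
  comp <- data.frame(node_id = sprintf("cpd_%02d", seq_len(n_comp)),
                     type = "compound", gene_id = "",
                     label = sprintf("C%05d", seq_len(n_comp)),
                     stringsAsFactors = FALSE)
  nodes <- rbind(nodes, comp)
  gene_ids <- nodes$node_id[nodes$type == "gene"]
  edges <- data.frame(from = character(0), to = character(0),
                      interaction = character(0), stringsAsFactors = FALSE)
  if (length(gene_ids) >= 2) {
    pairs <- utils::combn(gene_ids, 2)
    keep <- stats::runif(ncol(pairs)) <= cfg$network_density
    if (any(keep))
      edges <- data.frame(from = pairs[1, keep], to = pairs[2, keep],
                          interaction = "assoc", stringsAsFactors = FALSE)
  }
  # anchor every compound to the first gene so the network is well formed
  edges <- rbind(edges,
                 data.frame(from = comp$node_id, to = nodes$node_id[1],
                            interaction = "reaction",
                            stringsAsFactors = FALSE))
  network <- gene_network(nodes, edges)
  list(datastore = ds, network = network, ref_org = "ref",
       truth = gs$truth, config = cfg)
}

# ---- sequence-level helpers -----------------------------------------------

codon_split <- function(nt) {
  substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
}

NONSTOP_CODONS <- local({
  cods <- names(GENETIC_CODE_TABLE)
  cods[GENETIC_CODE_TABLE[cods] != "*"]
})

random_cds <- function(n_codons) {
  paste(sample(NONSTOP_CODONS, n_codons, replace = TRUE), collapse = "")
}

# single-nucleotide neighbours of a codon, split by substitution class
codon_neighbours <- function(codon) {
  aa <- GENETIC_CODE_TABLE[[codon]]
  bases <- c("T", "C", "A", "G")
  syn <- character(0); nonsyn <- character(0)
  for (pos in 1:3) {
    for (bb in setdiff(bases, substr(codon, pos, pos))) {
      nb <- codon
      substr(nb, pos, pos) <- bb
      nb_aa <- GENETIC_CODE_TABLE[[nb]]
      if (nb_aa == "*") next  # never introduce stops
      if (nb_aa == aa) syn <- c(syn, nb) else nonsyn <- c(nonsyn, nb)
    }
  }
  list(syn = syn, nonsyn = nonsyn)
}

mutate_cds <- function(anc_nt, target_ka, target_ks) {
  codons <- codon_split(anc_nt)
  s_sites <- sum(syn_site_fraction(codons))
  n_sites <- 3 * length(codons) - s_sites
  n_syn <- round(target_ks * s_sites)
  n_nonsyn <- round(target_ka * n_sites)

  has_syn <- vapply(codons,
                    function(cd) length(codon_neighbours(cd)$syn) > 0, TRUE)
  has_nonsyn <- vapply(codons,
                       function(cd) length(codon_neighbours(cd)$nonsyn) > 0,
                       TRUE)
  avail <- seq_along(codons)
  pick <- function(ok, k) {
    if (k == 0) return(integer(0))
    cand <- intersect(avail, which(ok))
    if (length(cand) < k)
      stop("sequence too short to plant ", k, " changes")
    chosen <- cand[sample.int(length(cand), k)]
    avail <<- setdiff(avail, chosen)
    chosen
  }
  out <- codons
  for (i in pick(has_syn, n_syn)) {
    nb <- codon_neighbours(codons[i])$syn
    out[i] <- nb[sample.int(length(nb), 1)]
  }
  for (i in pick(has_nonsyn, n_nonsyn)) {
    nb <- codon_neighbours(codons[i])$nonsyn
    out[i] <- nb[sample.int(length(nb), 1)]
  }
  jc <- function(p) -3 / 4 * log(1 - 4 / 3 * p)
  list(nt = paste(out, collapse = ""),
       aa = paste(translate_codons(out), collapse = ""),
       n_syn = n_syn, n_nonsyn = n_nonsyn,
       planted_ks = jc(n_syn / s_sites),
       planted_ka = jc(n_nonsyn / n_sites))
}
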