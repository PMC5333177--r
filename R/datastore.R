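#' Read a flat-file homology datastore
#'
#' A datastore directory emulates the content a pathway database would
#' supply for evolutionary analysis: organisms with full taxonomic
#' lineages, genes, precomputed pairwise homology hits (Smith-Waterman
#' score and identity), protein-domain annotations, and nucleotide /
#' amino-acid sequences.
#'
#' Expected files (UTF-8, tab-separated, first line a header, lines
#' starting with \code{#} ignored):
#' \describe{
#'   \item{organisms.tsv}{\code{org_code}, \code{name}, \code{lineage}
#'     (semicolon-joined taxon names, root first).}
#'   \item{genes.tsv}{\code{gene_id}, \code{org_code}, \code{label},
#'     \code{annotation}.}
#'   \item{hits.tsv}{\code{query_gene}, \code{subject_gene},
#'     \code{sw_score}, \code{identity}.}
#'   \item{domains.tsv}{\code{gene_id}, \code{domain_id}.}
#'   \item{nt.fasta / aa.fasta}{CDS and protein sequences; FASTA ids are
#'     gene ids. A trailing stop codon on a CDS (nt length = 3*aa + 3) is
#'     trimmed on load.}
#' }
#'
#' @param path directory containing the datastore files.
#' @return An object of class \code{datastore}: a list with data frames
#'   \code{organisms}, \code{genes}, \code{hits}, \code{domains}, the
#'   list-column lineages parsed into character vectors, and named
#'   character vectors \code{nt_seqs}, \code{aa_seqs}.
#' @seealso [validate_datastore()], [write_datastore()], [simulate_datastore()]
#' @export
read_datastore <- function(path) {
  if (!dir.exists(path)) stop("datastore directory not found: ", path)
  need <- c("organisms.tsv", "genes.tsv", "hits.tsv", "domains.tsv",
            "nt.fasta", "aa.fasta")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing) > 0)
    stop("datastore is missing mandatory file(s): ",
         paste(missing, collapse = ", "))

  organisms <- read_tsv_table(file.path(path, "organisms.tsv"),
                              c("org_code", "name", "lineage"))
  genes     <- read_tsv_table(file.path(path, "genes.tsv"),
                              c("gene_id", "org_code", "label", "annotation"))
  hits      <- read_tsv_table(file.path(path, "hits.tsv"),
                              c("query_gene", "subject_gene", "sw_score",
                                "identity"))
  domains   <- read_tsv_table(file.path(path, "domains.tsv"),
                              c("gene_id", "domain_id"))
  hits$sw_score <- as.numeric(hits$sw_score)
  hits$identity <- as.numeric(hits$identity)
  if (anyNA(hits$sw_score) || anyNA(hits$identity))
    stop("hits.tsv: non-numeric sw_score or identity value")

  nt <- read_fasta_vector(file.path(path, "nt.fasta"), "DNA")
  aa <- read_fasta_vector(file.path(path, "aa.fasta"), "AA")

  ds <- new_datastore(organisms, genes, hits, domains, nt, aa)
  bad <- validate_datastore(ds)
  if (length(bad) > 0)
    stop("invalid datastore:\n  ", paste(bad, collapse = "\n  "))
  ds
}

#' Assemble a datastore from in-memory tables
#'
#' Lower-level constructor used by [read_datastore()] and the synthetic
#' generator. Trims trailing stop codons from CDS sequences whose length
#' is 3*aa + 3, and parses lineage strings. No validation is performed;
#' call [validate_datastore()] for that.
#'
#' @param organisms,genes,hits,domains data frames with the columns
#'   documented in [read_datastore()].
#' @param nt_seqs,aa_seqs named character vectors of sequences keyed by
#'   gene id (may be empty).
#' @return A \code{datastore} object.
#' @export
new_datastore <- function(organisms, genes,
                          hits = empty_hits(), domains = empty_domains(),
                          nt_seqs = character(0), aa_seqs = character(0)) {
  organisms$lineage_split <- lapply(strsplit(organisms$lineage, ";",
                                             fixed = TRUE), trimws)
  nt_seqs <- toupper(nt_seqs)
  aa_seqs <- toupper(aa_seqs)
  # trailing stop included by CDS convention: trim when nt = 3*aa + 3
  for (g in names(nt_seqs)) {
    if (g %in% names(aa_seqs) &&
        nchar(nt_seqs[[g]]) == 3L * nchar(aa_seqs[[g]]) + 3L) {
      nt_seqs[[g]] <- substr(nt_seqs[[g]], 1L, nchar(nt_seqs[[g]]) - 3L)
    }
  }
  structure(list(organisms = organisms, genes = genes, hits = hits,
                 domains = domains, nt_seqs = nt_seqs, aa_seqs = aa_seqs),
            class = "datastore")
}

empty_hits <- function() {
  data.frame(query_gene = character(0), subject_gene = character(0),
             sw_score = numeric(0), identity = numeric(0),
             stringsAsFactors = FALSE)
}

empty_domains <- function() {
  data.frame(gene_id = character(0), domain_id = character(0),
             stringsAsFactors = FALSE)
}

#' Validate a datastore against its structural invariants
#'
#' Checks cross-references and type invariants: lineages non-empty with a
#' shared root and no repeated taxon within one lineage; gene org codes
#' known; hit queries/subjects distinct, known, with sw_score >= 0 and
#' identity in [0, 1]; (gene, domain) pairs unique; sequence ids known;
#' and, for genes carrying both sequences, nt length = 3 * aa length
#' (after stop trimming).
#'
#' @param ds a \code{datastore}.
#' @return Character vector of violation messages; empty when valid.
#'   Never throws.
#' @export
validate_datastore <- function(ds) {
  v <- character(0)
  say <- function(...) v <<- c(v, paste0(...))

  org <- ds$organisms
  if (anyDuplicated(org$org_code))
    say("organisms: duplicated org_code ",
        paste(unique(org$org_code[duplicated(org$org_code)]), collapse = ","))
  roots <- character(0)
  for (i in seq_len(nrow(org))) {
    lin <- org$lineage_split[[i]]
    if (length(lin) == 0 || all(lin == ""))
      say("organisms row ", i, ": empty lineage")
    else {
      roots <- c(roots, lin[1])
      if (anyDuplicated(lin))
        say("organisms row ", i, ": repeated taxon in lineage")
    }
  }
  if (length(unique(roots)) > 1)
    say("organisms: lineages do not share a single root (",
        paste(unique(roots), collapse = " / "), ")")

  if (!all(ds$genes$org_code %in% org$org_code))
    say("genes: unknown org_code ",
        paste(unique(setdiff(ds$genes$org_code, org$org_code)), collapse = ","))
  if (anyDuplicated(ds$genes$gene_id))
    say("genes: duplicated gene_id")

  known <- ds$genes$gene_id
  h <- ds$hits
  for (col in c("query_gene", "subject_gene")) {
    bad <- setdiff(unique(h[[col]]), known)
    if (length(bad) > 0)
      say("hits: unknown ", col, " ", paste(bad, collapse = ","))
  }
  if (any(h$query_gene == h$subject_gene))
    say("hits row ", which(h$query_gene == h$subject_gene)[1],
        ": query equals subject")
  if (any(h$sw_score < 0)) say("hits: negative sw_score")
  if (any(h$identity < 0 | h$identity > 1))
    say("hits: identity outside [0,1]")

  bad <- setdiff(unique(ds$domains$gene_id), known)
  if (length(bad) > 0)
    say("domains: unknown gene_id ", paste(bad, collapse = ","))
  if (anyDuplicated(ds$domains))
    say("domains: duplicated (gene_id, domain_id) pair")

  for (nm in c("nt_seqs", "aa_seqs")) {
    bad <- setdiff(names(ds[[nm]]), known)
    if (length(bad) > 0)
      say(nm, ": sequence for unknown gene ", paste(bad, collapse = ","))
  }
  both <- intersect(names(ds$nt_seqs), names(ds$aa_seqs))
  for (g in both) {
    if (nchar(ds$nt_seqs[[g]]) != 3L * nchar(ds$aa_seqs[[g]]))
      say("sequences for ", g, ": nt length ", nchar(ds$nt_seqs[[g]]),
          " is not 3 x aa length ", nchar(ds$aa_seqs[[g]]))
  }
  v
}

#' Write a datastore to a directory
#'
#' Inverse of [read_datastore()]: writes the six datastore files in the
#' documented TSV/FASTA schema. Reading the result back yields an
#' equivalent datastore.
#'
#' @param ds a \code{datastore}.
#' @param path output directory (created if needed).
#' @return \code{path}, invisibly.
#' @export
write_datastore <- function(ds, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  org <- ds$organisms
  org$lineage <- vapply(org$lineage_split, paste, "", collapse = ";")
  write_tsv_table(org[c("org_code", "name", "lineage")],
                  file.path(path, "organisms.tsv"))
  write_tsv_table(ds$genes[c("gene_id", "org_code", "label", "annotation")],
                  file.path(path, "genes.tsv"))
  write_tsv_table(ds$hits[c("query_gene", "subject_gene", "sw_score",
                            "identity")],
                  file.path(path, "hits.tsv"))
  write_tsv_table(ds$domains[c("gene_id", "domain_id")],
                  file.path(path, "domains.tsv"))
  write_fasta_vector(ds$nt_seqs, file.path(path, "nt.fasta"), "DNA")
  write_fasta_vector(ds$aa_seqs, file.path(path, "aa.fasta"), "AA")
  invisible(path)
}

#' @export
print.datastore <- function(x, ...) {
  cat("<datastore>\n")
  cat("  organisms:", nrow(x$organisms), "\n")
  cat("  genes:    ", nrow(x$genes), "\n")
  cat("  hits:     ", nrow(x$hits), "\n")
  cat("  domains:  ", nrow(x$domains), "\n")
  cat("  sequences:", length(x$nt_seqs), "nt /", length(x$aa_seqs), "aa\n")
  invisible(x)
}

# ---- low-level TSV / FASTA helpers ----------------------------------------

read_tsv_table <- function(file, expected_cols) {
  lines <- readLines(file, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0)
    stop(basename(file), ": missing header line")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!all(expected_cols %in% header))
    stop(basename(file), ": header must contain columns ",
         paste(expected_cols, collapse = ", "))
  body <- lines[-1]
  rows <- strsplit(body, "\t", fixed = TRUE)
  nc <- length(header)
  out <- vector("list", nc)
  for (j in seq_len(nc)) {
    out[[j]] <- vapply(seq_along(rows), function(i) {
      r <- rows[[i]]
      if (length(r) < j) {
        if (length(r) < length(expected_cols))
          stop(basename(file), " line ", which(keep)[i + 1L],
               ": expected ", nc, " fields, found ", length(r))
        return("")
      }
      r[[j]]
    }, "")
  }
  names(out) <- header
  df <- as.data.frame(out, stringsAsFactors = FALSE, optional = TRUE)
  df[expected_cols]
}

write_tsv_table <- function(df, file) {
  con <- file(file, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0) {
    body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
    writeLines(body, con)
  }
}

read_fasta_vector <- function(file, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (file.size(file) == 0) return(stats::setNames(character(0), character(0)))
  xs <- if (type == "DNA") Biostrings::readDNAStringSet(file)
        else Biostrings::readAAStringSet(file)
  out <- as.character(xs)
  # FASTA descriptions may carry annotation after the id
  names(out) <- vapply(strsplit(names(xs), "\\s+"), `[`, "", 1L)
  out
}

write_fasta_vector <- function(seqs, file, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (length(seqs) == 0) {
    file.create(file)
    return(invisible(file))
  }
  xs <- if (type == "DNA") Biostrings::DNAStringSet(seqs)
        else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(xs, file)
  invisible(file)
}
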