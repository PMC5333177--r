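#' Global protein alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment of two protein sequences under BLOSUM62-type
#' substitution scoring and affine gap penalties: a gap run of length L
#' costs \code{gap_open + L * gap_extend}. Defaults (BLOSUM62, open 11,
#' extend 1) are the customary protein NW parameters.
#'
#' @param a,b protein sequences (non-empty strings over the 20 standard
#'   residues).
#' @param matrix substitution matrix name (default \code{"BLOSUM62"});
#'   any matrix shipped with Biostrings.
#' @param gap_open,gap_extend positive gap penalties.
#' @return A list of class \code{protein_alignment}: \code{aligned_a},
#'   \code{aligned_b} (equal-length gapped strings), \code{score},
#'   \code{identity} (identical columns over alignment length).
#' @export
global_align <- function(a, b, matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  for (nm in c("a", "b")) {
    s <- get(nm)
    if (!is.character(s) || length(s) != 1 || nchar(s) == 0)
      stop("sequence ", nm, " must be a non-empty string")
    bad <- regmatches(s, regexpr("[^ACDEFGHIKLMNPQRSTVWY]", s))
    if (length(bad) > 0 && nzchar(bad))
      stop("unknown residue '", bad, "' in sequence ", nm, " at position ",
           regexpr("[^ACDEFGHIKLMNPQRSTVWY]", s))
  }
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be > 0")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  sa <- as.character(Biostrings::alignedPattern(aln))
  sb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(sa, "")[[1]]
  cb <- strsplit(sb, "")[[1]]
  structure(list(aligned_a = sa, aligned_b = sb,
                 score = Biostrings::score(aln),
                 identity = mean(ca == cb & ca != "-")),
            class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("<protein_alignment> length ", nchar(x$aligned_a),
      ", score ", x$score, ", identity ",
      sprintf("%.3f", x$identity), "\n", sep = "")
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Thread nucleotide sequences through a protein alignment
#'
#' Produces a codon alignment by replacing each aligned residue with its
#' source codon and each gap with the gap codon \code{"---"}. Every
#' codon must translate (standard genetic code) to the residue it is
#' threaded under.
#'
#' @param pa a [global_align()] result.
#' @param nt_a,nt_b in-frame CDS strings, length exactly 3x the ungapped
#'   length of the corresponding aligned protein (no stop codon).
#' @return A list of class \code{codon_alignment}: \code{codons_a},
#'   \code{codons_b} (character vectors of "---" or codon triples, equal
#'   length).
#' @export
codon_align <- function(pa, nt_a, nt_b) {
  thread <- function(aligned, nt, which) {
    res <- strsplit(aligned, "")[[1]]
    n_res <- sum(res != "-")
    nt <- toupper(nt)
    if (nchar(nt) != 3L * n_res)
      stop("nt_", which, " length ", nchar(nt), " != 3 x ", n_res,
           " aligned residues")
    codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
    out <- character(length(res))
    k <- 0L
    for (i in seq_along(res)) {
      if (res[i] == "-") { out[i] <- "---"; next }
      k <- k + 1L
      tr <- GENETIC_CODE_TABLE[[codons[k]]]
      if (is.null(tr) || is.na(tr) || tr != res[i])
        stop("codon ", k, " of nt_", which, " (", codons[k],
             ") does not translate to aligned residue ", res[i])
      out[i] <- codons[k]
    }
    out
  }
  structure(list(codons_a = thread(pa$aligned_a, nt_a, "a"),
                 codons_b = thread(pa$aligned_b, nt_b, "b")),
            class = "codon_alignment")
}

# standard genetic code as a plain named vector lookup
GENETIC_CODE_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- unlist(lapply(bases, function(b1)
    unlist(lapply(bases, function(b2) paste0(b1, b2, bases)))))
  stats::setNames(aas, codons)
})

translate_codons <- function(codons) unname(GENETIC_CODE_TABLE[codons])
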