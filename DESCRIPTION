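Package: phylage
Title: Phylostratigraphic Age and Divergence Analysis of Gene Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline evolutionary analysis of gene networks from a flat-file
    homology datastore. Filters candidate homologs by Smith-Waterman score,
    identity and protein-domain composition, clusters network genes into
    homology groups, computes per-gene phylostratigraphic age indices (PAI)
    as last-common-ancestor depths on a merged taxonomy of organism
    lineages, estimates Ka/Ks divergence against the nearest ortholog with
    Nei-Gojobori (1986) counting on a codon alignment threaded through a
    global protein alignment, derives network-level age statistics and
    phylogenetic profiles, and renders static HTML reports with threshold
    sweeps. Includes a seeded synthetic-data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    methods,
    stats,
    utils,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
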