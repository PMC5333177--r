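# phylage

Evolutionary analysis of gene networks, fully offline: how old is each
gene in a pathway, and how strongly is it conserved?

`phylage` is for researchers who have a gene network (a KEGG-style
pathway, or just a gene set) and a flat-file datastore of homology
evidence — organisms with taxonomic lineages, precomputed pairwise hits
with Smith–Waterman scores and identities, protein-domain annotations,
and coding/protein sequences — and want per-gene and network-level
evolutionary characteristics without touching any remote database.

## What it computes

**Phylostratigraphic age index (PAI).** For a reference-organism gene
with orthologs detected in a set of organisms *O*, on a taxonomy built
by merging all organism lineages into one prefix tree,

    PAI = min over o in O of depth( LCA(reference, o) )

with the root ("Cellular Organisms") at depth 0 and the reference
terminal taxon at depth *N* (*N* = 14 for a human-style lineage, taxon
"Homo"). PAI 0 means the gene is shared beyond the deepest split in the
taxonomy (ancient); PAI *N* means no ortholog outside the reference
organism (young). Orthologs are the genes surviving the user's
SW-score / identity / domain-composition filters.

**Divergence index (DI).** Ka/Ks of the gene against its *nearest*
ortholog (deepest LCA, optionally capped by taxonomic distance or an
organism whitelist): global Needleman–Wunsch protein alignment (BLOSUM62,
affine gaps 11/1), codons threaded through the protein alignment, and
Nei–Gojobori (1986) counting with Jukes–Cantor correction. DI < 1
suggests purifying, DI > 1 diversifying selection.

**Network statistics.** For gene-node ages PAI_i and full-network node
degrees d_i:

    Gene Set PAI = Σ PAI_i / N_genes
    Network PAI  = Σ (PAI_i · d_i) / (2 · N_genes)

plus oldest / median / youngest taxon summaries, per-gene phylogenetic
(presence/absence) profiles, homology clustering of network genes with
optional cluster collapsing, age-based color scales and a concentric
PAI-ring layout, identity-threshold sweeps, and a static HTML report.

## Worked example

Everything below is runnable as-is; the package ships a seeded
synthetic-data generator that plants known ground truth (each gene's
birth level on the lineage, and each ortholog pair's substitution
counts), so the printed numbers are reproducible.

```r
library(phylage)

sim <- simulate_datastore(sim_config(seed = 3, n_genes = 8,
                                     codon_length = 60))
fit <- evo_analysis(sim$network, sim$datastore, sim$ref_org)
print(fit)
#> <evo_analysis> reference organism ref
#> <gene_network> 9 nodes (8 gene, 1 compound, 0 map), 3 edges
#> thresholds: SW >= 500, identity >= 0.5, domain mode none
#> Gene set PAI = 7.375; Network PAI = 1.625
#> Median taxon = clade_07; Oldest taxon = clade_03; Youngest taxon = clade_11
#> Total orthologs analyzed: 106
#> 8 homology cluster(s)

head(as.data.frame(fit)[, c("gene_id", "pai", "ka", "ks", "di")], 3)
#>    gene_id pai         ka        ks        di
#> 1 ref:g001   4 0.05161742 0.1689350 0.3055461
#> 2 ref:g002   9 0.05478315 0.1640754 0.3338901
#> 3 ref:g003  11 0.05456952 0.1660291 0.3286745
```

`Gene set PAI = 7.375` is the mean age index of the 8 genes (the
generator planted birth levels 4, 9, 11, 6, 3, 9, 7, 10 — recovered
exactly). Each `di` is Ka/Ks against the gene's nearest planted
ortholog; the generator's defaults (Ka 0.05, Ks 0.15 per site) are
recovered within counting noise, correctly indicating purifying
selection (DI ≈ 1/3). A threshold sweep and HTML report follow the same
pattern:

```r
sw  <- threshold_sweep(sim$network, sim$datastore, sim$ref_org,
                       c(0.2, 0.5, 0.8, 0.95))
render_report(list(toy = fit), "report_out", sweeps = list(toy = sw))
```

A thin command-line front end over the same functions is installed at
`inst/cli/phylage.R` (subcommands `analyze`, `sweep`, `simulate`,
`report`).

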