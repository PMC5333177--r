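---
title: "Methods: gene ages and divergence in networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene ages and divergence in networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylage)
```

## The model

`phylage` treats a gene network as a set of typed nodes (genes,
compounds, pathway cross-references) with undirected edges, and asks
two questions about every gene of a chosen reference organism: *when*
did it arise, and *under what selective regime* has it evolved?

### Age: the phylostratigraphic age index

Organism lineages (root-to-terminal taxon lists, as distributed with
organism databases) are merged into a single prefix tree; depth is
counted in edges from the shared root, so a human-style lineage of 15
taxa puts "Cellular Organisms" at depth 0 and "Homo" at depth 14. For a
gene whose filtered homolog set contains genes of organisms $O$,

$$\mathrm{PAI} = \min_{o \in O}\; \mathrm{depth}\!\left(\mathrm{LCA}(\mathrm{ref}, o)\right),$$

i.e. the depth on the reference lineage of the last common ancestor
covering every ortholog-bearing organism. The two formulations — the
minimum over pairwise LCA depths, and the deepest reference-lineage
node ancestral to all of $O$ — are equivalent, and the test suite
brute-forces that equivalence on random taxonomies. Conventions:

* organisms equal to the reference are dropped from $O$: within-genome
  homologs (paralogs) drive network clustering, not age;
* an empty $O$ yields PAI $= N$, the terminal depth — a gene with no
  detected ortholog outside the reference genome is maximally young.
  The root/terminal anchoring makes the index comparable across genes
  of one reference organism but *not* across organisms with different
  lineage lengths;
* depth counts every rank present in the lineage strings; no rank
  normalization is attempted. Lineages of unequal length are handled
  naturally by the merged tree.

Orthologs are detected from a precomputed hit table: a hit survives
when `sw_score >= sw_min` **and** `identity >= identity_min` (both
inclusive — the thresholds a user sets are minimum acceptable values),
optionally followed by a domain-composition filter. The *simple* domain
filter ranks domains by how many candidate homologs carry them (ties
broken lexicographically for determinism) and requires the top $T$;
$T = 0$ disables the requirement and $T$ beyond the ranking length
degrades to "carries every ranked domain". The *detailed* filter keeps
candidates carrying at least one user-chosen domain — the literal
reading of discarding candidates that "contain none of them"; a
stricter all-of variant would be a one-line change but is not the
default reading implemented. Hits are treated as symmetric evidence
(a one-way hit links both genes), since homology is symmetric even when
search reporting is not.

### Divergence: Ka/Ks against the nearest ortholog

The divergence index of a gene is Ka/Ks against its *nearest* ortholog:
the candidate whose organism has the deepest LCA with the reference,
after optionally restricting to a whitelist of organisms and/or capping
the taxonomic distance, defined as $N - \mathrm{depth(LCA)}$ — the
number of reference-lineage levels below the terminal taxon. Ties are
broken by organism code, then gene id, so the choice is reproducible.
Using the closest available species keeps the substitution process far
from saturation, where the counting method is most reliable.

The pipeline is: global Needleman–Wunsch protein alignment under
BLOSUM62 with affine gap costs (a gap run of length $L$ costs
$11 + 1 \cdot L$ — the customary protein alignment defaults, delegated
to `Biostrings::pairwiseAlignment`, whose traceback is deterministic);
codon threading, replacing each aligned residue by its source codon and
each gap by `---`, with every codon checked to translate to the residue
it sits under; then Nei–Gojobori (1986) counting:

* per codon, each position contributes the fraction of its three
  single-nucleotide neighbours that are synonymous (neighbours that are
  stop codons count as nonsynonymous); site totals are averaged over
  the two sequences;
* codon pairs differing at $k$ positions are scored by averaging the
  synonymous/nonsynonymous step counts over all $k!$ minimal
  substitution pathways with equal weight. All pathways are counted,
  including those passing through intermediate stop codons — the
  uniform-weighting convention; variants that exclude stop pathways
  differ only in rare multi-hit codons;
* columns containing a gap codon or a stop codon are excluded entirely,
  which is why the synthetic generator never emits internal stops — a
  planted change must never silently shrink the countable sites;
* proportions $p_N = N_d/N$, $p_S = S_d/S$ get the Jukes–Cantor
  correction $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$.

Status flags make the partial domain explicit: `saturated` when either
proportion reaches $3/4$ (the correction diverges), `undefined_ks_zero`
when $S_d = 0$ (Ka/Ks has no value; the gene pair may still be reported
with Ka), `no_ortholog` when selection yields nothing. A DI value
exists only for status `ok`.

### Network-level statistics

With per-gene ages $\mathrm{PAI}_i$ and full-network degrees $d_i$:

$$\mathrm{Gene\ Set\ PAI} = \frac{\sum_i \mathrm{PAI}_i}{N}, \qquad
  \mathrm{Network\ PAI} = \frac{\sum_i \mathrm{PAI}_i\, d_i}{2N},$$

where $N$ counts gene nodes only — compounds and map nodes carry no age
and must not dilute the denominator — while degree counts *every*
incident edge, because gene–compound–gene wiring is how pathway
diagrams encode gene connectivity. The Network PAI denominator is the
literal printed formula ($2N$, not $\sum_i d_i$); as a consequence the
statistic is not bounded by the maximum PAI on dense networks (a
$k$-regular gene-only network gives exactly $k/2$ times the Gene Set
PAI, a closed form the tests exercise). The oldest/median/youngest
taxon summaries name the taxa at the extreme and median attained ages;
for an even gene count the *lower* middle value is used so the median
is an attained depth and therefore has a taxon name.

## Tunable parameters

| parameter | default | units | why this default |
|---|---|---|---|
| `sw_min` | 500 | SW score | the canonical working threshold for curated-database homology hits |
| `identity_min` | 0.5 | fraction | half-identical over the aligned region; permissive but excludes spurious hits |
| `domain_mode` | `none` | — | domain filtering is refinement, off unless asked for |
| `domain_threshold_T` | 0 | domains | 0 = no requirement |
| `max_dist` | unset | lineage levels | DI quality control only; unset considers all orthologs |
| gap open / extend | 11 / 1 | score | standard BLOSUM62 affine defaults |
| Ka/Ks method | NG86 | — | the classical counting method, fully specified and checkable by enumeration |

## The synthetic generator

`simulate_datastore()` builds study inputs with *planted* ground truth:

* a reference lineage of depth 14 (the human-like depth) with
  `branching` organisms diverging immediately below every level, so
  every LCA depth 0…13 is attainable;
* each gene is assigned a birth level $b$ and receives orthologs only
  in organisms inside the clade at depth $b$, always including one at
  the clade boundary — so its true PAI is exactly $b$ at any sampling
  density (`ortholog_density` thins the non-boundary organisms);
* hit scores and identities are drawn above the default thresholds
  (SW in [600, 2000], identity in [0.6, 0.99]), so default filtering
  keeps every planted hit while threshold sweeps progressively orphan
  genes;
* ortholog sequences are copies of the reference CDS (default 300
  codons) with `round(target_ks * S)` synonymous and
  `round(target_ka * N)` nonsynonymous single-nucleotide changes
  planted at distinct codons; defaults Ka = 0.05, Ks = 0.15 per site
  describe a moderately conserved ortholog pair under purifying
  selection (Ka/Ks ≈ 1/3). One change per codon keeps the planted
  difference counts exactly recoverable by NG86 (no multi-hit pathway
  ambiguity), so the remaining discrepancy is only the site-count
  averaging between the two sequences and the Jukes–Cantor mapping.

What the generator does *not* emulate: indels (DI fixtures are
gap-free), among-site rate variation, transition/transversion bias,
base-composition skew, correlated domain gain/loss, and the realistic
ortholog-detection noise of a live homology search. Passing the
recovery tests therefore demonstrates the *estimators* are correct on
their own assumptions — not that real-database analyses are free of
detection artefacts. Published pathway-level statistic values obtained
against a live, versioned organism database are for the same reason not
reproducible from a desk fixture and are out of scope; the test suite
replaces them with exact worked examples on the canonical human lineage
depths and with planted-truth recovery.

Determinism: every stochastic step flows from a single integer seed
through R's default Mersenne-Twister stream, which is platform-stable;
the same seed reproduces the same datastore byte for byte.

## Numerical and design choices

* **Inclusive thresholds** (`>=`) everywhere a user sets a minimum.
* **Degenerate color input** (all values equal) maps every gene to the
  mid-scale anchor (green for the heatmap, white for the gradient)
  rather than dividing by a zero range.
* **Ring layout radii** use the *rank* of the distinct PAI values, not
  the raw value, so a network with ages {0, 13, 14} stays readable;
  genes sharing an age are evenly spaced on their circle, and compound
  and map nodes sit on separate outermost circles per type.
* **Cluster collapsing** drops self-loops produced by intra-cluster
  edges and merges duplicate edges; the member list is preserved in the
  merged node's label, and reachability between clusters connected
  through gene paths is preserved (tested).
* **Empty ortholog sets, empty hit tables and singleton clusters** are
  values, not errors, throughout; errors are reserved for structural
  impossibilities (unknown organisms, unresolvable gene nodes, CDS not
  matching its protein).
* **Trailing stop codons** on CDS records (length $3\cdot\mathrm{aa}+3$)
  are trimmed on load, the usual database convention.
* **Report rendering is pure presentation**: re-rendering identical
  results with timestamps disabled is byte-identical, every plot has a
  sibling plain-text data file, links are relative, and histograms use
  one bin per integer age level so bin counts sum to the gene count.

Problem sizes in the shipped tests were chosen to exercise the
estimators well inside their assumptions: exhaustive alignment
enumeration up to length 6 over 200 random pairs, NG86 enumeration up
to 10 codons, 50 genes for exact age recovery, and 100 pairs of 300
codons for rate recovery.

## Known limitations

* PAI resolution is bounded by the lineage strings supplied: ranks
  absent from the lineages cannot be distinguished, and indices are not
  comparable across reference organisms with different lineage depths.
* NG86 is a counting method: it ignores transition/transversion bias
  and codon usage, and saturates quickly ($p \ge 3/4$ undefined); for
  deep comparisons a likelihood method would be preferable (the method
  field in the output leaves room for alternatives).
* Network PAI follows the printed $2N$ normalization and is therefore
  degree-sensitive by design; comparing it across networks of very
  different density conflates age and topology.
* The homology stage consumes precomputed hits; it cannot rescue
  orthologs the upstream search never reported.
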