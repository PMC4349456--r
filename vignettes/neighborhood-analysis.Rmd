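---
title: "Predicting the metabolic role of a transcriptional regulator from gene neighborhoods"
author: "funcdisc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the metabolic role of a transcriptional regulator from gene neighborhoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcdisc)
```

## The problem

Prokaryotic genes serving one metabolic process are frequently clustered:
a transcriptional regulator (TR) often sits beside the operon it controls.
Any *single* genome is unreliable evidence, though — rearrangements,
insertions and deletions scramble local gene order on evolutionary
timescales. The signal becomes robust when pooled across genomes: if the
homologs of an uncharacterized TR are repeatedly found near genes of the
same enzymatic family, in many unrelated genomes, the regulator very
likely controls that metabolic area, and the substrates and products of
those enzymes are natural candidates for its effector molecule.

`funcdisc` automates exactly this argument. Given a query TR, a
collection of annotated genomes, a pairwise protein-similarity table and
a local metabolic reference (EC number → reactions → compounds, and
EC/compound → pathway), it produces three ranked tables: over-represented
enzymes, metabolites and pathways across the pooled neighborhoods.

## The procedure

1. **Homolog selection** (`selectHomologs()`). Candidates are the query's
   *bidirectional best hits*: gene pairs that are each other's
   best-scoring Smith–Waterman match between two genomes, the standard
   conservative orthology proxy. Pairs below a local-alignment score of
   100 are never recorded (the floor used by precomputed similarity
   databases), candidates below the amino-acid identity cutoff
   (aa-IDc, default 40%) are discarded, at most one candidate per genome
   is kept, and the list is truncated to `nHomologs` (default 100) after
   ranking by score. The query itself is always analyzed alongside its
   homologs.
2. **Neighborhood extraction** (`extractNeighborhood()`). For each
   homolog, the window of `nNeighbors` genes upstream and downstream
   (default 10, i.e. at most 21 genes) by *rank along the replicon*, not
   by base pairs. Windows truncate at linear replicon ends and wrap
   around circular ones without duplicating genes. Strand is ignored:
   regulated clusters routinely mix strands.
3. **Enzyme summary** (`summarizeEnzymes()`). Each EC number is scored by
   the number of *distinct* neighborhoods containing at least one gene
   annotated with it. Presence per neighborhood — not raw gene count — so
   a tandem duplication in one genome cannot inflate a rank. Genes with
   several EC numbers contribute each independently.
4. **Metabolite summary** (`summarizeMetabolites()`). The compound
   universe is the union of substrates and products over all reactions of
   the summary enzymes; a compound's frequency is the number of distinct
   neighborhoods containing at least one enzyme whose reactions involve
   it. Two enzymes sharing a compound within one neighborhood count that
   neighborhood once. An optional exclusion list removes currency
   metabolites (water, ATP, NAD(H), CO2, phosphate, ...); it is **off by
   default**, and a starter list ships in
   `inst/extdata/currency_metabolites.txt`.
5. **Pathway summary** (`summarizePathways()`). A pathway's hit count is
   the sum of frequencies of every summary EC and compound mapped to it.
   "Number of hits" is genuinely ambiguous between frequency-weighted and
   distinct-entity counting, so both are implemented
   (`scoreMode = "weighted"` is the default; `"distinct"` counts each
   mapped entity once). Weighted is the default because it preserves the
   evidence gradient between an enzyme seen in 18 neighborhoods and one
   seen in 2.

All ranking ties break lexicographically by identifier, and every stage
is deterministic, so identical inputs give byte-identical reports
(`renderHtml()`, `renderJson()`).

An enzyme can be metabolically characterized yet absent from the pathway
map — transport-system components (e.g. an ABC transporter ATPase) are
the notorious case. The pipeline then produces a populated enzyme summary
and an *empty* pathway table, and the report renders with an explicit
notice instead of failing; interpretation falls back to reading the
neighborhood representations directly.

## Parameters that matter

| parameter | default | unit | why this default |
|---|---|---|---|
| `aaIdc` | 40 | % identity | below ~40% same-family regulators that are not functional homologs pass; above it true homologs are lost and cross-genome counts starve |
| `nHomologs` | 100 | genes | one per genome; a strict cutoff often leaves far fewer, which is fine |
| `nNeighbors` | 10 | genes per side | windows of 5–20 genes bracket typical operon and local-cluster sizes |
| `swFloor` | 100 | score | records below it are noise-level for unrelated proteins |
| scoring | BLOSUM62, gap open 11, extend 1 | — | the standard protein local-alignment setting; configurable via `alignmentScoring()` |

Percent identity uses the full alignment length, gap columns included, in
the denominator (the BLAST convention). A gap of length $L$ costs
$\mathrm{open} + L\cdot\mathrm{ext}$.

## The synthetic pangenome generator

Real multi-genome datastores are large and network-bound, so testing and
demonstration run on seeded synthetic pangenomes
(`generatePangenome()`). The generator emulates precisely the features
the method exploits, and perturbs them the way real genomes do:

* one TR ortholog family spanning all genomes, descended from a random
  ancestor by point substitution at 2% per site (pairwise identity
  ~95%, comfortably above any practical aa-IDc);
* a planted cluster of `clusterSize` enzyme genes (default 4), all
  mapped to one planted pathway, placed immediately beside the TR with
  probability `conservationProb` per genome (default 0.8); conserved
  clusters have their internal order shuffled with probability
  `rearrangementRate` (default 0.1), non-conserved cluster genes are
  deleted with probability `indelRate` (default 0.1) or relocated
  uniformly at random — the insertion/deletion/rearrangement confounders
  the multi-genome pooling is meant to defeat;
* `decoyEcCount` decoy enzyme genes per genome (default 8), each mapped
  to its own decoy pathway and placed uniformly, providing the
  background the planted signal must beat (a decoy lands inside a
  default window roughly a third of the time on a 60-gene replicon);
* unannotated random filler genes; one circular replicon per genome by
  default, exercising window wraparound.

The similarity table is built by aligning within-family pairs only, the
in-silico equivalent of a precomputed all-vs-all table with a score
floor: unrelated random proteins of these lengths score far below 100,
so cross-family records cannot exist. The test suite verifies this
shortcut by comparing the generator's table against a full
`bestBestHits()` cross-product on a small pangenome.

What the generator does **not** emulate: phylogenetic structure (all
genomes are independent draws from one ancestor, no tree), realistic
amino-acid composition or length distributions, multi-replicon genomes,
horizontal transfer, paralogy within a genome, or annotation error. A
passing planted-pathway test therefore shows the *counting machinery*
recovers a conserved-context signal under order scrambling and decoys;
it says nothing about homolog detection sensitivity at remote
evolutionary distances, which is bounded by the aligner and cutoffs, not
by this package.

## The binding model

The companion module quantifies regulator–operator binding from
fluorescence-anisotropy titrations. The measured anisotropy change at
total protein concentration $E$ is modeled by the Hill saturation form

$$\Delta A \;=\; \Delta A_T\,\frac{E^{H}}{K_d^{H} + E^{H}}$$

with dissociation constant $K_d$ (units of $E$), Hill coefficient $H$
and total anisotropy change $\Delta A_T$. The curve is monotone in $E$,
$\Delta A(0)=0$, and $\Delta A(K_d)=\Delta A_T/2$ for any $H$ — the
identities the unit tests pin down. Fitting (`fitHill()`) is unweighted
nonlinear least squares by Levenberg–Marquardt with all three parameters
bounded positive, initialized at $H=1$, $\Delta A_T=\max\Delta A$, and
$K_d$ at the concentration closest to half-max signal. A fit that fails
to converge is returned flagged rather than raised, so titration batches
process unattended. Concentration units are carried as a tag (nM for
operator titrations, mM for effector-modulated ones) and never
converted.

Two conventions deserve note. First, the saturation form above is the
standard one for anisotropy titrations in which the labeled operator
concentration is far below $K_d$; ligand-depletion corrections are out
of scope. Second, fits are unweighted — anisotropy noise is
approximately homoscedastic on the $\Delta A$ scale.

```{r hill-example}
E <- 10^seq(log10(0.5), log10(250), length.out = 12)
set.seed(1)
pts <- simulateTitration(E, kd = 19, h = 1, deltaAT = 1, noiseSd = 0.02)
fitHill(pts, unit = "nM")
```

## Numerical and design choices

* **Coordinates.** Genes live in a `GRanges` (1-based, inclusive — the
  container's native convention); GFF3 is read with `rtracklayer` and
  the gene `index` used for windows is assigned by start-coordinate
  order within each replicon, so input row order never matters.
* **Identifiers.** Reference and similarity identifiers are normalized
  to uppercase with whitespace stripped; gene ids are `org:locus`.
* **Tie-breaks.** Best-hit ties, homolog-rank ties and all summary-rank
  ties resolve lexicographically by identifier.
* **Similarity storage.** One record per unordered pair with symmetric
  semantics (scores are symmetric for symmetric matrices); best-best
  hits are computed per genome pair and the query's partners are used.
* **Degenerate inputs.** Empty annotation files, genomes without
  proteomes, enzymes without reactions, references without pathway maps
  and EC-free neighborhoods all degrade to empty-but-valid tables and
  complete reports, with warnings where information is lost.
* **A note on equation provenance.** The anisotropy-fitting equation in
  the source literature for this approach is referenced but its body is
  not reproducible from the available text, and its narrative calls $E$
  "the total MetJ concentration" — almost certainly a slip for the
  GST-tagged regulator under study. The standard Hill saturation form
  is adopted here and documented prominently rather than silently
  corrected.

## Scale of the shipped validation

The test suite and acceptance script are sized for a laptop-class run:
alignment oracle checks on 200 random pairs of length ≤ 12 against an
exhaustive Gotoh dynamic program; brute-force recounts of all three
summary tables on pangenomes of 12–15 genomes; planted-pathway recovery
on twenty 20-genome pangenomes (conservation 0.8, 8 decoy ECs); Hill
parameter recovery on 50 replicate titrations of 12 points at 2% noise.
These sizes were chosen as the smallest at which each claim is
informative: the planted-pathway run exercises every pipeline stage at
the generator's default study conditions, and the titration design
brackets the half-saturation point on both affinity scales.

## Limitations

* Ranking is by raw counts; no over-representation *significance* test
  is attempted (neighborhood contents are phylogenetically correlated,
  so naive p-values would mislead).
* No operon-boundary or operator-motif inference; the neighborhood is a
  symmetric rank window.
* Predictions inherit annotation quality: unannotated enzymes and
  pathway-less ECs are invisible to the pathway table.
* The full Smith–Waterman pass (`bestBestHits()`) is exact and
  therefore quadratic; it is intended for fixture-scale proteomes, with
  precomputed similarity tables as the expected input path at scale.
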