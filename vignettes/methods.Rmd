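---
title: "Methods: gene-family inference from coding sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family inference from coding sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genefamr)
```

# Overview

`genefamr` infers gene families from per-species coding sequences (CDS) and
GFF3 annotation, in the style of the Ensembl Compara GeneTrees pipeline. The
pipeline is a fixed composition of ten stages:

1. **prepare** — parse CDS FASTA and GFF3, keep the longest CDS per gene,
   and mangle each sequence id to `<id>_<species>`.
2. **translate** — translate each CDS in frame 1.
3. **search** — all-vs-all local protein alignment, reported as 12-column
   tabular similarity hits.
4. **parse-hits** — convert hits to integer-weighted undirected edges.
5. **cluster** — sparse-graph hierarchical clustering into families.
6. **align** — per-family progressive protein multiple alignment.
7. **backtranslate** — codon-aware nucleotide alignment from the protein
   alignment.
8. **tree** — five candidate neighbor-joining gene trees, reconciled
   against the species tree; the best rooting is kept.
9. **aggregate** — trees, CIGAR-encoded alignment rows and gene features
   are written into one SQLite store.
10. **orphans** — sequences in no family are collected as orphan genes.

Every stage exchanges data through a standard text format (FASTA, GFF3,
12-column tabular, 3-column edge lists, one-line-per-cluster files, aligned
FASTA, NHX, SQLite), so stages can be run individually or end to end with
`run_pipeline()`.

# Preparation

Species labels are sanitized (lowercased, whitespace to `_`, other
punctuation dropped) so that mangled identifiers survive Newick/NHX and
tabular formats unquoted. Ids are demangled by longest-suffix match against
the declared labels, which makes labels containing underscores unambiguous.
When a gene has several transcripts, only the longest CDS is kept; length
ties break to the lexicographically smallest transcript id so the selection
is deterministic.

# Similarity search and edge weights

The search stage computes optimal local alignments (Smith–Waterman with
affine gaps, BLOSUM62, gap open 11 / extend 1) for every ordered pair of
proteins. Raw scores $S$ are converted to bit scores and e-values with the
Karlin–Altschul statistics used by ungapped BLASTP defaults:

$$S' = \frac{\lambda S - \ln K}{\ln 2}, \qquad
  E = m\,n\,2^{-S'}$$

with $\lambda = 0.267$, $K = 0.041$, $m$ the query length and $n$ the total
number of residues in the database. Hits are filtered by an e-value cutoff
and optionally by query coverage, and at most one HSP per pair is kept.

Each undirected pair keeps its minimum e-value $E$ and receives the integer
weight

$$w = \min\!\left(100,\ \left\lfloor -\tfrac{\log_{10} E}{2} + 0.5
  \right\rfloor\right),$$

i.e. half of the negative decimal exponent, rounded half-up, floored at 0
and capped at 100 (an e-value of exactly 0 maps to 100). Optionally only
reciprocal best hits (RBH) are kept: a pair survives when each sequence is
the other's best partner by lowest e-value, then highest bit score, then
lexicographically smallest id.

# Clustering

Families are found by greedy agglomeration on the weighted graph. Starting
from singletons, the pair of clusters $X, Y$ maximizing the average
cross-edge weight $\sum w / (|X||Y|)$ is merged, subject to three
constraints: at least one cross edge, cross-edge density
$\#\text{edges}/(|X||Y|)$ at least `min_density`, and merged size at most
`max_size` (500). Ties break to the higher cross-edge count, then to the
pair whose smallest member ids are lexicographically least, so the merge
sequence is fully deterministic. A single-linkage mode instead takes
connected components and repeatedly removes the lightest edge from any
oversized component. Clusters smaller than `min_cluster_size` (3) are set
aside; their members later become orphans.

Six parameter presets `A`–`F` cover the e-value cutoff
($10^{-3}$/$10^{-10}$), query coverage (0/90), minimum edge weight (0/20)
and minimum density (0.34/0.50); preset `D` ($10^{-10}$, 0, 0, 0.34) is the
default.

# Multiple alignment and back-translation

Each family is aligned progressively: a UPGMA guide tree is built from
pairwise p-distances of global pairwise alignments, then profiles are
merged bottom-up with a profile–profile Gotoh algorithm (affine gaps, open
10 / extend 0.5) whose column scores are sum-of-pairs expectations over the
residue frequency vectors of each profile column. The traceback prefers
substitution over gaps in the first profile over gaps in the second, making
the alignment deterministic.

The protein alignment is back-translated to a codon alignment: each residue
expands to its source codon and each gap to `---`; the translation of every
degapped row is verified against the protein row, and a terminal stop codon
is dropped. Codon rows are therefore exactly three times the protein rows.

# Gene trees and reconciliation

Five candidate trees are estimated by neighbor joining from five distance
estimates: protein p-distance, Poisson-corrected protein distance
$-\ln(1-p)$, nucleotide p-distance, Jukes–Cantor distance, and
third-codon-position p-distance. Sites with gaps are removed pairwise, and
undefined corrections are clamped at a ceiling of 10. Negative NJ branch
lengths are clamped to zero.

Every candidate is rooted on the midpoint of each of its edges, and each
rooting is reconciled against the species tree by LCA mapping: an internal
node is a duplication (`D`) when it maps to the same species-tree node as
one of its children, otherwise a speciation (`S`); losses are counted from
the depth difference along the species tree between a node and each child
(minus one across speciation nodes). Duplication nodes carry a duplication
consistency score (DCS), the Jaccard index of the species sets under their
two children. Among all rootings of all candidates, the winner minimizes,
in order: duplication count, loss count, total branch length (tolerance
$10^{-9}$), and finally the Newick string, which makes the selection
deterministic. Trees are serialized as NHX with `S`, `D` and `DCS` tags.

# Aggregation and orphans

For each family the protein alignment rows are encoded as CIGAR strings
(run-length `M`/`D`, counts of 1 omitted) and stored together with the NHX
tree and the gene/transcript/exon/CDS coordinates in a single SQLite
database with a `transcript_species` view joining transcripts to species.
Orphans are all sequences that either appear in no edge of the similarity
graph or belong to a discarded (too small) cluster.

# Simulator

For testing, `simulate_families()` evolves unrelated root CDS down a Yule
species tree (unit height): per branch, each site mutates with probability
$\min(\text{subs\_per\_site} \times \text{branch length},\, 0.75)$, with
the start and stop codons held fixed and internal stop codons resampled;
codon indels (length 1–2 codons) arrive as a Poisson process; gene copies
duplicate or are lost per branch with fixed probabilities. The truth table
records the family and duplication count of every emitted sequence. The
simulator is intentionally simple — no rate heterogeneity, no selection, no
codon bias — and is meant to generate small benchmark inputs whose true
family structure is known, not realistic sequence evolution.

Problem sizes throughout the package (tens of sequences, a handful of
species) are a deliberate choice: every algorithm is exact rather than
heuristic, so behavior is checkable against brute-force oracles.

# A worked run

```{r pipeline, eval = FALSE}
sp <- simulate_species_tree(6, seed = 7)
sim <- simulate_families(sp, sim_params(seed = 42))
paths <- write_simulation(sim, sp, "input")
cfg <- pipeline_config(paths$cds, paths$gff3, paths$species_tree,
                       "run", preset = "D", seed = 42)
res <- run_pipeline(cfg)
res$counts
family_stats(res$families)
```
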