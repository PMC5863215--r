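# genefamr

Gene-family discovery, alignment and gene trees from coding sequences — a
desk-scale, fully deterministic pipeline in the style of the Ensembl Compara
GeneTrees workflow.

Given per-species CDS FASTA and GFF3 annotation plus a species tree,
`genefamr` translates coding sequences, performs all-vs-all protein
similarity search, converts hits into a weighted sparse graph, clusters the
graph into gene families, aligns each family (protein and codon-aware
back-translated nucleotide alignments), builds species-tree-reconciled gene
trees annotated with speciation/duplication events and duplication
consistency scores (NHX), and aggregates everything into a single SQLite
store. It also identifies orphan genes and ships a gene-family simulator
for generating benchmark inputs with known truth.

## Core algorithms

- **Similarity → edges.** Optimal local alignments (Smith–Waterman, affine
  gaps, BLOSUM62, open 11 / extend 1) are scored with Karlin–Altschul
  statistics, `S' = (λS − ln K)/ln 2`, `E = m·n·2^(−S')` (λ = 0.267,
  K = 0.041), and emitted as 12-column tabular hits. Each undirected pair
  receives the integer weight `w = min(100, round(−log10(E)/2))`
  (half-up; `E = 0` maps to 100). For example:

  | e-value | 1 | 1e-3 | 1e-40 | 1e-250 |
  |---------|---|------|-------|--------|
  | weight  | 0 | 2    | 20    | 100    |

- **Clustering.** Greedy agglomeration maximizing average cross-edge
  weight `Σw/(|X||Y|)` under a cross-edge density floor and a maximum size
  of 500; ties break by edge count, then by smallest member ids, so merges
  are deterministic. Six presets `A`–`F` span e-value cutoff
  (1e-3/1e-10), query coverage (0/90), minimum edge weight (0/20) and
  minimum density (0.34/0.50); preset `D` (1e-10, 0, 0, 0.34) is the
  default. Clusters smaller than 3 members are discarded.

- **Alignment.** Progressive MSA over a UPGMA guide tree with
  profile–profile Gotoh alignment (sum-of-pairs expected scores, open 10 /
  extend 0.5), then codon-aware back-translation (residue → source codon,
  gap → `---`, terminal stop dropped, translation verified).

- **Trees.** Five neighbor-joining candidates from five distances
  (protein p, Poisson `−ln(1−p)`, nucleotide p, Jukes–Cantor, third-codon
  p; pairwise deletion; corrections clamped at 10). Every rooting of every
  candidate is reconciled against the species tree by LCA mapping
  (duplication when a node maps where a child maps; losses from
  species-tree depth differences; DCS = Jaccard index of child species
  sets), and the winner minimizes duplications, then losses, then total
  branch length, then the Newick string.

- **Aggregation.** Alignment rows become CIGAR strings (`2MDM` for
  `MK-R`); trees (NHX), CIGARs and gene/transcript/exon/CDS features land
  in one SQLite database with a `transcript_species` view.

## Worked example

Simulate three unrelated families across six species, run the pipeline with
preset D, and inspect the result:

```r
library(genefamr)

sp  <- simulate_species_tree(6, seed = 7)
sim <- simulate_families(sp, sim_params(seed = 42))   # 6 species, 3 families
paths <- write_simulation(sim, sp, "input")

cfg <- pipeline_config(paths$cds, paths$gff3, paths$species_tree,
                       "run", preset = "D", seed = 42)
res <- run_pipeline(cfg)

str(res$counts)
#> $ species : 6      $ cds     : 18     $ proteins: 18
#> $ hits    : 108    $ edges   : 45     $ clusters: 3
#> $ families: 3      $ discarded_ids: 0 $ orphans : 0

family_stats(res$families)
#>   families larger_than_200 smaller_than_3 largest mean_size
#> 1        3               0              0       6         6

store_query(res$store, "SELECT family_id, count(*) AS n
                        FROM family_member GROUP BY family_id")
#>   family_id n
#> 1         1 6
#> 2         2 6
#> 3         3 6
```

The run directory contains every intermediate in its standard text format:
`prepared_cds.fasta`, `proteins.fasta`, `hits.tsv` (12-column tabular),
`edges.tsv`, `clusters.txt`, per-family `*_prot.fasta_aln`,
`*_codon.fasta_aln` and `*.nhx`, `families.sqlite`, `orphans.fasta` and a
JSON manifest. Reruns with the same inputs and seed are byte-identical.

A thin command-line wrapper with per-stage subcommands (`prepare`,
`translate`, `search`, `parse-hits`, `cluster`, `align`, `backtranslate`,
`tree`, `aggregate`, `orphans`, `simulate`, `run`, `stats`) is installed at
`inst/cli/genefamr.R`:

```sh
Rscript inst/cli/genefamr.R simulate --seed 5 --species 4 --families 2 --out sim
Rscript inst/cli/genefamr.R run --cds sp1=sim/sp1_cds.fasta ... \
    --gff3 sp1=sim/sp1.gff3 ... --species-tree sim/species_tree.nwk \
    --out run --preset D --seed 5
Rscript inst/cli/genefamr.R stats --clusters run/clusters.txt
```

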