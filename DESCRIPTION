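Package: genefamr
Title: Gene Family Discovery, Alignment and Gene Trees from Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for inferring gene families from coding
    sequences of multiple species, in the style of the Ensembl Compara
    GeneTrees pipeline. Starting from per-species CDS FASTA and GFF3
    annotation, it translates coding sequences, performs all-vs-all protein
    similarity search, converts hits to a weighted sparse graph, clusters the
    graph into gene families, aligns each family (protein and codon-aware
    back-translated nucleotide alignments), builds species-tree-reconciled
    gene trees annotated with speciation/duplication events and duplication
    consistency scores (NHX), and aggregates trees, CIGAR-encoded alignments
    and gene features into a single SQLite store. Includes an orphan-gene
    identification procedure and a gene-family simulator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    igraph,
    rtracklayer,
    DBI,
    RSQLite,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
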