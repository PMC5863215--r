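#' Simulation parameters
#'
#' Conditions for the synthetic gene-family generator. The defaults emulate
#' a small multi-species validation set: several mutually dissimilar
#' families present in every species of a six-species tree, with mild
#' divergence and no duplication or loss.
#'
#' @param n_species number of species (leaves of the simulated tree).
#' @param n_families number of unrelated gene families.
#' @param root_cds_length nominal root CDS length in nucleotides (multiple
#'   of 3, including start and stop codons); per-family lengths vary within
#'   +/-20% so family roots are mutually unalignable.
#' @param subs_per_site expected substitutions per site per unit branch
#'   length (trees are unit height, so this is the root-to-tip divergence).
#' @param indel_rate expected codon-preserving indel events per codon per
#'   unit branch length.
#' @param dup_prob probability of a gene duplication on each branch.
#' @param loss_prob probability of a gene loss on each branch.
#' @param seed integer random seed; every simulation is deterministic per
#'   seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_species = 6L, n_families = 3L,
                       root_cds_length = 300L, subs_per_site = 0.05,
                       indel_rate = 0.02, dup_prob = 0, loss_prob = 0,
                       seed = 1L) {
  stopifnot(root_cds_length %% 3 == 0, dup_prob >= 0, dup_prob <= 1,
            loss_prob >= 0, loss_prob <= 1, n_species >= 2, n_families >= 1)
  structure(list(n_species = as.integer(n_species),
                 n_families = as.integer(n_families),
                 root_cds_length = as.integer(root_cds_length),
                 subs_per_site = subs_per_site, indel_rate = indel_rate,
                 dup_prob = dup_prob, loss_prob = loss_prob,
                 seed = as.integer(seed)), class = "sim_params")
}

SENSE_CODONS <- local({
  codes <- Biostrings::GENETIC_CODE
  names(codes[codes != "*"])
})

random_sense_codons <- function(n) {
  sample(SENSE_CODONS, n, replace = TRUE)
}

#' Simulate a species tree
#'
#' Yule (pure-birth) tree with branch lengths normalized to unit root
#' height, leaves labelled `sp1..spN`. Deterministic per seed.
#'
#' @param n_species number of leaves (>= 2).
#' @param seed integer random seed.
#' @return A [species_tree()].
#' @export
simulate_species_tree <- function(n_species, seed = 1L) {
  if (n_species < 2) stop("need at least 2 species")
  set.seed(seed)
  phy <- ape::rphylo(n_species, birth = 1, death = 0)
  phy$tip.label <- paste0("sp", seq_len(n_species))
  depths <- ape::node.depth.edgelength(phy)
  phy$edge.length <- phy$edge.length / max(depths)
  root <- parse_newick(ape::write.tree(phy))
  species_tree(root)
}

#' Simulate gene families down a species tree
#'
#' Each family starts from a random root CDS (start codon, random sense
#' codons, stop codon; no internal stops) and evolves down the species tree:
#' on every branch each gene copy may be lost, may duplicate, and accrues
#' codon-position-aware substitutions (mutations creating internal stop
#' codons are resampled) and codon-length indels. Families are seeded
#' independently with length-varied roots, so inter-family similarity is
#' that of random sequences.
#'
#' @param sp a [species_tree()] (e.g. from [simulate_species_tree()]).
#' @param params a [sim_params()].
#' @return A list with elements `cds` (named list of per-species nucleotide
#'   [seq_set()]s), `features` (named list of per-species feature data
#'   frames), and `truth` (data frame: `id`, `species`, `family`, `n_dups`).
#' @export
simulate_families <- function(sp, params = sim_params()) {
  stopifnot(inherits(sp, "species_tree"), inherits(params, "sim_params"))
  set.seed(params$seed)
  species <- tree_leaves(sp$root)
  out <- list()  # per species: list of list(id, seq, family, n_dups)
  for (s in species) out[[s]] <- list()
  for (fam in seq_len(params$n_families)) {
    n_codons <- max(10L, round(params$root_cds_length / 3 *
                                 stats::runif(1, 0.8, 1.2)))
    root_seq <- paste0("ATG",
                       paste(random_sense_codons(n_codons - 2L), collapse = ""),
                       sample(c("TAA", "TAG", "TGA"), 1))
    copies_at_leaf <- evolve_subtree(sp$root, list(list(seq = root_seq,
                                                        n_dups = 0L)),
                                     params, at_root = TRUE)
    for (s in names(copies_at_leaf)) {
      for (cp in copies_at_leaf[[s]]) {
        k <- length(out[[s]]) + 1L
        gene_id <- sprintf("%sf%dg%d", s, fam,
                           sum(vapply(out[[s]], function(x)
                             x$family == fam, logical(1))) + 1L)
        out[[s]][[k]] <- list(gene_id = gene_id, seq = cp$seq, family = fam,
                              n_dups = cp$n_dups)
      }
    }
    if (sum(lengths(copies_at_leaf)) == 0) {
      stop("family ", fam, " lost in every species; lower loss_prob")
    }
  }
  cds <- list(); features <- list(); truth <- list()
  for (s in species) {
    recs <- out[[s]]
    if (length(recs) == 0) {
      cds[[s]] <- NULL
      next
    }
    gene_ids <- vapply(recs, `[[`, character(1), "gene_id")
    tr_ids <- paste0(gene_ids, ".t1")
    seqs <- vapply(recs, `[[`, character(1), "seq")
    cds[[s]] <- seq_set(id = tr_ids, seq = seqs, species = "", moltype = "nt")
    features[[s]] <- synthetic_features(gene_ids, tr_ids, nchar(seqs), s)
    truth[[s]] <- data.frame(
      id = tr_ids, species = s,
      family = vapply(recs, `[[`, integer(1), "family"),
      n_dups = vapply(recs, `[[`, integer(1), "n_dups"),
      stringsAsFactors = FALSE)
  }
  list(cds = cds, features = features,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

# recursively evolve a set of gene copies down the tree; returns a named
# list (species -> list of copies) of surviving leaf copies
evolve_subtree <- function(node, copies, params, at_root = FALSE) {
  if (!at_root) {
    blen <- if (is.na(node$length)) 0 else node$length
    survivors <- list()
    for (cp in copies) {
      if (stats::runif(1) < params$loss_prob) next
      lineages <- if (stats::runif(1) < params$dup_prob) {
        list(list(seq = cp$seq, n_dups = cp$n_dups + 1L),
             list(seq = cp$seq, n_dups = cp$n_dups + 1L))
      } else list(cp)
      for (lin in lineages) {
        lin$seq <- mutate_cds(lin$seq, blen, params)
        survivors[[length(survivors) + 1L]] <- lin
      }
    }
    copies <- survivors
  }
  if (is_leaf(node)) {
    res <- list()
    res[[node$label]] <- copies
    return(res)
  }
  if (length(copies) == 0) {
    return(stats::setNames(rep(list(list()), length(tree_leaves(node))),
                           tree_leaves(node)))
  }
  res <- list()
  for (ch in node$children) {
    res <- c(res, evolve_subtree(ch, copies, params))
  }
  res
}

# per-branch substitutions (internal stop codons resampled) and
# codon-length indels; start and stop codons are preserved
mutate_cds <- function(seq, blen, params) {
  n <- nchar(seq)
  n_codons <- n %/% 3L
  chars <- strsplit(seq, "")[[1]]
  p <- min(params$subs_per_site * blen, 0.75)
  mutable <- 4:(n - 3L)  # keep start and stop codons intact
  hit <- mutable[stats::runif(length(mutable)) < p]
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  # resample codons that became internal stops
  for (c_idx in 2:(n_codons - 1L)) {
    codon <- paste(chars[(3 * c_idx - 2):(3 * c_idx)], collapse = "")
    if (codon %in% c("TAA", "TAG", "TGA")) {
      chars[(3 * c_idx - 2):(3 * c_idx)] <-
        strsplit(random_sense_codons(1), "")[[1]]
    }
  }
  codons <- vapply(seq_len(n_codons), function(k)
    paste(chars[(3 * k - 2):(3 * k)], collapse = ""), character(1))
  n_events <- stats::rpois(1, params$indel_rate * n_codons * blen)
  for (e in seq_len(n_events)) {
    if (length(codons) < 5) break
    len <- sample(1:2, 1)
    if (stats::runif(1) < 0.5) {
      pos <- sample(2:(length(codons) - 1L), 1)
      codons <- append(codons, random_sense_codons(len), after = pos)
    } else {
      pos <- sample(2:(length(codons) - 1L - len + 1L), 1)
      codons <- codons[-(pos:(pos + len - 1L))]
    }
  }
  paste(codons, collapse = "")
}

# self-consistent synthetic coordinates: tandem genes on one chromosome,
# one transcript with a single exon and a single CDS segment each
synthetic_features <- function(gene_ids, tr_ids, lens, species,
                               spacer = 1000L) {
  starts <- cumsum(c(1L, utils::head(lens + spacer, -1)))
  ends <- starts + lens - 1L
  rbind(
    data.frame(feature_id = gene_ids, ftype = "gene", parent_id = "",
               species = species, chrom = "chr1", start = starts, end = ends,
               strand = "+", rank = 1L, symbol = gene_ids,
               stringsAsFactors = FALSE),
    data.frame(feature_id = tr_ids, ftype = "transcript",
               parent_id = gene_ids, species = species, chrom = "chr1",
               start = starts, end = ends, strand = "+", rank = 1L,
               symbol = NA_character_, stringsAsFactors = FALSE),
    data.frame(feature_id = paste0(tr_ids, ".e1"), ftype = "exon",
               parent_id = tr_ids, species = species, chrom = "chr1",
               start = starts, end = ends, strand = "+", rank = 1L,
               symbol = NA_character_, stringsAsFactors = FALSE),
    data.frame(feature_id = paste0(tr_ids, ".cds"), ftype = "cds_segment",
               parent_id = tr_ids, species = species, chrom = "chr1",
               start = starts, end = ends, strand = "+", rank = 1L,
               symbol = NA_character_, stringsAsFactors = FALSE)
  )
}

#' Write a simulated dataset to disk
#'
#' Emits per-species CDS FASTA and GFF3, the species tree in Newick, and
#' the truth table as a tab-separated file — the same dialects the pipeline
#' consumes.
#'
#' @param sim result of [simulate_families()].
#' @param sp the [species_tree()] used for the simulation.
#' @param dir output directory (created if needed).
#' @return A list of file paths (`cds`, `gff3`, `species_tree`, `truth`).
#' @export
write_simulation <- function(sim, sp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cds_paths <- character(0); gff_paths <- character(0)
  for (s in names(sim$cds)) {
    cds_paths[s] <- file.path(dir, paste0(s, "_cds.fasta"))
    write_fasta(sim$cds[[s]], cds_paths[s])
    gff_paths[s] <- file.path(dir, paste0(s, ".gff3"))
    write_gff3(sim$features[[s]], gff_paths[s])
  }
  tree_path <- file.path(dir, "species_tree.nwk")
  write_species_tree(sp, tree_path)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(cds = cds_paths, gff3 = gff_paths, species_tree = tree_path,
       truth = truth_path)
}

#' Write feature records as GFF3
#'
#' @param features a feature data frame (see [feature_store()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  type_map <- c(gene = "gene", transcript = "mRNA", exon = "exon",
                cds_segment = "CDS")
  lines <- "##gff-version 3"
  ord <- order(match(features$ftype, names(type_map)), features$start)
  f <- features[ord, , drop = FALSE]
  attrs <- ifelse(f$ftype == "gene",
                  paste0("ID=", f$feature_id,
                         ifelse(is.na(f$symbol), "",
                                paste0(";Name=", f$symbol))),
                  paste0("ID=", f$feature_id, ";Parent=", f$parent_id))
  phase <- ifelse(f$ftype == "cds_segment", "0", ".")
  lines <- c(lines, paste(f$chrom, "genefamr", type_map[f$ftype], f$start,
                          f$end, ".", f$strand, phase, attrs, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
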