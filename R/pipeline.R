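#' Parameter presets
#'
#' Six named parameter sets (A-F) covering the similarity-search e-value
#' and query-coverage cutoffs and the clustering minimum edge weight and
#' density. All presets share `max_hsps = 1`, non-single-link clustering,
#' a maximum cluster size of 500 and a minimum kept-cluster size of 3.
#' Preset D holds the Compara default parameters.
#'
#' @param name one of `"A"`..`"F"`.
#' @return A list with elements `search` ([search_params()]) and `cluster`
#'   ([cluster_params()]).
#' @export
preset <- function(name = c("D", "A", "B", "C", "E", "F")) {
  name <- match.arg(name)
  tab <- list(
    A = list(evalue = 1e-03, qcov = 0,  minw = 0,  dens = 0.34),
    B = list(evalue = 1e-03, qcov = 0,  minw = 20, dens = 0.50),
    C = list(evalue = 1e-03, qcov = 90, minw = 0,  dens = 0.34),
    D = list(evalue = 1e-10, qcov = 0,  minw = 0,  dens = 0.34),
    E = list(evalue = 1e-10, qcov = 0,  minw = 20, dens = 0.50),
    F = list(evalue = 1e-10, qcov = 90, minw = 20, dens = 0.50)
  )[[name]]
  list(
    name = name,
    search = search_params(evalue_cutoff = tab$evalue,
                           qcov_cutoff = tab$qcov, max_hsps = 1L),
    cluster = cluster_params(min_edge_weight = tab$minw,
                             min_density = tab$dens, max_size = 500L,
                             single_link = FALSE, min_cluster_size = 3L)
  )
}

#' Pipeline configuration
#'
#' @param cds_paths named character vector of per-species CDS FASTA paths
#'   (names are the raw species names; they are sanitized internally).
#' @param gff_paths named character vector of per-species GFF3 paths (same
#'   names as `cds_paths`).
#' @param species_tree a [species_tree()] or path to a Newick file whose
#'   leaves are the sanitized species labels.
#' @param out_dir run directory (created).
#' @param preset preset name, `"A"`..`"F"`.
#' @param search,cluster optional explicit [search_params()] /
#'   [cluster_params()] overriding the preset.
#' @param msa an [msa_params()].
#' @param rbh_only keep only reciprocal best hits when building edges.
#' @param select_longest keep only the longest CDS per gene.
#' @param seed integer seed recorded in the manifest (the pipeline itself
#'   is deterministic; the seed also drives any simulation upstream).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cds_paths, gff_paths, species_tree, out_dir,
                            preset = "D", search = NULL, cluster = NULL,
                            msa = msa_params(), rbh_only = FALSE,
                            select_longest = TRUE, seed = 1L) {
  stopifnot(length(cds_paths) >= 1, !is.null(names(cds_paths)),
            identical(sort(names(cds_paths)), sort(names(gff_paths))))
  p <- genefamr::preset(preset)
  structure(list(cds_paths = cds_paths, gff_paths = gff_paths,
                 species_tree = species_tree, out_dir = out_dir,
                 preset = p$name,
                 search = if (is.null(search)) p$search else search,
                 cluster = if (is.null(cluster)) p$cluster else cluster,
                 msa = msa, rbh_only = isTRUE(rbh_only),
                 select_longest = isTRUE(select_longest),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full gene-family pipeline
#'
#' Executes prepare, translate, similarity search, hit parsing, clustering,
#' per-family protein alignment, codon back-translation, gene-tree
#' construction and reconciliation, aggregation into the SQLite store, and
#' orphan identification. Every intermediate is persisted in its standard
#' text format under the run directory, and a JSON manifest records the
#' configuration, seed and per-stage counts. Reruns with identical inputs
#' and seed reproduce byte-identical text outputs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the run directory, per-stage counts and
#'   the kept families.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  # -- prepare ---------------------------------------------------------------
  species_raw <- names(config$cds_paths)
  labels <- sanitize_species(species_raw)
  if (anyDuplicated(labels)) stop("species labels collide after sanitization")
  all_feats <- list(); all_cds <- list()
  for (i in seq_along(species_raw)) {
    sp_name <- species_raw[i]
    lab <- labels[i]
    feats <- stage("prepare", read_gff3(config$gff_paths[[sp_name]], lab))
    cds <- stage("prepare", read_fasta(config$cds_paths[[sp_name]], "nt"))
    st <- feature_store(feats)
    if (config$select_longest) {
      cds <- stage("prepare", select_longest_cds(cds, st))
    }
    cds <- stage("prepare", mangle_headers(cds, lab))
    all_feats[[lab]] <- feats
    all_cds[[lab]] <- cds
  }
  store <- feature_store(do.call(rbind, all_feats))
  cds <- do.call(rbind, all_cds)
  attr(cds, "moltype") <- "nt"
  class(cds) <- c("seq_set", "data.frame")
  cds <- cds[order(cds$id), , drop = FALSE]
  rownames(cds) <- NULL
  write_fasta(cds, out("prepared_cds.fasta"))
  sp <- if (inherits(config$species_tree, "species_tree")) {
    config$species_tree
  } else {
    stage("prepare", read_species_tree(config$species_tree))
  }
  missing_sp <- setdiff(labels, tree_leaves(sp$root))
  if (length(missing_sp) > 0) {
    stop("species absent from species tree: ",
         paste(missing_sp, collapse = ", "))
  }
  # -- translate -------------------------------------------------------------
  proteins <- stage("translate", translate_set(cds))
  write_fasta(proteins, out("proteins.fasta"))
  # -- similarity search -----------------------------------------------------
  hits <- stage("search", all_vs_all(proteins, config$search))
  write_tabular12(hits, out("hits.tsv"))
  # -- edges -----------------------------------------------------------------
  edges <- stage("parse-hits", parse_hits(hits, rbh_only = config$rbh_only))
  write_edges(edges, out("edges.tsv"))
  # -- clustering ------------------------------------------------------------
  clusters <- stage("cluster",
                    hcluster(edges, config$cluster, nodes = proteins$id))
  write_clusters(clusters, out("clusters.txt"))
  filt <- split_and_filter(clusters, config$cluster)
  writeLines(filt$discarded_ids, out("discarded_ids.txt"))
  # -- per-family alignment, back-translation, trees -------------------------
  fam_dir <- out("families")
  dir.create(fam_dir, showWarnings = FALSE)
  species_map <- stats::setNames(cds$species, cds$id)
  families <- vector("list", length(filt$kept))
  for (i in seq_along(filt$kept)) {
    ids <- filt$kept[[i]]
    fam_prots <- subset_fasta(proteins, ids)
    prot_aln <- stage("align", align_family(fam_prots, config$msa))
    write_fasta_aln(prot_aln, file.path(fam_dir,
                                        sprintf("family%03d_prot.fasta_aln", i)))
    fam_cds <- subset_fasta(cds, ids)
    codon_aln <- stage("backtranslate",
                       back_translate_alignment(prot_aln, fam_cds))
    write_fasta_aln(codon_aln, file.path(fam_dir,
                                         sprintf("family%03d_codon.fasta_aln", i)))
    cands <- stage("tree", build_candidate_trees(codon_aln, prot_aln))
    tree <- stage("tree", select_and_root(cands, sp,
                                          species = species_map[ids]))
    write_nhx(tree, file.path(fam_dir, sprintf("family%03d.nhx", i)))
    families[[i]] <- make_family_record(i, tree, prot_aln)
  }
  # -- aggregate and orphans -------------------------------------------------
  store_path <- out("families.sqlite")
  stage("aggregate", aggregate_families(families, store, store_path))
  orphans <- stage("orphans",
                   find_orphans(cds$id, edges, filt$discarded_ids, cds))
  write_fasta(orphans, out("orphans.fasta"))
  counts <- list(species = length(labels), cds = nrow(cds),
                 proteins = nrow(proteins), hits = nrow(hits),
                 edges = nrow(edges), clusters = length(clusters),
                 families = length(filt$kept),
                 discarded_ids = length(filt$discarded_ids),
                 orphans = nrow(orphans))
  manifest <- list(
    package = "genefamr",
    version = as.character(utils::packageVersion("genefamr")),
    preset = config$preset, seed = config$seed,
    rbh_only = config$rbh_only,
    search = unclass(config$search), cluster = unclass(config$cluster),
    msa = unclass(config$msa), counts = counts)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(list(out_dir = config$out_dir, counts = counts,
                 families = filt$kept, store = store_path))
}

#' Family-count summary
#'
#' Summarizes a clustering result the way large-scale runs are usually
#' reported: total number of families, number larger than 200 members,
#' number smaller than 3, the largest size and the mean size.
#'
#' @param clusters list of member-id vectors.
#' @return A one-row data frame.
#' @export
family_stats <- function(clusters) {
  sizes <- lengths(clusters)
  data.frame(families = length(sizes),
             larger_than_200 = sum(sizes > 200),
             smaller_than_3 = sum(sizes < 3),
             largest = if (length(sizes)) max(sizes) else 0L,
             mean_size = if (length(sizes)) mean(sizes) else NA_real_)
}
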