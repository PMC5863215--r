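#' CIGAR encoding of aligned rows
#'
#' Run-length encodes a gapped alignment row: residue runs become `M`
#' tokens, gap runs `D` tokens, with counts of 1 omitted on write (both
#' forms are accepted on read). This is the compact per-member alignment
#' representation stored by the aggregator, following the Compara
#' cigar-line convention.
#'
#' @param gapped_row a gapped string, e.g. `"MK-R"`.
#' @return The CIGAR string, e.g. `"2MDM"`.
#' @export
msa_to_cigar <- function(gapped_row) {
  stopifnot(length(gapped_row) == 1, nchar(gapped_row) > 0)
  chars <- strsplit(gapped_row, "")[[1]]
  if (all(chars == "-")) stop("all-gap alignment row")
  r <- rle(chars == "-")
  paste0(ifelse(r$lengths == 1, "", r$lengths),
         ifelse(r$values, "D", "M"), collapse = "")
}

#' @rdname msa_to_cigar
#' @param cigar a CIGAR string over `M`/`D` tokens.
#' @param ungapped the ungapped sequence whose length must equal the sum of
#'   `M` counts.
#' @export
cigar_to_row <- function(cigar, ungapped) {
  m <- gregexpr("([0-9]*)([MD])", cigar)[[1]]
  if (m[1] == -1 || sum(attr(m, "match.length")) != nchar(cigar)) {
    stop("malformed CIGAR string: ", cigar)
  }
  tokens <- regmatches(cigar, gregexpr("[0-9]*[MD]", cigar))[[1]]
  counts <- as.integer(sub("[MD]$", "", tokens))
  counts[is.na(counts)] <- 1L
  ops <- substr(tokens, nchar(tokens), nchar(tokens))
  if (sum(counts[ops == "M"]) != nchar(ungapped)) {
    stop("CIGAR M-length ", sum(counts[ops == "M"]),
         " does not match ungapped length ", nchar(ungapped))
  }
  out <- character(length(tokens))
  pos <- 1L
  for (k in seq_along(tokens)) {
    if (ops[k] == "M") {
      out[k] <- substr(ungapped, pos, pos + counts[k] - 1L)
      pos <- pos + counts[k]
    } else {
      out[k] <- strrep("-", counts[k])
    }
  }
  paste(out, collapse = "")
}

#' Family records
#'
#' One aggregated gene family: its identifier, its NHX gene tree, and one
#' CIGAR-encoded protein alignment row per member.
#'
#' @param family_id integer family identifier.
#' @param newick the NHX tree string.
#' @param members data frame with columns `id` (sequence/leaf id) and
#'   `cigar`.
#' @return A `family_record`.
#' @export
family_record <- function(family_id, newick, members) {
  stopifnot(all(c("id", "cigar") %in% names(members)))
  leaf_ids <- tree_leaves(parse_newick(newick))
  if (!setequal(leaf_ids, members$id)) {
    stop("family ", family_id, ": member ids do not match gene-tree leaves")
  }
  structure(list(family_id = as.integer(family_id), newick = newick,
                 members = members), class = "family_record")
}

#' Build a family record from a gene tree and protein alignment
#'
#' @param family_id integer identifier.
#' @param tree an annotated `gene_tree`.
#' @param prot_aln the family's [protein_alignment()].
#' @return A [family_record()].
#' @export
make_family_record <- function(family_id, tree, prot_aln) {
  members <- data.frame(
    id = names(prot_aln),
    cigar = vapply(as.character(prot_aln), msa_to_cigar, character(1)),
    stringsAsFactors = FALSE)
  family_record(family_id, nhx_string(tree), members)
}

store_schema_version <- "genefamr-store-1"

#' Aggregate families, alignments and features into an SQLite store
#'
#' Writes a single-file relational database with tables `gene`,
#' `transcript`, `exon`, `cds_segment`, `gene_family` and `family_member`
#' (foreign keys enforced), plus a `transcript_species` view joining
#' transcripts to their gene's species. Family member ids are demangled to
#' transcript ids against the feature store's species labels.
#'
#' @param families list of [family_record()]s.
#' @param store a [feature_store()].
#' @param path output SQLite file path (overwritten).
#' @return `path`, invisibly.
#' @export
aggregate_families <- function(families, store, path) {
  stopifnot(inherits(store, "feature_store"))
  fam_ids <- vapply(families, `[[`, integer(1), "family_id")
  if (anyDuplicated(fam_ids)) {
    stop("duplicate family_id(s): ",
         paste(unique(fam_ids[duplicated(fam_ids)]), collapse = ", "))
  }
  feats <- store$features
  species_labels <- unique(feats$species)
  transcripts <- feats[feats$ftype == "transcript", , drop = FALSE]
  resolve <- function(id) {
    if (id %in% transcripts$feature_id) return(id)
    plain <- tryCatch(demangle_id(id, species_labels),
                      error = function(e) NA_character_)
    if (!is.na(plain) && plain %in% transcripts$feature_id) return(plain)
    stop("family member '", id, "' has no transcript in the feature store")
  }
  if (file.exists(path)) unlink(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  DBI::dbExecute(con, "CREATE TABLE meta (key TEXT PRIMARY KEY, value TEXT)")
  DBI::dbExecute(con, "INSERT INTO meta VALUES ('schema_version', :v)",
                 params = list(v = store_schema_version))
  DBI::dbExecute(con, "CREATE TABLE gene (
    gene_id TEXT PRIMARY KEY, symbol TEXT, species TEXT NOT NULL,
    chrom TEXT NOT NULL, start INTEGER NOT NULL, end INTEGER NOT NULL,
    strand TEXT NOT NULL)")
  DBI::dbExecute(con, "CREATE TABLE transcript (
    transcript_id TEXT PRIMARY KEY,
    gene_id TEXT NOT NULL REFERENCES gene(gene_id),
    start INTEGER NOT NULL, end INTEGER NOT NULL)")
  DBI::dbExecute(con, "CREATE TABLE exon (
    exon_id TEXT NOT NULL,
    transcript_id TEXT NOT NULL REFERENCES transcript(transcript_id),
    rank INTEGER NOT NULL, start INTEGER NOT NULL, end INTEGER NOT NULL,
    PRIMARY KEY (transcript_id, rank))")
  DBI::dbExecute(con, "CREATE TABLE cds_segment (
    transcript_id TEXT NOT NULL REFERENCES transcript(transcript_id),
    rank INTEGER NOT NULL, start INTEGER NOT NULL, end INTEGER NOT NULL,
    PRIMARY KEY (transcript_id, rank))")
  DBI::dbExecute(con, "CREATE TABLE gene_family (
    family_id INTEGER PRIMARY KEY, newick TEXT NOT NULL)")
  DBI::dbExecute(con, "CREATE TABLE family_member (
    family_id INTEGER NOT NULL REFERENCES gene_family(family_id),
    transcript_id TEXT NOT NULL REFERENCES transcript(transcript_id),
    cigar TEXT NOT NULL,
    PRIMARY KEY (family_id, transcript_id))")
  DBI::dbExecute(con, "CREATE VIEW transcript_species AS
    SELECT t.transcript_id AS transcript_id, g.species AS species
    FROM transcript t JOIN gene g ON t.gene_id = g.gene_id")
  genes <- feats[feats$ftype == "gene", , drop = FALSE]
  DBI::dbWriteTable(con, "gene", data.frame(
    gene_id = genes$feature_id, symbol = genes$symbol,
    species = genes$species, chrom = genes$chrom, start = genes$start,
    end = genes$end, strand = genes$strand, stringsAsFactors = FALSE),
    append = TRUE)
  DBI::dbWriteTable(con, "transcript", data.frame(
    transcript_id = transcripts$feature_id, gene_id = transcripts$parent_id,
    start = transcripts$start, end = transcripts$end,
    stringsAsFactors = FALSE), append = TRUE)
  exons <- feats[feats$ftype == "exon", , drop = FALSE]
  if (nrow(exons) > 0) {
    DBI::dbWriteTable(con, "exon", data.frame(
      exon_id = exons$feature_id, transcript_id = exons$parent_id,
      rank = exons$rank, start = exons$start, end = exons$end,
      stringsAsFactors = FALSE), append = TRUE)
  }
  cds <- feats[feats$ftype == "cds_segment", , drop = FALSE]
  if (nrow(cds) > 0) {
    DBI::dbWriteTable(con, "cds_segment", data.frame(
      transcript_id = cds$parent_id, rank = cds$rank, start = cds$start,
      end = cds$end, stringsAsFactors = FALSE), append = TRUE)
  }
  for (fam in families) {
    DBI::dbExecute(con, "INSERT INTO gene_family VALUES (:id, :nwk)",
                   params = list(id = fam$family_id, nwk = fam$newick))
    tr_ids <- vapply(fam$members$id, resolve, character(1))
    DBI::dbWriteTable(con, "family_member", data.frame(
      family_id = fam$family_id, transcript_id = unname(tr_ids),
      cigar = fam$members$cigar, stringsAsFactors = FALSE), append = TRUE)
  }
  invisible(path)
}

#' Query helpers for the aggregated store
#'
#' @param path path to a store written by [aggregate_families()].
#' @param query an SQL query string.
#' @return A data frame.
#' @export
store_query <- function(path, query) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbGetQuery(con, query)
}

#' @rdname store_query
#' @export
transcript_species <- function(path) {
  store_query(path, "SELECT * FROM transcript_species ORDER BY transcript_id")
}

#' Identify orphan genes
#'
#' Orphans are the sequences that either never made it into the similarity
#' graph (no edge in either column) or belonged to a cluster discarded by
#' the size filter. The returned set is deduplicated and sorted.
#'
#' @param all_cds_ids ids of every CDS that entered the pipeline.
#' @param edges the edge data frame produced by [parse_hits()].
#' @param discarded_ids ids discarded by [split_and_filter()].
#' @param cds the CDS [seq_set()] to extract orphan sequences from.
#' @return The orphan [seq_set()] (possibly empty).
#' @export
find_orphans <- function(all_cds_ids, edges, discarded_ids, cds) {
  in_graph <- union(edges$a, edges$b)
  orphan_ids <- sort(unique(c(setdiff(all_cds_ids, in_graph), discarded_ids)))
  subset_fasta(cds, orphan_ids)
}
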