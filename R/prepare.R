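#' Sanitize a species label
#'
#' Lowercases, replaces runs of whitespace with underscores and drops every
#' other non-alphanumeric character, so that mangled identifiers survive
#' Newick/NHX and tabular formats unquoted.
#'
#' @param species a species name, e.g. `"Homo sapiens"`.
#' @return The sanitized label, e.g. `"homo_sapiens"`.
#' @export
sanitize_species <- function(species) {
  s <- tolower(trimws(species))
  s <- gsub("[[:space:]]+", "_", s)
  gsub("[^a-z0-9_]", "", s)
}

#' Append the species label to every sequence identifier
#'
#' Each id becomes `<original_id>_<species_label>` and the record's species
#' field is set, so that downstream tree tools can recover the species of
#' every gene from the identifier alone.
#'
#' @param records a [seq_set()].
#' @param species sanitized species label (see [sanitize_species()]).
#' @return The mangled [seq_set()].
#' @export
mangle_headers <- function(records, species) {
  stopifnot(inherits(records, "seq_set"))
  if (length(species) != 1 || is.na(species) || species == "") {
    stop("species label must be a single non-empty string")
  }
  if (species != sanitize_species(species)) {
    stop("species label '", species, "' is not sanitized; use sanitize_species()")
  }
  new_ids <- paste0(records$id, "_", species)
  dup <- new_ids[duplicated(new_ids)]
  if (length(dup) > 0) {
    stop("header mangling causes id collision(s): ",
         paste(unique(dup), collapse = ", "))
  }
  seq_set(id = new_ids, seq = records$seq, species = species,
          moltype = seq_moltype(records))
}

#' Recover the original identifier from a mangled one
#'
#' Uses longest-suffix match against the declared species labels, since the
#' labels may themselves contain underscores.
#'
#' @param id mangled identifier(s).
#' @param species_labels character vector of sanitized species labels.
#' @return For `demangle_id`, the original identifier(s); for
#'   `species_of_id`, the matched species label(s).
#' @export
demangle_id <- function(id, species_labels) {
  sp <- species_of_id(id, species_labels)
  substr(id, 1L, nchar(id) - nchar(sp) - 1L)
}

#' @rdname demangle_id
#' @export
species_of_id <- function(id, species_labels) {
  labs <- species_labels[order(nchar(species_labels), decreasing = TRUE)]
  vapply(id, function(x) {
    for (s in labs) {
      if (endsWith(x, paste0("_", s))) return(s)
    }
    stop("id '", x, "' does not end in any declared species label")
  }, character(1), USE.NAMES = FALSE)
}

#' Keep only the longest CDS per gene
#'
#' Each CDS record is resolved (demangling the id if necessary) to a
#' transcript in the feature store, and for every gene only the longest CDS
#' is retained. Length ties are broken by the lexicographically smallest
#' transcript id, so the selection is deterministic.
#'
#' @param cds a nucleotide [seq_set()] of per-transcript CDS.
#' @param store a [feature_store()].
#' @return The filtered [seq_set()], one record per gene.
#' @export
select_longest_cds <- function(cds, store) {
  stopifnot(inherits(cds, "seq_set"), inherits(store, "feature_store"))
  feats <- store$features
  transcripts <- feats[feats$ftype == "transcript", , drop = FALSE]
  species_labels <- unique(feats$species)
  tr_ids <- vapply(seq_len(nrow(cds)), function(i) {
    id <- cds$id[i]
    if (id %in% transcripts$feature_id) return(id)
    plain <- tryCatch(demangle_id(id, species_labels), error = function(e) NA_character_)
    if (!is.na(plain) && plain %in% transcripts$feature_id) return(plain)
    stop("CDS id '", id, "' has no transcript in the feature store")
  }, character(1))
  genes <- transcripts$parent_id[match(tr_ids, transcripts$feature_id)]
  ord <- order(genes, -nchar(cds$seq), tr_ids)
  keep_rows <- ord[!duplicated(genes[ord])]
  out <- cds[sort(keep_rows), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "moltype") <- seq_moltype(cds)
  class(out) <- class(cds)
  out
}
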