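#' Gene feature stores
#'
#' A `feature_store` holds gene/transcript/exon/CDS-segment records parsed
#' from GFF3 (or the equivalent JSON serialization), indexed by feature id
#' and by parent. Coordinates are 1-based inclusive throughout, as in GFF3.
#'
#' @param features data frame with columns `feature_id`, `ftype`,
#'   `parent_id`, `species`, `chrom`, `start`, `end`, `strand`, `rank`
#'   (and optionally `symbol`).
#' @return A `feature_store`.
#' @export
feature_store <- function(features) {
  need <- c("feature_id", "ftype", "parent_id", "species", "chrom",
            "start", "end", "strand", "rank")
  miss <- setdiff(need, names(features))
  if (length(miss) > 0) stop("missing feature columns: ", paste(miss, collapse = ", "))
  if (!"symbol" %in% names(features)) features$symbol <- NA_character_
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$rank <- as.integer(features$rank)
  bad <- features$end < features$start
  if (any(bad)) {
    stop("end < start for feature(s): ",
         paste(features$feature_id[bad], collapse = ", "))
  }
  if (!all(features$ftype %in% c("gene", "transcript", "exon", "cds_segment"))) {
    stop("unknown feature type(s): ",
         paste(setdiff(features$ftype, c("gene", "transcript", "exon",
                                         "cds_segment")), collapse = ", "))
  }
  # ids must be unique except cds_segment, which is keyed by (transcript, rank)
  keyed <- features[features$ftype != "cds_segment", ]
  dup <- keyed$feature_id[duplicated(keyed$feature_id)]
  if (length(dup) > 0) stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  # referential closure
  has_parent <- features$parent_id != ""
  unresolved <- setdiff(features$parent_id[has_parent], features$feature_id)
  if (length(unresolved) > 0) {
    stop("unresolvable Parent id(s): ", paste(unresolved, collapse = ", "))
  }
  # cds_segment ranks consecutive from 1 per transcript
  cds <- features[features$ftype == "cds_segment", ]
  if (nrow(cds) > 0) {
    by_tr <- split(cds$rank, cds$parent_id)
    ok <- vapply(by_tr, function(r) identical(sort(r), seq_along(r)), logical(1))
    if (!all(ok)) {
      stop("non-consecutive cds_segment ranks for transcript(s): ",
           paste(names(by_tr)[!ok], collapse = ", "))
    }
  }
  rownames(features) <- NULL
  structure(list(features = features), class = "feature_store")
}

#' @export
print.feature_store <- function(x, ...) {
  tab <- table(x$features$ftype)
  cat("feature_store:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

fs_features <- function(store, ftype = NULL) {
  f <- store$features
  if (!is.null(ftype)) f <- f[f$ftype %in% ftype, , drop = FALSE]
  f
}

fs_get <- function(store, id) {
  f <- store$features
  f[f$feature_id == id & f$ftype != "cds_segment", , drop = FALSE]
}

fs_children <- function(store, id, ftype = NULL) {
  f <- store$features
  f <- f[f$parent_id == id, , drop = FALSE]
  if (!is.null(ftype)) f <- f[f$ftype %in% ftype, , drop = FALSE]
  f[order(f$rank, f$feature_id), , drop = FALSE]
}

# gene id owning a transcript id
fs_gene_of <- function(store, transcript_id) {
  tr <- fs_get(store, transcript_id)
  tr <- tr[tr$ftype == "transcript", , drop = FALSE]
  if (nrow(tr) == 0) {
    stop("no transcript with id '", transcript_id, "' in feature store")
  }
  tr$parent_id[1]
}

#' Read gene features from GFF3
#'
#' Parses gene, mRNA (mapped to `transcript`), exon and CDS lines, keeping
#' only the ID/Parent/Name attributes. CDS segments are ranked 1..n along
#' each transcript in 5'-to-3' order (ascending start on `+`, descending on
#' `-`); exons likewise. Coordinates stay 1-based inclusive.
#'
#' @param path path to a GFF3 file.
#' @param species species label applied to all records.
#' @return A data frame of feature records (see [feature_store()]).
#' @export
read_gff3 <- function(path, species) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  type <- as.character(df$type)
  keep <- type %in% c("gene", "mRNA", "exon", "CDS")
  df <- df[keep, , drop = FALSE]
  type <- type[keep]
  get1 <- function(col) {
    if (!col %in% names(df)) return(rep(NA_character_, nrow(df)))
    v <- df[[col]]
    if (is(v, "List") || is.list(v)) {
      vapply(as.list(v), function(e) if (length(e) == 0) NA_character_ else as.character(e[1]),
             character(1))
    } else as.character(v)
  }
  ids <- get1("ID")
  parents <- get1("Parent")
  symbols <- get1("Name")
  ftype <- c(gene = "gene", mRNA = "transcript", exon = "exon",
             CDS = "cds_segment")[type]
  is_cds <- ftype == "cds_segment"
  if (any(is.na(parents[ftype != "gene"]))) {
    stop("feature(s) without Parent attribute in ", path)
  }
  if (any(is.na(ids[!is_cds]))) stop("feature(s) without ID attribute in ", path)
  ids[is_cds & is.na(ids)] <- paste0(parents[is_cds & is.na(ids)], "_cds")
  feats <- data.frame(
    feature_id = ids,
    ftype = ftype,
    parent_id = ifelse(is.na(parents), "", parents),
    species = species,
    chrom = as.character(df$seqnames),
    start = as.integer(df$start),
    end = as.integer(df$end),
    strand = as.character(df$strand),
    rank = 1L,
    symbol = symbols,
    stringsAsFactors = FALSE
  )
  # rank exons and cds segments 5'->3' within each transcript
  for (ft in c("exon", "cds_segment")) {
    sel <- which(feats$ftype == ft)
    if (length(sel) == 0) next
    for (tr in unique(feats$parent_id[sel])) {
      idx <- sel[feats$parent_id[sel] == tr]
      neg <- any(feats$strand[idx] == "-")
      ord <- order(feats$start[idx], decreasing = neg)
      feats$rank[idx[ord]] <- seq_along(idx)
    }
  }
  # referential check with named offender
  known <- feats$feature_id[feats$ftype %in% c("gene", "transcript")]
  need_parent <- feats$ftype != "gene"
  bad <- need_parent & !(feats$parent_id %in% known)
  if (any(bad)) {
    stop("unresolvable Parent '", feats$parent_id[which(bad)[1]],
         "' for feature '", feats$feature_id[which(bad)[1]], "'")
  }
  rownames(feats) <- NULL
  feats
}

#' Read gene features from the JSON serialization
#'
#' Accepts an array of objects with the same fields as the GFF3-derived
#' feature records: `feature_id`, `ftype`, `parent_id`, `species`, `chrom`,
#' `start`, `end`, `strand`, `rank` (and optionally `symbol`).
#'
#' @param path path to a JSON file.
#' @return A data frame of feature records.
#' @export
read_features_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!is.data.frame(x)) stop("expected a JSON array of feature objects")
  if (is.null(x$parent_id)) x$parent_id <- ""
  x$parent_id[is.na(x$parent_id)] <- ""
  x
}
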