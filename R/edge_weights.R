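#' Convert an e-value to an integer edge weight
#'
#' The weight is minus log10 of the e-value divided by 2, replaced with 100
#' when greater than 100, rounded half-up to an integer and floored at 0.
#' An e-value of 0 (similarity-search underflow) maps to 100, the limit of
#' the formula.
#'
#' @param evalue non-negative e-value(s).
#' @return Integer weight(s) in 0..100.
#' @export
compute_weight <- function(evalue) {
  if (any(is.na(evalue)) || any(evalue < 0)) stop("e-values must be non-negative")
  w <- ifelse(evalue == 0, Inf, -log10(evalue) / 2)
  w <- pmin(w, 100)
  w <- floor(w + 0.5)  # round half-up
  as.integer(pmax(w, 0))
}

#' Convert similarity hits to weighted graph edges
#'
#' Removes self-matches, collapses duplicate ordered pairs keeping the
#' minimum e-value, optionally keeps only reciprocal best hits, and merges
#' the two directions of each surviving pair into one undirected edge whose
#' weight is [compute_weight()] of the better directional e-value.
#'
#' A pair is a reciprocal best hit when each sequence is the other's best
#' partner, "best" meaning lowest e-value with ties broken by higher
#' bitscore and then lexicographically smallest subject id.
#'
#' @param hits a 12-column hits data frame (see [all_vs_all()]).
#' @param rbh_only keep only reciprocal best hits.
#' @return A data frame of edges with columns `a`, `b` (with `a < b`) and
#'   integer `weight`, sorted by (`a`, `b`).
#' @export
parse_hits <- function(hits, rbh_only = FALSE) {
  hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  if (nrow(hits) == 0) return(empty_edges())
  # collapse duplicate ordered pairs: min evalue (ties: max bitscore)
  ord <- order(hits$qseqid, hits$sseqid, hits$evalue, -hits$bitscore)
  hits <- hits[ord, , drop = FALSE]
  key <- paste(hits$qseqid, hits$sseqid, sep = "\r")
  hits <- hits[!duplicated(key), , drop = FALSE]
  if (rbh_only) {
    best <- best_partners(hits)
    recip <- vapply(seq_len(nrow(hits)), function(i) {
      identical(best[[hits$qseqid[i]]], hits$sseqid[i]) &&
        identical(best[[hits$sseqid[i]]], hits$qseqid[i])
    }, logical(1))
    hits <- hits[recip, , drop = FALSE]
  }
  if (nrow(hits) == 0) return(empty_edges())
  a <- pmin(hits$qseqid, hits$sseqid)
  b <- pmax(hits$qseqid, hits$sseqid)
  df <- data.frame(a = a, b = b, evalue = hits$evalue,
                   stringsAsFactors = FALSE)
  df <- df[order(df$a, df$b, df$evalue), , drop = FALSE]
  df <- df[!duplicated(paste(df$a, df$b, sep = "\r")), , drop = FALSE]
  edges <- data.frame(a = df$a, b = df$b, weight = compute_weight(df$evalue),
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  edges
}

# best partner per query: lowest evalue, then highest bitscore, then
# lexicographically smallest subject id
best_partners <- function(hits) {
  ord <- order(hits$qseqid, hits$evalue, -hits$bitscore, hits$sseqid)
  h <- hits[ord, , drop = FALSE]
  first <- h[!duplicated(h$qseqid), , drop = FALSE]
  stats::setNames(as.list(first$sseqid), first$qseqid)
}

empty_edges <- function() {
  data.frame(a = character(0), b = character(0), weight = integer(0),
             stringsAsFactors = FALSE)
}

#' Read / write the 3-column edge format
#'
#' Tab-separated `id_a`, `id_b`, integer weight: the input format of the
#' sparse-graph clustering stage.
#'
#' @param path file path.
#' @param edges an edge data frame (see [parse_hits()]).
#' @return `read_edges`: the edge data frame; `write_edges`: `path`.
#' @export
read_edges <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_edges())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3)) {
    stop("expected 3 tab-separated columns at line ", which(nf != 3)[1])
  }
  m <- do.call(rbind, parts)
  data.frame(a = m[, 1], b = m[, 2], weight = as.integer(m[, 3]),
             stringsAsFactors = FALSE)
}

#' @rdname read_edges
#' @export
write_edges <- function(edges, path) {
  writeLines(paste(edges$a, edges$b, edges$weight, sep = "\t"), path)
  invisible(path)
}
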