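#' Similarity search parameters
#'
#' Parameters of the all-vs-all protein similarity search. Scoring uses
#' BLOSUM62 with affine gap penalties (open 11, extend 1) and gapped
#' Karlin-Altschul constants lambda = 0.267, K = 0.041, pinned for
#' reproducibility. Only the single highest-scoring local alignment per
#' ordered pair is reported (`max_hsps = 1`).
#'
#' @param evalue_cutoff discard hits with e-value above this.
#' @param qcov_cutoff discard hits covering less than this percentage of the
#'   query (0-100).
#' @param word_size seed word size (kept for interface compatibility; the
#'   desk-scale search computes exact optimal local alignments).
#' @param max_hsps maximum local alignments kept per ordered pair.
#' @param matrix substitution matrix name.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return A `search_params` list.
#' @export
search_params <- function(evalue_cutoff = 1e-3, qcov_cutoff = 0,
                          word_size = 3L, max_hsps = 1L,
                          matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  stopifnot(evalue_cutoff > 0, qcov_cutoff >= 0, qcov_cutoff <= 100)
  structure(list(evalue_cutoff = evalue_cutoff, qcov_cutoff = qcov_cutoff,
                 word_size = as.integer(word_size),
                 max_hsps = as.integer(max_hsps), matrix = matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = 0.267, K = 0.041),
            class = "search_params")
}

# substitution matrix with X scoring 0 against everything
scoring_matrix <- function(name = "BLOSUM62") {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- get(name, envir = e)
  if ("X" %in% rownames(m)) {
    m["X", ] <- 0L
    m[, "X"] <- 0L
  }
  m
}

#' All-vs-all protein similarity search
#'
#' Computes, for every ordered (query, subject) pair, the optimal gapped
#' local alignment (Smith-Waterman, affine gaps) and reports it in the
#' 12-column tabular form when it passes the e-value and query-coverage
#' cutoffs. Bitscore is `(lambda * S - ln K) / ln 2` and e-value
#' `m * n * 2^(-bitscore)` with `m` the query length and `n` the total
#' number of database residues. Self-pairs are reported here; they are
#' removed downstream when hits are converted to graph edges.
#'
#' @param proteins an amino-acid [seq_set()] of at least two sequences.
#' @param params a [search_params()].
#' @return A data frame of similarity hits with the 12 standard columns,
#'   sorted by query id, then ascending e-value, then subject id.
#' @export
all_vs_all <- function(proteins, params = search_params()) {
  stopifnot(inherits(proteins, "seq_set"), inherits(params, "search_params"))
  if (nrow(proteins) < 2) stop("need at least two sequences")
  if (any(grepl("\\*", proteins$seq))) {
    stop("stop characters in protein sequence(s): ",
         paste(proteins$id[grepl("\\*", proteins$seq)], collapse = ", "))
  }
  mat <- scoring_matrix(params$matrix)
  seqs <- Biostrings::AAStringSet(stats::setNames(proteins$seq, proteins$id))
  n_db <- sum(nchar(proteins$seq))
  rows <- vector("list", nrow(proteins)^2)
  k <- 0L
  for (qi in seq_len(nrow(proteins))) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = rep(seqs[qi], length(seqs)), subject = seqs,
      type = "local", substitutionMatrix = mat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend,
      scoreOnly = FALSE)
    score <- Biostrings::score(pa)
    for (si in seq_along(seqs)) {
      if (score[si] <= 0) next
      al <- pa[si]
      bitscore <- (params$lambda * score[si] - log(params$K)) / log(2)
      m <- nchar(proteins$seq[qi])
      evalue <- m * n_db * 2^(-bitscore)
      prange <- Biostrings::pattern(al)
      srange <- Biostrings::subject(al)
      qstart <- Biostrings::start(prange); qend <- Biostrings::end(prange)
      alen <- Biostrings::nchar(al)
      nmatch <- Biostrings::nmatch(al)
      nmism <- Biostrings::nmismatch(al)
      ind <- Biostrings::nindel(al)
      gapopen <- sum(Biostrings::insertion(ind)[, "Length"]) +
        sum(Biostrings::deletion(ind)[, "Length"])
      qcov <- 100 * (qend - qstart + 1) / m
      if (evalue > params$evalue_cutoff || qcov < params$qcov_cutoff) next
      k <- k + 1L
      rows[[k]] <- data.frame(
        qseqid = proteins$id[qi], sseqid = proteins$id[si],
        pident = round(100 * nmatch / alen, 3), length = alen,
        mismatch = nmism, gapopen = gapopen,
        qstart = qstart, qend = qend,
        sstart = Biostrings::start(srange), send = Biostrings::end(srange),
        evalue = evalue, bitscore = round(bitscore, 1),
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (k == 0) empty_hits() else do.call(rbind, rows[seq_len(k)])
  hits[order(hits$qseqid, hits$evalue, hits$sseqid), , drop = FALSE] -> hits
  rownames(hits) <- NULL
  hits
}

hit_columns <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

empty_hits <- function() {
  data.frame(qseqid = character(0), sseqid = character(0),
             pident = numeric(0), length = integer(0), mismatch = integer(0),
             gapopen = integer(0), qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0), evalue = numeric(0),
             bitscore = numeric(0), stringsAsFactors = FALSE)
}

#' Read / write 12-column tabular similarity hits
#'
#' The tab-separated 12-column similarity format (the BLAST `outfmt 6`
#' dialect): qseqid, sseqid, pident, length, mismatch, gapopen, qstart,
#' qend, sstart, send, evalue, bitscore. Externally produced files are
#' accepted verbatim.
#'
#' @param path file path.
#' @param hits a hits data frame.
#' @return `read_tabular12`: the hits data frame; `write_tabular12`: `path`.
#' @export
read_tabular12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12)) {
    stop("expected 12 tab-separated columns, found ", nf[nf != 12][1],
         " at line ", which(nf != 12)[1])
  }
  m <- do.call(rbind, parts)
  hits <- data.frame(
    qseqid = m[, 1], sseqid = m[, 2], pident = as.numeric(m[, 3]),
    length = as.integer(m[, 4]), mismatch = as.integer(m[, 5]),
    gapopen = as.integer(m[, 6]), qstart = as.integer(m[, 7]),
    qend = as.integer(m[, 8]), sstart = as.integer(m[, 9]),
    send = as.integer(m[, 10]), evalue = as.numeric(m[, 11]),
    bitscore = as.numeric(m[, 12]), stringsAsFactors = FALSE)
  if (any(is.na(hits$evalue)) || any(hits$evalue < 0)) {
    stop("invalid e-value at line ",
         which(is.na(hits$evalue) | hits$evalue < 0)[1])
  }
  hits
}

#' @rdname read_tabular12
#' @export
write_tabular12 <- function(hits, path) {
  stopifnot(all(hit_columns %in% names(hits)))
  lines <- vapply(seq_len(nrow(hits)), function(i) {
    paste(vapply(hit_columns, function(col) {
      v <- hits[[col]][i]
      if (is.numeric(v)) as.character(v) else v
    }, character(1)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
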