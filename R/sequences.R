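#' Sequence sets
#'
#' A `seq_set` is the package's container for a collection of named
#' sequences: a data frame with columns `id`, `species` and `seq`, plus a
#' `moltype` attribute (`"nt"` or `"aa"`). Nucleotide sets are restricted to
#' the unambiguous IUPAC alphabet plus `N`; amino-acid sets to the one-letter
#' amino-acid codes plus `X` and `*`.
#'
#' @param id character vector of unique, whitespace-free identifiers.
#' @param seq character vector of sequences (uppercased on construction).
#' @param species character vector of species labels (may be empty strings).
#' @param moltype `"nt"` or `"aa"`.
#' @return A `seq_set` data frame.
#' @export
seq_set <- function(id, seq, species = "", moltype = c("nt", "aa")) {
  moltype <- match.arg(moltype)
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  species <- rep_len(as.character(species), length(id))
  if (length(id) != length(seq)) {
    stop("`id` and `seq` must have the same length")
  }
  if (any(is.na(id)) || any(id == "") || any(grepl("[[:space:]]", id))) {
    stop("sequence ids must be non-empty and contain no whitespace")
  }
  dup <- id[duplicated(id)]
  if (length(dup) > 0) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(nchar(seq) == 0)) {
    stop("empty sequence for id(s): ", paste(id[nchar(seq) == 0], collapse = ", "))
  }
  pat <- if (moltype == "nt") "^[ACGTN]+$" else "^[ACDEFGHIKLMNPQRSTVWYX*]+$"
  bad <- !grepl(pat, seq)
  if (any(bad)) {
    stop("illegal ", moltype, " characters in sequence(s): ",
         paste(id[bad], collapse = ", "))
  }
  out <- data.frame(id = id, species = species, seq = seq,
                    stringsAsFactors = FALSE)
  attr(out, "moltype") <- moltype
  class(out) <- c("seq_set", "data.frame")
  out
}

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set of", nrow(x), attr(x, "moltype"), "sequences\n")
  if (nrow(x) > 0) {
    show <- utils::head(x, 6)
    cat(sprintf("  %s [%s] %d nt/aa\n", show$id, show$species, nchar(show$seq)),
        sep = "")
    if (nrow(x) > 6) cat("  ...\n")
  }
  invisible(x)
}

seq_moltype <- function(x) attr(x, "moltype")

#' Read sequences from a FASTA file
#'
#' Identifiers are the first whitespace-delimited token of each header; the
#' remainder of the header is dropped. Sequences are uppercased. Duplicate
#' identifiers and characters outside the expected alphabet are rejected.
#'
#' @param path path to a FASTA file.
#' @param moltype `"nt"` or `"aa"`.
#' @param species species label recorded on every record (optional).
#' @return A [seq_set()].
#' @export
read_fasta <- function(path, moltype = c("nt", "aa"), species = "") {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("not FASTA-formatted: ", path,
                                          " (", conditionMessage(e), ")"))
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(ss), "[[:space:]]+"), `[`, character(1), 1)
  seq_set(id = ids, seq = as.character(ss), species = species,
          moltype = moltype)
}

#' Write sequences to a FASTA file
#'
#' @param x a [seq_set()] or a named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (inherits(x, "seq_set")) {
    seqs <- stats::setNames(x$seq, x$id)
  } else {
    seqs <- x
  }
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# reverse complement of an unambiguous nucleotide string (N stays N)
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         vapply(seq, function(s) {
           paste(rev(strsplit(s, "")[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}
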