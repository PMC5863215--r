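#' Alignment containers
#'
#' Alignments are ordered named character vectors of equal-length gapped
#' rows (`-` as the gap character). A `protein_alignment` must not contain
#' all-gap columns and every row must degap to a non-empty sequence; a
#' `codon_alignment` additionally has a column count divisible by 3.
#'
#' @param rows named character vector of gapped rows.
#' @return An alignment object.
#' @export
protein_alignment <- function(rows) {
  validate_alignment(rows, "protein_alignment")
}

#' @rdname protein_alignment
#' @export
codon_alignment <- function(rows) {
  aln <- validate_alignment(rows, "codon_alignment")
  if (nchar(aln[[1]]) %% 3L != 0L) {
    stop("codon alignment length must be a multiple of 3")
  }
  aln
}

validate_alignment <- function(rows, cls) {
  rows <- unlist(rows)
  if (is.null(names(rows)) || any(names(rows) == "")) {
    stop("alignment rows must be named by sequence id")
  }
  if (length(rows) == 0) stop("empty alignment")
  lens <- nchar(rows)
  if (length(unique(lens)) != 1) stop("alignment rows have unequal lengths")
  if (any(gsub("-", "", rows) == "")) stop("alignment row degaps to an empty sequence")
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  if (any(colSums(mat != "-") == 0)) stop("alignment contains an all-gap column")
  structure(rows, class = cls)
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("protein_alignment:", length(x), "rows x", nchar(x[[1]]), "columns\n")
  invisible(x)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x), "rows x", nchar(x[[1]]), "columns\n")
  invisible(x)
}

#' Remove the gaps from an alignment row
#' @param row a gapped string (or vector of them).
#' @return The ungapped string(s).
#' @export
degap <- function(row) gsub("-", "", row)

#' Read / write aligned FASTA (fasta_aln)
#'
#' Gapped multi-FASTA with `-` gaps, used for both protein and codon
#' alignments.
#'
#' @param path file path.
#' @param moltype `"aa"` (protein) or `"nt"` (codon alignment).
#' @param aln an alignment object.
#' @return `read_fasta_aln`: an alignment object; `write_fasta_aln`: `path`.
#' @export
read_fasta_aln <- function(path, moltype = c("aa", "nt")) {
  moltype <- match.arg(moltype)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty alignment file: ", path)
  ids <- vapply(strsplit(names(ss), "[[:space:]]+"), `[`, character(1), 1)
  rows <- stats::setNames(toupper(as.character(ss)), ids)
  if (moltype == "aa") protein_alignment(rows) else codon_alignment(rows)
}

#' @rdname read_fasta_aln
#' @export
write_fasta_aln <- function(aln, path) {
  write_fasta(stats::setNames(as.character(aln), names(aln)), path)
}

# alignment as a character matrix (rows = sequences)
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(as.character(aln), ""))
  rownames(m) <- names(aln)
  m
}
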