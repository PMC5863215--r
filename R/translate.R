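#' Translate a coding sequence
#'
#' Standard-code translation in any of the six reading frames: frames 1-3
#' translate the forward strand offset by 0-2 positions, frames 4-6 the
#' reverse complement likewise. A trailing partial codon is dropped and a
#' single terminal stop codon is stripped; internal stops are retained as
#' `*` and flagged via the `internal_stops` attribute. Codons containing `N`
#' translate to `X`.
#'
#' @param seq a nucleotide string (or single-row [seq_set()]).
#' @param frame reading frame, 1-6.
#' @return The peptide string, with attribute `internal_stops` (logical).
#' @export
translate_cds <- function(seq, frame = 1L) {
  if (inherits(seq, "seq_set")) {
    stopifnot(nrow(seq) == 1)
    seq <- seq$seq
  }
  stopifnot(frame %in% 1:6)
  s <- toupper(seq)
  if (frame > 3) {
    s <- revcomp(s)
    frame <- frame - 3L
  }
  s <- substr(s, frame, nchar(s))
  n_codons <- nchar(s) %/% 3L
  if (n_codons < 1) stop("sequence shorter than one codon in frame")
  codons <- substring(s, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (length(aa) == 0) stop("sequence translates to an empty peptide")
  pep <- paste(aa, collapse = "")
  attr(pep, "internal_stops") <- any(aa == "*")
  pep
}

#' Six-frame translation
#'
#' @param rec a single-row nucleotide [seq_set()].
#' @return An amino-acid [seq_set()] of six records with ids suffixed
#'   `_1`..`_6`.
#' @export
six_frame <- function(rec) {
  stopifnot(inherits(rec, "seq_set"), nrow(rec) == 1)
  peps <- vapply(1:6, function(f) as.character(translate_cds(rec$seq, f)),
                 character(1))
  seq_set(id = paste0(rec$id, "_", 1:6), seq = peps,
          species = rec$species, moltype = "aa")
}

#' Translate every CDS in a set (frame 1)
#'
#' @param cds a nucleotide [seq_set()].
#' @param warn_internal_stops warn when a CDS translates with internal stops.
#' @return An amino-acid [seq_set()] with the same ids.
#' @export
translate_set <- function(cds, warn_internal_stops = TRUE) {
  stopifnot(inherits(cds, "seq_set"))
  peps <- character(nrow(cds))
  flagged <- character(0)
  for (i in seq_len(nrow(cds))) {
    p <- translate_cds(cds$seq[i], 1L)
    if (isTRUE(attr(p, "internal_stops"))) flagged <- c(flagged, cds$id[i])
    peps[i] <- as.character(p)
  }
  if (warn_internal_stops && length(flagged) > 0) {
    warning("internal stop codon(s) in: ", paste(flagged, collapse = ", "))
  }
  seq_set(id = cds$id, seq = peps, species = cds$species, moltype = "aa")
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each aligned residue column expands to its source codon and each gap to
#' `---`, so the codon alignment is exactly three times as long as the
#' protein alignment. The frame-1 translation of each CDS (after stripping a
#' single terminal stop codon, which is dropped from the codon alignment)
#' must equal the degapped protein row; rows with internal stops are
#' rejected.
#'
#' @param prot_aln a [protein_alignment()].
#' @param cds a nucleotide [seq_set()] containing every aligned id.
#' @return A [codon_alignment()].
#' @export
back_translate_alignment <- function(prot_aln, cds) {
  stopifnot(inherits(prot_aln, "protein_alignment"), inherits(cds, "seq_set"))
  rows <- unclass(prot_aln)
  attributes(rows) <- list(names = names(rows))
  missing <- setdiff(names(rows), cds$id)
  if (length(missing) > 0) {
    stop("no CDS for aligned id(s): ", paste(missing, collapse = ", "))
  }
  out <- vapply(names(rows), function(id) {
    nt <- cds$seq[match(id, cds$id)]
    n_codons <- nchar(nt) %/% 3L
    if (nchar(nt) %% 3L != 0L) {
      stop("CDS length of '", id, "' is not a multiple of 3")
    }
    codons <- substring(nt, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
    aa <- unname(Biostrings::GENETIC_CODE[codons])
    aa[is.na(aa)] <- "X"
    if (aa[length(aa)] == "*") {
      aa <- aa[-length(aa)]
      codons <- codons[-length(codons)]
    }
    if (any(aa == "*")) {
      stop("internal stop codon in CDS '", id, "'")
    }
    row_chars <- strsplit(rows[[id]], "")[[1]]
    residues <- row_chars[row_chars != "-"]
    if (length(residues) != length(aa) || any(residues != aa)) {
      bad <- if (length(residues) != length(aa)) {
        min(length(residues), length(aa)) + 1L
      } else which(residues != aa)[1]
      stop("translation mismatch for '", id, "' at residue ", bad,
           " (CDS translates '", paste(aa, collapse = ""),
           "', aligned row degaps to '", paste(residues, collapse = ""), "')")
    }
    pieces <- character(length(row_chars))
    pieces[row_chars == "-"] <- "---"
    pieces[row_chars != "-"] <- codons
    paste(pieces, collapse = "")
  }, character(1))
  codon_alignment(out)
}
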