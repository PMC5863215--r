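#' MSA scoring parameters
#'
#' @param matrix substitution matrix name.
#' @param gap_open,gap_extend affine gap penalties (positive costs; a gap of
#'   length L costs `gap_open + L * gap_extend`).
#' @return An `msa_params` list.
#' @export
msa_params <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.5) {
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend), class = "msa_params")
}

#' Progressive multiple alignment of a protein family
#'
#' Aligns the family progressively: pairwise global alignments give
#' p-distance estimates, a UPGMA guide tree orders the merges, and profiles
#' are aligned by global profile-profile dynamic programming with affine
#' gaps and sum-of-pairs substitution scoring. The DP traceback prefers the
#' diagonal, then the vertical move, making the result deterministic for a
#' fixed input order.
#'
#' @param proteins an amino-acid [seq_set()] of at least 2 sequences.
#' @param params an [msa_params()].
#' @return A [protein_alignment()] with rows in input order.
#' @export
align_family <- function(proteins, params = msa_params()) {
  stopifnot(inherits(proteins, "seq_set"))
  if (nrow(proteins) < 2) stop("need at least 2 sequences to align")
  if (any(nchar(gsub("-", "", proteins$seq)) == 0)) stop("empty sequence")
  mat <- scoring_matrix(params$matrix)
  ids <- proteins$id
  seqs <- stats::setNames(proteins$seq, ids)
  n <- length(ids)
  if (n == 2) {
    prof <- profile_align(profile_of(seqs[1]), profile_of(seqs[2]), mat, params)
    return(profile_to_alignment(prof, ids))
  }
  # guide tree: UPGMA on pairwise p-distances from global alignments
  ord_ids <- sort(ids)
  d <- matrix(0, n, n, dimnames = list(ord_ids, ord_ids))
  aas <- Biostrings::AAStringSet(seqs)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pa <- Biostrings::pairwiseAlignment(
        aas[ord_ids[i]], aas[ord_ids[j]], type = "global",
        substitutionMatrix = mat, gapOpening = params$gap_open,
        gapExtension = params$gap_extend)
      d[i, j] <- d[j, i] <- 1 - Biostrings::nmatch(pa) / Biostrings::nchar(pa)
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  profiles <- lapply(ord_ids, function(id) profile_of(seqs[id]))
  merged <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    get_prof <- function(m) if (m < 0) profiles[[-m]] else merged[[m]]
    merged[[k]] <- profile_align(get_prof(hc$merge[k, 1]),
                                 get_prof(hc$merge[k, 2]), mat, params)
  }
  profile_to_alignment(merged[[length(merged)]], ids)
}

# a profile is a character matrix: rows = sequences (named), cols = columns
profile_of <- function(seq) {
  m <- matrix(strsplit(unname(seq), "")[[1]], nrow = 1)
  rownames(m) <- names(seq)
  m
}

profile_to_alignment <- function(prof, id_order) {
  rows <- apply(prof, 1, paste, collapse = "")
  protein_alignment(rows[id_order[id_order %in% names(rows)]])
}

# column-pair sum-of-pairs scores, gaps scoring 0: S[i,j] =
# mean over row pairs of mat[a_i, b_j]
profile_score_matrix <- function(pa, pb, mat) {
  letters <- rownames(mat)
  count_cols <- function(p) {
    cm <- matrix(0, ncol(p), length(letters),
                 dimnames = list(NULL, letters))
    for (r in seq_len(nrow(p))) {
      ch <- p[r, ]
      ok <- which(ch != "-" & ch %in% letters)
      if (length(ok) > 0) {
        idx <- cbind(ok, match(ch[ok], letters))
        cm[idx] <- cm[idx] + 1
      }
    }
    cm
  }
  ca <- count_cols(pa); cb <- count_cols(pb)
  (ca %*% mat %*% t(cb)) / (nrow(pa) * nrow(pb))
}

# global profile-profile alignment, affine gaps (Gotoh), traceback
# preference: diagonal, then up (gap in B), then left (gap in A)
profile_align <- function(pa, pb, mat, params) {
  go <- params$gap_open; ge <- params$gap_extend
  la <- ncol(pa); lb <- ncol(pb)
  S <- profile_score_matrix(pa, pb, mat)
  NEG <- -1e18
  M <- matrix(NEG, la + 1, lb + 1)
  X <- matrix(NEG, la + 1, lb + 1)  # column of A against gap in B (up)
  Y <- matrix(NEG, la + 1, lb + 1)  # column of B against gap in A (left)
  # traceback matrices store the predecessor state: 1 = M, 2 = X, 3 = Y
  tbM <- matrix(0L, la + 1, lb + 1)
  tbX <- matrix(0L, la + 1, lb + 1)
  tbY <- matrix(0L, la + 1, lb + 1)
  M[1, 1] <- 0
  for (i in seq_len(la)) {
    open_s <- M[i, 1] - go - ge
    ext_s <- X[i, 1] - ge
    X[i + 1, 1] <- max(open_s, ext_s)
    tbX[i + 1, 1] <- if (open_s >= ext_s) 1L else 2L
  }
  for (j in seq_len(lb)) {
    open_s <- M[1, j] - go - ge
    ext_s <- Y[1, j] - ge
    Y[1, j + 1] <- max(open_s, ext_s)
    tbY[1, j + 1] <- if (open_s >= ext_s) 1L else 3L
  }
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      prev <- c(M[i, j], X[i, j], Y[i, j])
      b <- which.max(prev)  # ties: M, then X, then Y
      M[i + 1, j + 1] <- prev[b] + S[i, j]
      tbM[i + 1, j + 1] <- b
      xcand <- c(M[i, j + 1] - go - ge, X[i, j + 1] - ge,
                 Y[i, j + 1] - go - ge)
      bx <- which.max(xcand)
      X[i + 1, j + 1] <- xcand[bx]
      tbX[i + 1, j + 1] <- bx
      ycand <- c(M[i + 1, j] - go - ge, X[i + 1, j] - go - ge,
                 Y[i + 1, j] - ge)
      by <- which.max(ycand)
      Y[i + 1, j + 1] <- ycand[by]
      tbY[i + 1, j + 1] <- by
    }
  }
  # traceback, preferring diagonal, then up, then left
  i <- la; j <- lb
  fin <- c(M[la + 1, lb + 1], X[la + 1, lb + 1], Y[la + 1, lb + 1])
  state <- which.max(fin)
  cols_a <- integer(0)  # 0 marks a gap column
  cols_b <- integer(0)
  while (i > 0 || j > 0) {
    if (state == 1) {
      cols_a <- c(i, cols_a); cols_b <- c(j, cols_b)
      state <- tbM[i + 1, j + 1]
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      cols_a <- c(i, cols_a); cols_b <- c(0L, cols_b)
      state <- tbX[i + 1, j + 1]
      i <- i - 1
    } else {
      cols_a <- c(0L, cols_a); cols_b <- c(j, cols_b)
      state <- tbY[i + 1, j + 1]
      j <- j - 1
    }
  }
  build <- function(p, cols) {
    out <- matrix("-", nrow(p), length(cols))
    rownames(out) <- rownames(p)
    nz <- cols != 0L
    out[, nz] <- p[, cols[nz], drop = FALSE]
    out
  }
  rbind(build(pa, cols_a), build(pb, cols_b))
}

#' Sum-of-pairs score of an alignment
#'
#' Scores every pair of rows with the substitution matrix and affine gap
#' costs (columns where both rows are gaps are skipped for that pair); used
#' as a sanity floor for the progressive aligner.
#'
#' @param aln a [protein_alignment()].
#' @param params an [msa_params()].
#' @return The total score.
#' @export
sum_of_pairs_score <- function(aln, params = msa_params()) {
  mat <- scoring_matrix(params$matrix)
  m <- alignment_matrix(aln)
  total <- 0
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):nrow(m)) {
      a <- m[i, ]; b <- m[j, ]
      keep <- !(a == "-" & b == "-")
      a <- a[keep]; b <- b[keep]
      gap <- a == "-" | b == "-"
      total <- total + sum(mat[cbind(a[!gap], b[!gap])])
      # affine gap runs
      r <- rle(gap)
      runs <- r$lengths[r$values]
      total <- total - sum(params$gap_open + runs * params$gap_extend)
    }
  }
  total
}
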