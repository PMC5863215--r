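# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and Biostrings alignment routines) so that tests compare
# two unrelated implementations.

# full Smith-Waterman with affine gaps (gap of length L costs open + L*ext);
# returns the optimal local alignment score
sw_oracle_score <- function(a, b, mat, open = 11, ext = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  la <- length(a); lb <- length(b)
  NEG <- -1e9
  M <- matrix(0, la + 1, lb + 1)
  X <- matrix(NEG, la + 1, lb + 1)
  Y <- matrix(NEG, la + 1, lb + 1)
  best <- 0
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
      s <- mat[a[i], b[j]]
      M[i + 1, j + 1] <- max(0, M[i, j] + s, X[i, j] + s, Y[i, j] + s)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# best partner per query id by a double loop: lowest evalue, then highest
# bitscore, then lexicographically smallest subject
rbh_oracle <- function(hits) {
  hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  qs <- unique(hits$qseqid)
  best <- list()
  for (q in qs) {
    h <- hits[hits$qseqid == q, , drop = FALSE]
    b <- NULL
    for (r in seq_len(nrow(h))) {
      if (is.null(b) ||
          h$evalue[r] < b$evalue ||
          (h$evalue[r] == b$evalue && h$bitscore[r] > b$bitscore) ||
          (h$evalue[r] == b$evalue && h$bitscore[r] == b$bitscore &&
           h$sseqid[r] < b$sseqid)) {
        b <- h[r, ]
      }
    }
    best[[q]] <- b$sseqid
  }
  pairs <- character(0)
  for (q in qs) {
    s <- best[[q]]
    if (!is.null(best[[s]]) && best[[s]] == q) {
      pairs <- c(pairs, paste(min(q, s), max(q, s)))
    }
  }
  sort(unique(pairs))
}

# greedy agglomeration recomputed from scratch each iteration straight off
# the raw edge list (no incremental state)
naive_hcluster <- function(edges, nodes, params) {
  edges <- edges[edges$weight >= params$min_edge_weight, , drop = FALSE]
  clusters <- as.list(sort(nodes))
  cross <- function(ci, cj) {
    sel <- (edges$a %in% ci & edges$b %in% cj) |
      (edges$a %in% cj & edges$b %in% ci)
    list(w = sum(edges$weight[sel]), n = sum(sel))
  }
  repeat {
    best <- NULL
    nc <- length(clusters)
    for (i in seq_len(nc - 1)) {
      for (j in (i + 1):nc) {
        if (length(clusters[[i]]) + length(clusters[[j]]) > params$max_size) next
        cw <- cross(clusters[[i]], clusters[[j]])
        if (cw$n < 1) next
        denom <- length(clusters[[i]]) * length(clusters[[j]])
        if (cw$n / denom < params$min_density) next
        avg <- cw$w / denom
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        cand <- list(i = i, j = j, avg = avg, n = cw$n, key = key)
        if (is.null(best) || cand$avg > best$avg + 1e-12 ||
            (abs(cand$avg - best$avg) <= 1e-12 &&
             (cand$n > best$n ||
              (cand$n == best$n &&
               (key[1] < best$key[1] ||
                (key[1] == best$key[1] && key[2] < best$key[2])))))) {
          best <- cand
        }
      }
    }
    if (is.null(best)) break
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  canon_clusters(clusters)
}

canon_clusters <- function(clusters) {
  cl <- unname(lapply(clusters, sort))
  cl[order(vapply(cl, `[`, character(1), 1))]
}

# exhaustive enumeration of all global alignments of two short sequences
# under affine gaps (gap of length L costs open + L*ext); returns max score
enumerate_pair_score <- function(a, b, mat, open = 10, ext = 0.5) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  # memo-free recursion: tiny inputs only
  rec2 <- function(i, j, state) {
    if (i > length(a) && j > length(b)) return(0)
    out <- -Inf
    if (i <= length(a) && j <= length(b)) {
      out <- max(out, mat[a[i], b[j]] + rec2(i + 1, j + 1, "M"))
    }
    if (i <= length(a)) {
      cost <- ext + if (state == "X") 0 else open
      out <- max(out, -cost + rec2(i + 1, j, "X"))
    }
    if (j <= length(b)) {
      cost <- ext + if (state == "Y") 0 else open
      out <- max(out, -cost + rec2(i, j + 1, "Y"))
    }
    out
  }
  rec2(1, 1, "M")
}

# random sense-codon CDS (ATG ... stop) for fixtures
random_cds <- function(n_codons, with_stop = TRUE) {
  codes <- Biostrings::GENETIC_CODE
  sense <- names(codes[codes != "*"])
  paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE),
                      collapse = ""),
         if (with_stop) sample(c("TAA", "TAG", "TGA"), 1) else "")
}
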