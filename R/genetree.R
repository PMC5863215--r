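#' Pairwise distance matrices from alignments
#'
#' Distances use pairwise deletion: only columns where both rows are
#' ungapped are compared. Corrected distances that are undefined (Poisson
#' with p close to 1; Jukes-Cantor with p >= 3/4) are clamped to a ceiling
#' of 10 substitutions per site.
#'
#' @param aln an alignment object.
#' @param method one of `"p"` (proportion of differing sites), `"poisson"`
#'   (`-ln(1 - p)`), `"jc"` (Jukes-Cantor) or `"p3"` (p-distance restricted
#'   to third codon positions; codon alignments only).
#' @return A symmetric distance matrix keyed by sequence id.
#' @export
alignment_distances <- function(aln, method = c("p", "poisson", "jc", "p3")) {
  method <- match.arg(method)
  mat <- alignment_matrix(aln)
  if (method == "p3") {
    if (ncol(mat) %% 3 != 0) stop("third-position distance needs a codon alignment")
    mat <- mat[, seq(3, ncol(mat), by = 3), drop = FALSE]
  }
  ids <- rownames(mat)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  ceiling_d <- 10
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(ok)) {
        stop("no overlapping ungapped sites between '", ids[i], "' and '",
             ids[j], "'")
      }
      p <- mean(mat[i, ok] != mat[j, ok])
      dij <- switch(method,
        p = p,
        p3 = p,
        poisson = if (p >= 1 - exp(-ceiling_d)) ceiling_d else -log(1 - p),
        jc = if (p >= 0.75 * (1 - exp(-4 / 3 * ceiling_d))) ceiling_d
             else -0.75 * log(1 - 4 * p / 3))
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Wraps the standard neighbor-joining algorithm; the 3-taxon case is solved
#' directly by the three-point formulas. Negative branch lengths are clamped
#' to zero. The result is an unrooted tree.
#'
#' @param d symmetric distance matrix keyed by sequence id.
#' @return An `ape` `phylo` object (unrooted).
#' @export
nj_tree <- function(d) {
  ids <- rownames(d)
  if (length(ids) < 3) stop("need at least 3 sequences for a tree")
  if (length(ids) == 3) {
    v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    txt <- sprintf("(%s:%.10f,%s:%.10f,%s:%.10f);",
                   ids[1], max(v1, 0), ids[2], max(v2, 0), ids[3], max(v3, 0))
    return(ape::read.tree(text = txt))
  }
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Build candidate gene trees from a family's alignments
#'
#' Builds exactly five unrooted neighbor-joining trees from five distance
#' estimators: protein p-distance, protein Poisson-corrected distance,
#' nucleotide p-distance, nucleotide Jukes-Cantor distance, and a
#' synonymous-proxy p-distance restricted to third codon positions.
#'
#' @param codon_aln a [codon_alignment()].
#' @param prot_aln a [protein_alignment()] over the same ids.
#' @return A list of 5 unrooted `phylo` trees.
#' @export
build_candidate_trees <- function(codon_aln, prot_aln) {
  if (!setequal(names(codon_aln), names(prot_aln))) {
    stop("codon and protein alignments cover different ids")
  }
  if (length(prot_aln) < 3) stop("need at least 3 sequences")
  list(
    nj_tree(alignment_distances(prot_aln, "p")),
    nj_tree(alignment_distances(prot_aln, "poisson")),
    nj_tree(alignment_distances(codon_aln, "p")),
    nj_tree(alignment_distances(codon_aln, "jc")),
    nj_tree(alignment_distances(codon_aln, "p3"))
  )
}

# ---- rooting an unrooted phylo on each edge -------------------------------

# rooted nested tree from unrooted phylo, rooted at the midpoint of edge k
root_phylo_on_edge <- function(phy, k) {
  adj <- lapply(seq_len(max(phy$edge)), function(i) integer(0))
  elen <- new.env()
  for (e in seq_len(nrow(phy$edge))) {
    u <- phy$edge[e, 1]; v <- phy$edge[e, 2]
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
    assign(paste(min(u, v), max(u, v)), phy$edge.length[e], envir = elen)
  }
  ntip <- length(phy$tip.label)
  getlen <- function(u, v) get(paste(min(u, v), max(u, v)), envir = elen)
  subtree <- function(v, from, blen) {
    node <- tree_node(length = blen)
    nbrs <- setdiff(adj[[v]], from)
    if (v <= ntip) {
      node$label <- phy$tip.label[v]
      return(node)
    }
    node$children <- lapply(nbrs, function(w) subtree(w, v, getlen(v, w)))
    node
  }
  u <- phy$edge[k, 1]; v <- phy$edge[k, 2]
  half <- phy$edge.length[k] / 2
  tree_node(label = "", length = NA_real_,
            children = list(subtree(u, v, half), subtree(v, u, half)))
}

# ---- reconciliation -------------------------------------------------------

#' Reconcile a rooted gene tree against a species tree
#'
#' Standard last-common-ancestor reconciliation. Every leaf is mapped to its
#' species; every internal node to the species-tree LCA of its leaves' species.
#' A node is a duplication (`D`) when its mapping equals the mapping of
#' either child, otherwise a speciation (`S`). Losses are counted by the
#' path-depth formula (one loss per species-tree node skipped on the way
#' from a node to its child, children of a duplication starting at the
#' node's own mapping). Duplication nodes get a duplication consistency
#' score: the Jaccard overlap of the species sets under their two children.
#'
#' @param tree a rooted gene tree: a `gene_tree` object or a nested node
#'   whose leaf labels are sequence ids.
#' @param sp a [species_tree()].
#' @param species optional named character vector mapping leaf id to species
#'   label; when `NULL`, species are recovered from the mangled ids by
#'   longest-suffix match against the species-tree leaves.
#' @return A list with elements `tree` (annotated `gene_tree`), `dup_count`
#'   and `loss_count`.
#' @export
reconcile <- function(tree, sp, species = NULL) {
  root <- if (inherits(tree, "gene_tree")) tree$root else tree
  stopifnot(inherits(sp, "species_tree"))
  idx <- sp_index(sp)
  leaf_ids <- tree_leaves(root)
  if (is.null(species)) {
    species <- stats::setNames(
      species_of_id(leaf_ids, names(idx$leaf_of)), leaf_ids)
  }
  unknown <- setdiff(unname(species[leaf_ids]), names(idx$leaf_of))
  if (length(unknown) > 0) {
    stop("species not in species tree: ", paste(unknown, collapse = ", "))
  }
  dup <- 0L; loss <- 0L
  annotate <- function(node) {
    if (is_leaf(node)) {
      node$species <- unname(species[node$label])
      return(list(node = node, m = idx$leaf_of[[node$species]],
                  set = node$species))
    }
    if (length(node$children) != 2) {
      stop("gene tree must be binary for reconciliation")
    }
    l <- annotate(node$children[[1]])
    r <- annotate(node$children[[2]])
    node$children[[1]] <- l$node
    node$children[[2]] <- r$node
    m <- sp_lca(idx, l$m, r$m)
    is_dup <- (m == l$m) || (m == r$m)
    node$event <- if (is_dup) "D" else "S"
    node$taxon <- idx$labels[m]
    if (is_dup) {
      dup <<- dup + 1L
      inter <- length(intersect(l$set, r$set))
      node$dcs <- inter / length(union(l$set, r$set))
    }
    for (cm in c(l$m, r$m)) {
      skip <- idx$depth[cm] - idx$depth[m] - (if (is_dup) 0L else 1L)
      loss <<- loss + max(skip, 0L)
    }
    list(node = node, m = m, set = union(l$set, r$set))
  }
  res <- annotate(root)
  list(tree = structure(list(root = res$node), class = "gene_tree"),
       dup_count = dup, loss_count = loss)
}

#' Select and root the best candidate gene tree
#'
#' Roots every candidate on every edge, reconciles each rooted tree against
#' the species tree and returns the annotated tree minimizing, in order:
#' duplication count, loss count, total branch length, and finally the NHX
#' string (lexicographic), so the result is fully deterministic and
#' independent of candidate order.
#'
#' @param candidates list of unrooted `phylo` trees (see
#'   [build_candidate_trees()]).
#' @param sp a [species_tree()].
#' @param species optional leaf-id-to-species map (see [reconcile()]).
#' @return The selected annotated `gene_tree`, with attributes `dup_count`
#'   and `loss_count`.
#' @export
select_and_root <- function(candidates, sp, species = NULL) {
  stopifnot(length(candidates) >= 1)
  best <- NULL
  for (cand in candidates) {
    for (k in seq_len(nrow(cand$edge))) {
      rooted <- root_phylo_on_edge(cand, k)
      rec <- reconcile(rooted, sp, species)
      key <- list(dup = rec$dup_count, loss = rec$loss_count,
                  blen = tree_total_length(rec$tree$root),
                  nwk = node_to_newick(rec$tree$root, nhx = TRUE))
      if (is.null(best) || better_rooting(key, best$key)) {
        best <- list(key = key, rec = rec)
      }
    }
  }
  out <- best$rec$tree
  attr(out, "dup_count") <- best$rec$dup_count
  attr(out, "loss_count") <- best$rec$loss_count
  out
}

better_rooting <- function(a, b) {
  if (a$dup != b$dup) return(a$dup < b$dup)
  if (a$loss != b$loss) return(a$loss < b$loss)
  if (abs(a$blen - b$blen) > 1e-9) return(a$blen < b$blen)
  a$nwk < b$nwk
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("gene_tree:", length(tree_leaves(x$root)), "leaves\n")
  cat(node_to_newick(x$root, nhx = TRUE), ";\n", sep = "")
  invisible(x)
}

#' Write / read NHX-annotated gene trees
#'
#' Leaves carry `[&&NHX:S=<species>]`; internal nodes
#' `[&&NHX:D=Y|N:S=<mapped taxon>]` with `:DCS=<score>` on duplication
#' nodes. Reading inverts writing on structure, labels, branch lengths,
#' events and scores.
#'
#' @param tree a `gene_tree`.
#' @param path file path.
#' @return `read_nhx`: a `gene_tree`; `write_nhx`: `path`.
#' @export
write_nhx <- function(tree, path) {
  writeLines(nhx_string(tree), path)
  invisible(path)
}

#' @rdname write_nhx
#' @export
read_nhx <- function(path) {
  root <- parse_newick(paste(readLines(path), collapse = ""))
  structure(list(root = root), class = "gene_tree")
}

#' @rdname write_nhx
#' @export
nhx_string <- function(tree) {
  root <- if (inherits(tree, "gene_tree")) tree$root else tree
  paste0(node_to_newick(root, nhx = TRUE), ";")
}
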