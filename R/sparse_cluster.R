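#' Clustering parameters
#'
#' @param min_edge_weight edges lighter than this are dropped before
#'   clustering.
#' @param min_density minimum cross-edge density (cross-edge count divided
#'   by the product of the two cluster sizes) required for a merge.
#' @param max_size no cluster may grow beyond this many members.
#' @param single_link use connected-component (single-link) clustering
#'   instead of the density-constrained agglomeration.
#' @param min_cluster_size clusters smaller than this are discarded by
#'   [split_and_filter()] (gene-tree construction needs at least 3 genes).
#' @param max_cluster_size_filter optional upper size bound applied by
#'   [split_and_filter()].
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(min_edge_weight = 0L, min_density = 0.34,
                           max_size = 500L, single_link = FALSE,
                           min_cluster_size = 3L,
                           max_cluster_size_filter = NULL) {
  stopifnot(max_size >= 1, min_density >= 0, min_density <= 1)
  structure(list(min_edge_weight = as.integer(min_edge_weight),
                 min_density = min_density, max_size = as.integer(max_size),
                 single_link = isTRUE(single_link),
                 min_cluster_size = as.integer(min_cluster_size),
                 max_cluster_size_filter = max_cluster_size_filter),
            class = "cluster_params")
}

#' Sparse-graph hierarchical clustering
#'
#' Groups sequence ids into gene-family clusters from a weighted similarity
#' graph. Edges below `min_edge_weight` are dropped first. In single-link
#' mode, clusters are the connected components of the filtered graph, with
#' oversized components split by repeatedly removing the globally lightest
#' edge. Otherwise clusters are built agglomeratively: starting from
#' singletons, the pair of clusters with the highest average cross-edge
#' weight (absent edges counting 0) is merged, provided the cross-edge
#' density is at least `min_density` and the merged size at most
#' `max_size`; ties are broken by higher cross-edge count and then by the
#' lexicographically smallest pair of minimum member ids. The procedure is
#' deterministic and the merge log is returned for auditing.
#'
#' @param edges edge data frame (columns `a`, `b`, `weight`).
#' @param params a [cluster_params()].
#' @param nodes optional full node id set; ids absent from the (filtered)
#'   edges become singleton clusters.
#' @return A list of character vectors of member ids, sorted by decreasing
#'   size then smallest member id, with attribute `merge_log`.
#' @export
hcluster <- function(edges, params = cluster_params(), nodes = NULL) {
  stopifnot(inherits(params, "cluster_params"))
  if (is.null(nodes)) nodes <- union(edges$a, edges$b)
  nodes <- sort(unique(nodes))
  edges <- edges[edges$weight >= params$min_edge_weight, , drop = FALSE]
  edges <- edges[edges$a %in% nodes & edges$b %in% nodes, , drop = FALSE]
  if (params$single_link) {
    clusters <- single_link_clusters(edges, nodes, params$max_size)
    log <- NULL
  } else {
    res <- agglomerate(edges, nodes, params)
    clusters <- res$clusters
    log <- res$log
  }
  clusters <- lapply(clusters, sort)
  ord <- order(-lengths(clusters),
               vapply(clusters, `[`, character(1), 1))
  clusters <- clusters[ord]
  attr(clusters, "merge_log") <- log
  clusters
}

single_link_clusters <- function(edges, nodes, max_size) {
  g <- igraph::graph_from_data_frame(
    edges[, c("a", "b", "weight")], directed = FALSE,
    vertices = data.frame(name = nodes))
  repeat {
    comp <- igraph::components(g)
    if (max(comp$csize) <= max_size || igraph::ecount(g) == 0) break
    big <- which(comp$csize > max_size)
    in_big <- comp$membership[igraph::ends(g, igraph::E(g))[, 1]] %in% big
    w <- igraph::E(g)$weight
    cand <- which(in_big)
    drop <- cand[order(w[cand])][1]
    g <- igraph::delete_edges(g, drop)
  }
  comp <- igraph::components(g)
  split(names(comp$membership), comp$membership)
}

agglomerate <- function(edges, nodes, params) {
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  sumw <- matrix(0, n, n)
  cnt <- matrix(0L, n, n)
  if (nrow(edges) > 0) {
    ia <- idx[edges$a]; ib <- idx[edges$b]
    for (k in seq_along(ia)) {
      sumw[ia[k], ib[k]] <- sumw[ia[k], ib[k]] + edges$weight[k]
      sumw[ib[k], ia[k]] <- sumw[ia[k], ib[k]]
      cnt[ia[k], ib[k]] <- cnt[ia[k], ib[k]] + 1L
      cnt[ib[k], ia[k]] <- cnt[ia[k], ib[k]]
    }
  }
  members <- as.list(nodes)
  alive <- rep(TRUE, n)
  minid <- nodes
  size <- rep(1L, n)
  log <- list()
  repeat {
    best <- NULL
    live <- which(alive)
    for (ii in seq_along(live)) {
      i <- live[ii]
      if (ii == length(live)) break
      js <- live[(ii + 1):length(live)]
      js <- js[cnt[i, js] >= 1L & size[i] + size[js] <= params$max_size]
      if (length(js) == 0) next
      denom <- as.numeric(size[i]) * size[js]
      dens <- cnt[i, js] / denom
      js2 <- js[dens >= params$min_density]
      if (length(js2) == 0) next
      avg <- sumw[i, js2] / (as.numeric(size[i]) * size[js2])
      for (t in seq_along(js2)) {
        j <- js2[t]
        key <- sort(c(minid[i], minid[j]))
        cand <- list(i = i, j = j, avg = avg[t], cnt = cnt[i, j], key = key)
        if (is.null(best) ||
            cand$avg > best$avg + 1e-12 ||
            (abs(cand$avg - best$avg) <= 1e-12 &&
             (cand$cnt > best$cnt ||
              (cand$cnt == best$cnt &&
               (key[1] < best$key[1] ||
                (key[1] == best$key[1] && key[2] < best$key[2])))))) {
          best <- cand
        }
      }
    }
    if (is.null(best)) break
    i <- best$i; j <- best$j
    log[[length(log) + 1]] <- data.frame(
      x = minid[i], y = minid[j], avg_weight = best$avg,
      cross_edges = best$cnt,
      density = best$cnt / (as.numeric(size[i]) * size[j]),
      merged_size = size[i] + size[j], stringsAsFactors = FALSE)
    members[[i]] <- c(members[[i]], members[[j]])
    size[i] <- size[i] + size[j]
    minid[i] <- min(minid[i], minid[j])
    alive[j] <- FALSE
    sumw[i, ] <- sumw[i, ] + sumw[j, ]
    sumw[, i] <- sumw[i, ]
    cnt[i, ] <- cnt[i, ] + cnt[j, ]
    cnt[, i] <- cnt[i, ]
    sumw[i, i] <- 0; cnt[i, i] <- 0L
  }
  list(clusters = members[alive],
       log = if (length(log)) do.call(rbind, log) else NULL)
}

#' Filter clusters by size
#'
#' Splits a clustering result into kept clusters and the ids of discarded
#' ones. Clusters smaller than `min_cluster_size` (default 3) or, when set,
#' larger than `max_cluster_size_filter` are discarded; their member ids
#' feed the orphan-gene workflow.
#'
#' @param clusters list of member-id vectors (see [hcluster()]).
#' @param params a [cluster_params()].
#' @return A list with elements `kept` (list of sorted id vectors, ordered
#'   by first id) and `discarded_ids` (sorted character vector).
#' @export
split_and_filter <- function(clusters, params = cluster_params()) {
  sizes <- lengths(clusters)
  drop <- sizes < params$min_cluster_size
  if (!is.null(params$max_cluster_size_filter)) {
    drop <- drop | sizes > params$max_cluster_size_filter
  }
  kept <- lapply(clusters[!drop], sort)
  kept <- kept[order(vapply(kept, `[`, character(1), 1))]
  discarded <- sort(unique(unlist(clusters[drop], use.names = FALSE)))
  if (is.null(discarded)) discarded <- character(0)
  list(kept = kept, discarded_ids = discarded)
}

#' Subset sequences by id list
#'
#' Returns the records whose ids are listed, in list order (the per-cluster
#' FASTA extraction step).
#'
#' @param records a [seq_set()].
#' @param ids unique ids to keep.
#' @param missing_action `"error"` or `"warn"` when an id is absent.
#' @return The subset [seq_set()] in `ids` order.
#' @export
subset_fasta <- function(records, ids, missing_action = c("error", "warn")) {
  missing_action <- match.arg(missing_action)
  stopifnot(inherits(records, "seq_set"), !anyDuplicated(ids))
  hit <- match(ids, records$id)
  if (anyNA(hit)) {
    msg <- paste0("id(s) not in sequence set: ",
                  paste(ids[is.na(hit)], collapse = ", "))
    if (missing_action == "error") stop(msg) else warning(msg)
    hit <- hit[!is.na(hit)]
  }
  out <- records[hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "moltype") <- seq_moltype(records)
  class(out) <- class(records)
  out
}

#' Write / read cluster lists
#'
#' One line per cluster of tab-separated member ids.
#'
#' @param clusters list of id vectors.
#' @param path file path.
#' @return `read_clusters`: a list of id vectors; `write_clusters`: `path`.
#' @export
write_clusters <- function(clusters, path) {
  writeLines(vapply(clusters, paste, character(1), collapse = "\t"), path)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  lines <- readLines(path)
  strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
}
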