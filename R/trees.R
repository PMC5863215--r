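# Nested-list tree structure shared by species trees and gene trees.
# A node is list(label, length, children, species, event, dcs, taxon);
# leaves have zero children. Species trees carry taxon labels on internal
# nodes; gene trees carry per-leaf species and per-internal-node event
# annotations ("S"/"D") with a duplication consistency score on "D" nodes.

tree_node <- function(label = "", length = NA_real_, children = list()) {
  list(label = label, length = length, children = children,
       species = NA_character_, event = NA_character_, dcs = NA_real_,
       taxon = NA_character_)
}

is_leaf <- function(node) length(node$children) == 0

tree_leaves <- function(node) {
  if (is_leaf(node)) return(node$label)
  unlist(lapply(node$children, tree_leaves), use.names = FALSE)
}

tree_total_length <- function(node) {
  own <- if (is.na(node$length)) 0 else node$length
  own + sum(vapply(node$children, tree_total_length, numeric(1)))
}

# ---- Newick / NHX parsing -------------------------------------------------

#' Parse a Newick or NHX string
#'
#' Recursive-descent parser for Newick with optional `[&&NHX:...]` comments.
#' Recognized NHX tags: `S` (species/taxon), `D` (`Y`/`N`) and `DCS`
#' (duplication consistency score).
#'
#' @param text a Newick/NHX string (single tree, `;`-terminated or not).
#' @return The root node (nested list).
#' @keywords internal
parse_newick <- function(text) {
  text <- gsub("[\r\n[:space:]]+", "", text)
  pos <- 1L
  n <- nchar(text)
  peek <- function() if (pos > n) "" else substr(text, pos, pos)
  parse_node <- function() {
    node <- tree_node()
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        node$children[[length(node$children) + 1]] <- parse_node()
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("malformed Newick near position ", pos)
      }
    }
    # label
    start <- pos
    while (pos <= n && !substr(text, pos, pos) %in% c(",", ")", ":", ";", "[", "(")) {
      pos <<- pos + 1L
    }
    node$label <- substr(text, start, pos - 1L)
    if (peek() == ":") {
      pos <<- pos + 1L
      start <- pos
      while (pos <= n && !substr(text, pos, pos) %in% c(",", ")", ";", "[")) {
        pos <<- pos + 1L
      }
      node$length <- as.numeric(substr(text, start, pos - 1L))
    }
    if (peek() == "[") {
      close <- regexpr("]", substr(text, pos, n), fixed = TRUE)
      if (close < 0) stop("unterminated NHX comment")
      comment <- substr(text, pos, pos + close - 1L)
      pos <<- pos + close
      node <- apply_nhx(node, comment)
    }
    node
  }
  root <- parse_node()
  if (!peek() %in% c(";", "")) stop("trailing characters after tree")
  root
}

apply_nhx <- function(node, comment) {
  body <- sub("^\\[&&NHX:?", "", sub("\\]$", "", comment))
  if (body == "") return(node)
  for (kv in strsplit(body, ":", fixed = TRUE)[[1]]) {
    parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed NHX tag '", kv, "'")
    key <- parts[1]; val <- parts[2]
    if (key == "S") {
      if (is_leaf(node)) node$species <- val else node$taxon <- val
    } else if (key == "D") {
      node$event <- if (val == "Y") "D" else "S"
    } else if (key == "DCS") {
      node$dcs <- as.numeric(val)
    }
  }
  node
}

# ---- Newick / NHX serialization -------------------------------------------

format_branch_length <- function(x) {
  if (is.na(x)) "" else paste0(":", format(x, digits = 10, scientific = FALSE,
                                           trim = TRUE))
}

node_to_newick <- function(node, nhx = FALSE) {
  inner <- if (is_leaf(node)) {
    node$label
  } else {
    paste0("(", paste(vapply(node$children, node_to_newick, character(1),
                             nhx = nhx), collapse = ","), ")", node$label)
  }
  out <- paste0(inner, format_branch_length(node$length))
  if (nhx) {
    tags <- character(0)
    if (is_leaf(node)) {
      if (!is.na(node$species)) tags <- c(tags, paste0("S=", node$species))
    } else {
      if (!is.na(node$event)) {
        tags <- c(tags, paste0("D=", if (node$event == "D") "Y" else "N"))
      }
      if (!is.na(node$taxon)) tags <- c(tags, paste0("S=", node$taxon))
      if (!is.na(node$dcs)) {
        tags <- c(tags, paste0("DCS=", format(round(node$dcs, 6), trim = TRUE,
                                              scientific = FALSE)))
      }
    }
    if (length(tags) > 0) {
      out <- paste0(out, "[&&NHX:", paste(tags, collapse = ":"), "]")
    }
  }
  out
}

# ---- species trees --------------------------------------------------------

#' Species trees
#'
#' A `species_tree` is a rooted tree whose leaves are species labels.
#' Multifurcations are resolved deterministically on construction by
#' repeatedly joining the two children with the lexicographically smallest
#' leaf sets; unlabeled internal nodes receive postorder labels `n1`, `n2`,
#' ...
#'
#' @param root a nested tree node (see [parse_newick()]).
#' @return A `species_tree` object.
#' @export
species_tree <- function(root) {
  root <- binarize_node(root)
  leaves <- tree_leaves(root)
  if (anyDuplicated(leaves)) {
    stop("duplicate species label(s): ",
         paste(unique(leaves[duplicated(leaves)]), collapse = ", "))
  }
  root <- label_internals(root)$node
  structure(list(root = root), class = "species_tree")
}

# resolve multifurcations: repeatedly join the two children whose smallest
# leaf labels sort first
binarize_node <- function(node) {
  if (is_leaf(node)) return(node)
  node$children <- lapply(node$children, binarize_node)
  while (length(node$children) > 2) {
    keys <- vapply(node$children, function(ch) min(tree_leaves(ch)), character(1))
    ord <- order(keys)
    a <- node$children[[ord[1]]]; b <- node$children[[ord[2]]]
    joined <- tree_node(label = "", length = 0, children = list(a, b))
    node$children <- c(node$children[-ord[1:2]], list(joined))
  }
  node
}

label_internals <- function(node, counter = 0L) {
  if (is_leaf(node)) return(list(node = node, counter = counter))
  for (i in seq_along(node$children)) {
    res <- label_internals(node$children[[i]], counter)
    node$children[[i]] <- res$node
    counter <- res$counter
  }
  if (is.null(node$label) || node$label == "") {
    counter <- counter + 1L
    node$label <- paste0("n", counter)
  }
  list(node = node, counter = counter)
}

#' @export
print.species_tree <- function(x, ...) {
  cat("species_tree with", length(tree_leaves(x$root)), "species:",
      paste(tree_leaves(x$root), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a species tree in Newick format
#'
#' @param path file path.
#' @param tree a [species_tree()].
#' @return `read_species_tree`: a `species_tree`; `write_species_tree`:
#'   `path`.
#' @export
read_species_tree <- function(path) {
  species_tree(parse_newick(paste(readLines(path), collapse = "")))
}

#' @rdname read_species_tree
#' @export
write_species_tree <- function(tree, path) {
  writeLines(paste0(node_to_newick(tree$root), ";"), path)
  invisible(path)
}

#' Build a species tree from a taxonomy parent table
#'
#' @param taxa data frame with columns `label` and `parent` (empty or `NA`
#'   parent marks the root lineage). Leaves are the labels that are never
#'   parents; unary internal nodes are collapsed.
#' @return A [species_tree()].
#' @export
species_tree_from_taxonomy <- function(taxa) {
  stopifnot(all(c("label", "parent") %in% names(taxa)))
  label <- as.character(taxa$label)
  parent <- as.character(taxa$parent)
  parent[is.na(parent)] <- ""
  if (anyDuplicated(label)) stop("duplicate label(s) in taxonomy table")
  # the root is the unique node with no parent: either a label whose parent
  # is empty/unlisted, or a parent name that never appears as a label
  implicit <- setdiff(unique(parent[parent != ""]), label)
  rootless <- label[parent == ""]
  roots <- unique(c(implicit, rootless))
  if (length(roots) == 0) {
    stop("taxonomy table has no root; it contains a cycle")
  }
  if (length(roots) > 1) {
    stop("taxonomy table must have exactly one root, found: ",
         paste(roots, collapse = ", "))
  }
  # cycle check by walking up from every label
  for (l in label) {
    seen <- character(0)
    cur <- l
    while (cur %in% label) {
      if (cur %in% seen) stop("cycle in taxonomy table at '", cur, "'")
      seen <- c(seen, cur)
      cur <- parent[match(cur, label)]
    }
  }
  root_name <- roots
  build <- function(name) {
    kids <- label[parent == name]
    node <- tree_node(label = name, length = 1)
    if (length(kids) == 0) return(node)
    node$children <- lapply(sort(kids), build)
    if (length(node$children) == 1) {
      # collapse unary node
      child <- node$children[[1]]
      child$length <- sum(c(child$length, node$length), na.rm = TRUE)
      return(child)
    }
    node
  }
  root <- build(root_name)
  if (is_leaf(root)) {
    root$length <- NA_real_
  }
  species_tree(root)
}

# flatten a species tree for LCA queries
sp_index <- function(tree) {
  nodes <- list(); parent <- integer(0); depth <- integer(0)
  labels <- character(0)
  walk <- function(node, par, dep) {
    idx <- length(labels) + 1L
    labels[idx] <<- node$label
    parent[idx] <<- par
    depth[idx] <<- dep
    for (ch in node$children) walk(ch, idx, dep + 1L)
  }
  walk(tree$root, 0L, 0L)
  leaf_idx <- stats::setNames(seq_along(labels), labels)
  is_leaf_v <- !(seq_along(labels) %in% parent)
  list(labels = labels, parent = parent, depth = depth,
       leaf_of = leaf_idx[is_leaf_v])
}

sp_lca <- function(index, i, j) {
  while (index$depth[i] > index$depth[j]) i <- index$parent[i]
  while (index$depth[j] > index$depth[i]) j <- index$parent[j]
  while (i != j) { i <- index$parent[i]; j <- index$parent[j] }
  i
}
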