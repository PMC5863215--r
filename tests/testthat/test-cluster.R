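edge_df <- function(a, b, w) {
  data.frame(a = a, b = b, weight = as.integer(w), stringsAsFactors = FALSE)
}

test_that("a fully connected triangle clusters together", {
  edges <- edge_df(c("A", "B", "A"), c("B", "C", "C"), c(100, 100, 100))
  cl <- hcluster(edges, cluster_params(min_density = 0.34))
  expect_equal(cl[[1]], c("A", "B", "C"))
  expect_length(cl, 1)
})

test_that("edges below the minimum weight leave singletons behind", {
  edges <- edge_df(c("A", "B", "A", "D"), c("B", "C", "C", "E"),
                   c(100, 100, 100, 10))
  cl <- hcluster(edges, cluster_params(min_edge_weight = 20,
                                       min_density = 0.34))
  expect_equal(cl, list(c("A", "B", "C"), "D", "E"), ignore_attr = TRUE)
})

test_that("low cross-density forbids merging two triangles over a bridge", {
  edges <- edge_df(c("A", "B", "A", "D", "E", "D", "C"),
                   c("B", "C", "C", "E", "F", "F", "D"),
                   c(100, 100, 100, 100, 100, 100, 1))
  cl <- hcluster(edges, cluster_params(min_density = 0.5))
  expect_equal(cl, list(c("A", "B", "C"), c("D", "E", "F")),
               ignore_attr = TRUE)
  # cross density between the triangles is 1/9 < 0.5; the naive oracle agrees
  oracle <- naive_hcluster(edges, c("A", "B", "C", "D", "E", "F"),
                           cluster_params(min_density = 0.5))
  expect_equal(canon_clusters(cl), oracle)
})

test_that("agglomeration matches the from-scratch greedy oracle on random graphs", {
  set.seed(5)
  for (rep in 1:8) {
    n <- sample(4:8, 1)
    nodes <- paste0("n", seq_len(n))
    pairs <- t(utils::combn(nodes, 2))
    keep <- stats::runif(nrow(pairs)) < 0.6
    edges <- edge_df(pairs[keep, 1], pairs[keep, 2],
                     sample(0:100, sum(keep), replace = TRUE))
    params <- cluster_params(min_edge_weight = sample(c(0L, 20L), 1),
                             min_density = sample(c(0.34, 0.5), 1),
                             max_size = sample(c(3L, 500L), 1))
    got <- hcluster(edges, params, nodes = nodes)
    expect_equal(canon_clusters(got), naive_hcluster(edges, nodes, params),
                 info = paste("rep", rep))
  }
})

test_that("clusters partition the node set and respect max_size", {
  set.seed(9)
  nodes <- paste0("n", 1:12)
  pairs <- t(utils::combn(nodes, 2))
  edges <- edge_df(pairs[, 1], pairs[, 2],
                   sample(50:100, nrow(pairs), replace = TRUE))
  params <- cluster_params(min_density = 0.2, max_size = 5L)
  cl <- hcluster(edges, params, nodes = nodes)
  expect_setequal(unlist(cl), nodes)
  expect_false(any(duplicated(unlist(cl))))
  expect_true(all(lengths(cl) <= 5))
  # merge log replay: every merge met the density and size constraints
  log <- attr(cl, "merge_log")
  expect_true(all(log$density >= 0.2))
  expect_true(all(log$merged_size <= 5))
})

test_that("single-link mode yields components and splits oversized ones", {
  edges <- edge_df(c("A", "B", "C", "D"), c("B", "C", "D", "E"),
                   c(50, 10, 50, 50))
  cl <- hcluster(edges, cluster_params(single_link = TRUE, max_size = 500))
  expect_equal(cl, list(c("A", "B", "C", "D", "E")), ignore_attr = TRUE)
  cl3 <- hcluster(edges, cluster_params(single_link = TRUE, max_size = 3))
  # the lightest edge (B-C, weight 10) is removed first
  expect_equal(canon_clusters(cl3), list(c("A", "B"), c("C", "D", "E")))
})

test_that("size filtering moves small and oversized clusters to discarded", {
  clusters <- list("a", c("b", "c"), c("d", "e", "f"),
                   c("g", "h", "i", "j", "k"))
  res <- split_and_filter(clusters, cluster_params(min_cluster_size = 3))
  expect_length(res$kept, 2)
  expect_equal(res$discarded_ids, c("a", "b", "c"))
  res2 <- split_and_filter(clusters,
                           cluster_params(min_cluster_size = 3,
                                          max_cluster_size_filter = 4))
  expect_length(res2$kept, 1)
  expect_true(all(c("g", "h", "i", "j", "k") %in% res2$discarded_ids))
  all_big <- list(c("a", "b", "c"), c("d", "e", "f"))
  expect_length(split_and_filter(all_big)$discarded_ids, 0)
})

test_that("subset_fasta returns records in id order and reports missing ids", {
  ss <- seq_set(c("a", "b", "c"), c("ATG", "AAA", "CCC"), moltype = "nt")
  out <- subset_fasta(ss, c("b", "a"))
  expect_equal(out$id, c("b", "a"))
  expect_equal(nrow(subset_fasta(ss, character(0))), 0)
  expect_error(subset_fasta(ss, "z"), "z")
  expect_warning(out2 <- subset_fasta(ss, c("a", "z"), missing_action = "warn"),
                 "z")
  expect_equal(out2$id, "a")
})

test_that("cluster lists roundtrip through the one-line-per-cluster format", {
  f <- withr::local_tempfile()
  cl <- list(c("a", "b", "c"), c("d", "e"))
  write_clusters(cl, f)
  expect_equal(read_clusters(f), cl)
})
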