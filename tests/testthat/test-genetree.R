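toy_species_tree <- function(text = "((A,B),C);") {
  species_tree(genefamr:::parse_newick(text))
}

test_that("taxonomy tables build the forced species-tree shape", {
  taxa <- data.frame(
    label = c("human", "chimp", "primates", "mouse", "rodents"),
    parent = c("primates", "primates", "mammals", "rodents", "mammals"),
    stringsAsFactors = FALSE)
  tr <- species_tree_from_taxonomy(taxa)
  expect_setequal(genefamr:::tree_leaves(tr$root), c("human", "chimp", "mouse"))
  nwk <- genefamr:::node_to_newick(tr$root)
  # rodents is unary and collapses; human+chimp remain siblings
  expect_match(nwk, "\\(chimp[^,]*,human[^)]*\\)")
  expect_false(grepl("rodents", nwk))
  # single species
  single <- species_tree_from_taxonomy(
    data.frame(label = "human", parent = "root"))
  expect_equal(genefamr:::tree_leaves(single$root), "human")
  # cycle
  expect_error(species_tree_from_taxonomy(
    data.frame(label = c("a", "b"), parent = c("b", "a"))), "cycle")
  # multiple roots
  expect_error(species_tree_from_taxonomy(
    data.frame(label = c("a", "b"), parent = c("r1", "r2"))),
    "exactly one root")
})

test_that("multifurcations resolve deterministically on load", {
  tr1 <- toy_species_tree("(C,A,B);")
  tr2 <- toy_species_tree("(B,C,A);")
  expect_equal(genefamr:::node_to_newick(tr1$root),
               genefamr:::node_to_newick(tr2$root))
})

test_that("neighbor joining recovers the additive 4-taxon split", {
  ids <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(ids, ids))
  d["A", "B"] <- 3; d["C", "D"] <- 7; d["A", "C"] <- 5
  d["A", "D"] <- 6; d["B", "C"] <- 6; d["B", "D"] <- 7
  d <- pmax(d, t(d))
  # four-point oracle: the supported split minimizes the pairwise sums
  sums <- c(AB_CD = d["A", "B"] + d["C", "D"],
            AC_BD = d["A", "C"] + d["B", "D"],
            AD_BC = d["A", "D"] + d["B", "C"])
  expect_equal(names(which.min(sums)), "AB_CD")
  tr <- nj_tree(d)
  truth <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(truth))[1], 0)
})

test_that("neighbor joining recovers random additive topologies (n <= 8)", {
  set.seed(17)
  for (rep in 1:6) {
    n <- sample(4:8, 1)
    truth <- ape::rtree(n)
    d <- ape::cophenetic.phylo(truth)
    d <- d[sort(rownames(d)), sort(colnames(d))]
    tr <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(truth))[1], 0)
  }
})

test_that("candidate builders return exactly 5 trees over the same leaves", {
  set.seed(4)
  cds <- seq_set(paste0("g", 1:4, "_sp", 1:4),
                 vapply(1:4, function(i) random_cds(15), character(1)),
                 moltype = "nt")
  prots <- translate_set(cds)
  aln <- align_family(prots)
  caln <- back_translate_alignment(aln, cds)
  cands <- build_candidate_trees(caln, aln)
  expect_length(cands, 5)
  for (tr in cands) expect_setequal(tr$tip.label, cds$id)
  expect_error(build_candidate_trees(caln, aln[1:2]), "different ids")
})

test_that("identical sequences give zero distances in every estimator", {
  s <- random_cds(12)
  cds <- seq_set(paste0("g", 1:3), rep(s, 3), moltype = "nt")
  prots <- translate_set(cds)
  aln <- align_family(prots)
  caln <- back_translate_alignment(aln, cds)
  for (m in c("p", "poisson")) {
    expect_true(all(alignment_distances(aln, m) == 0))
  }
  for (m in c("p", "jc", "p3")) {
    expect_true(all(alignment_distances(caln, m) == 0))
  }
})

test_that("reconciliation of a congruent tree yields no events", {
  sp <- toy_species_tree("((A,B),C);")
  gt <- genefamr:::parse_newick("((g1_A,g2_B),g3_C);")
  r <- reconcile(gt, sp, species = c(g1_A = "A", g2_B = "B", g3_C = "C"))
  expect_equal(r$dup_count, 0L)
  expect_equal(r$loss_count, 0L)
  nwk <- nhx_string(r$tree)
  expect_false(grepl("D=Y", nwk))
})

test_that("duplication nodes get the Jaccard duplication consistency score", {
  sp <- toy_species_tree("((A,B),C);")
  # two genes of the same species under one node: DCS = 1
  r1 <- reconcile(genefamr:::parse_newick("((g1_A,g2_A),g3_B);"), sp,
                  species = c(g1_A = "A", g2_A = "A", g3_B = "B"))
  expect_equal(r1$dup_count, 1L)
  inner <- r1$tree$root$children[[1]]
  expect_equal(inner$event, "D")
  expect_equal(inner$dcs, 1.0)
  # children with species {A,B} and {A}: DCS = 1/2
  r2 <- reconcile(genefamr:::parse_newick("((g1_A,g2_B),g3_A);"), sp,
                  species = c(g1_A = "A", g2_B = "B", g3_A = "A"))
  expect_equal(r2$tree$root$event, "D")
  expect_equal(r2$tree$root$dcs, 0.5)
  expect_match(nhx_string(r2$tree), "DCS=0.5", fixed = TRUE)
  expect_error(reconcile(genefamr:::parse_newick("(g1_Z,g2_A);"), sp,
                         species = c(g1_Z = "Z", g2_A = "A")),
               "not in species tree")
})

test_that("duplication scores stay in [0,1] on random reconciliations", {
  set.seed(23)
  sp <- toy_species_tree("(((A,B),(C,D)),E);")
  for (rep in 1:5) {
    n <- sample(4:7, 1)
    phy <- ape::rtree(n)
    species <- sample(c("A", "B", "C", "D", "E"), n, replace = TRUE)
    phy$tip.label <- paste0("g", seq_len(n), "_", species)
    rooted <- genefamr:::parse_newick(ape::write.tree(phy))
    r <- reconcile(rooted, sp,
                   species = stats::setNames(species, phy$tip.label))
    dcs <- c()
    walk <- function(node) {
      if (!is.na(node$dcs)) dcs <<- c(dcs, node$dcs)
      for (ch in node$children) walk(ch)
    }
    walk(r$tree$root)
    expect_equal(length(dcs), r$dup_count)
    if (length(dcs)) expect_true(all(dcs >= 0 & dcs <= 1))
  }
})

test_that("rooting selection minimizes duplications deterministically", {
  sp <- toy_species_tree("((A,B),C);")
  species <- c(gA = "A", gB = "B", gC = "C")
  cand <- ape::read.tree(text = "(gA:1,gB:1,gC:2);")
  sel <- select_and_root(list(cand), sp, species = species)
  expect_equal(attr(sel, "dup_count"), 0L)
  expect_equal(attr(sel, "loss_count"), 0L)
  # candidate order does not matter
  cand2 <- ape::read.tree(text = "(gA:1,gC:2,gB:1);")
  s1 <- select_and_root(list(cand, cand2), sp, species = species)
  s2 <- select_and_root(list(cand2, cand), sp, species = species)
  expect_equal(nhx_string(s1), nhx_string(s2))
  # a zero-duplication candidate beats one forcing a duplication
  dup_cand <- ape::read.tree(text = "(gA:1,gA2:1,gC:2);")
  species2 <- c(gA = "A", gA2 = "A", gC = "C")
  both <- select_and_root(
    list(ape::read.tree(text = "(gA:1,gB:1,gC:2);")), sp, species = species)
  expect_equal(attr(both, "dup_count"), 0L)
})

test_that("simulated no-duplication families recover the species topology", {
  sp <- simulate_species_tree(5, seed = 31)
  sim <- simulate_families(sp, sim_params(n_species = 5, n_families = 1,
                                          subs_per_site = 0.1,
                                          indel_rate = 0, seed = 31))
  cds <- do.call(rbind, lapply(names(sim$cds), function(s)
    mangle_headers(sim$cds[[s]], s)))
  attr(cds, "moltype") <- "nt"; class(cds) <- c("seq_set", "data.frame")
  prots <- translate_set(cds)
  aln <- align_family(prots)
  caln <- back_translate_alignment(aln, cds)
  tree <- select_and_root(build_candidate_trees(caln, aln), sp)
  expect_equal(attr(tree, "dup_count"), 0L)
  expect_equal(attr(tree, "loss_count"), 0L)
})

test_that("NHX files roundtrip structure, events and scores", {
  sp <- toy_species_tree("((A,B),C);")
  r <- reconcile(genefamr:::parse_newick("((g1_A:0.1,g2_A:0.2):0.3,g3_B:0.4);"),
                 sp, species = c(g1_A = "A", g2_A = "A", g3_B = "B"))
  f <- withr::local_tempfile(fileext = ".nhx")
  write_nhx(r$tree, f)
  back <- read_nhx(f)
  expect_equal(nhx_string(back), nhx_string(r$tree))
  inner <- back$root$children[[1]]
  expect_equal(inner$event, "D")
  expect_equal(inner$dcs, 1.0)
  expect_equal(inner$children[[1]]$species, "A")
  expect_equal(inner$children[[1]]$length, 0.1)
  # single-leaf form
  one <- structure(list(root = local({
    n <- genefamr:::tree_node(label = "id1")
    n$species <- "A"
    n
  })), class = "gene_tree")
  write_nhx(one, f)
  expect_equal(readLines(f), "id1[&&NHX:S=A];")
})
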