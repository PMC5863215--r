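test_that("CIGAR encoding follows the M/D run-length convention", {
  expect_equal(msa_to_cigar("MK-R"), "2MDM")
  expect_equal(msa_to_cigar("AAAA"), "4M")
  expect_equal(msa_to_cigar("--AA-"), "2D2MD")
  expect_error(msa_to_cigar("----"), "all-gap")
})

test_that("CIGAR decoding inverts encoding and checks lengths", {
  expect_equal(cigar_to_row("2MDM", "MKR"), "MK-R")
  expect_equal(cigar_to_row("2M1D1M", "MKR"), "MK-R")  # explicit 1-counts
  expect_error(cigar_to_row("3M", "MK"), "does not match")
  expect_error(cigar_to_row("2Q", "MK"), "malformed")
  set.seed(8)
  for (rep in 1:100) {
    n <- sample(1:30, 1)
    chars <- sample(c(LETTERS[1:5], "-"), n, replace = TRUE)
    if (all(chars == "-")) chars[1] <- "A"
    row <- paste(chars, collapse = "")
    cig <- msa_to_cigar(row)
    expect_equal(cigar_to_row(cig, degap(row)), row)
    expect_equal(msa_to_cigar(cigar_to_row(cig, degap(row))), cig)
  }
})

toy_store <- function() {
  feats <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(
      feature_id = c(sprintf("g%d", i), sprintf("t%d", i),
                     sprintf("t%d.e1", i), sprintf("t%d.cds", i)),
      ftype = c("gene", "transcript", "exon", "cds_segment"),
      parent_id = c("", sprintf("g%d", i), sprintf("t%d", i),
                    sprintf("t%d", i)),
      species = paste0("sp", i), chrom = "chr1",
      start = 1L + (i - 1L) * 100L, end = 50L + (i - 1L) * 100L,
      strand = "+", rank = 1L, symbol = sprintf("SYM%d", i),
      stringsAsFactors = FALSE)
  }))
  feature_store(feats)
}

toy_family <- function(id = 1L) {
  nwk <- paste0("((t1_sp1[&&NHX:S=sp1],t2_sp2[&&NHX:S=sp2])",
                "[&&NHX:D=N:S=n1],t3_sp3[&&NHX:S=sp3])[&&NHX:D=N:S=n2];")
  family_record(id, nwk, data.frame(
    id = c("t1_sp1", "t2_sp2", "t3_sp3"),
    cigar = c("5M", "4MD", "D4M"), stringsAsFactors = FALSE))
}

test_that("aggregation writes the relational store with the species view", {
  path <- withr::local_tempfile(fileext = ".sqlite")
  aggregate_families(list(toy_family()), toy_store(), path)
  expect_equal(nrow(store_query(path, "SELECT * FROM gene")), 3)
  expect_equal(nrow(store_query(path, "SELECT * FROM family_member")), 3)
  view <- transcript_species(path)
  expect_equal(view$transcript_id, c("t1", "t2", "t3"))
  expect_equal(view$species, c("sp1", "sp2", "sp3"))
  # the view equals the manual join
  manual <- store_query(path, "SELECT t.transcript_id, g.species
                               FROM transcript t JOIN gene g
                               ON t.gene_id = g.gene_id
                               ORDER BY t.transcript_id")
  expect_equal(view, manual, ignore_attr = TRUE)
  # referential integrity
  fk <- store_query(path, "SELECT count(*) AS n FROM family_member fm
                           LEFT JOIN transcript t USING (transcript_id)
                           WHERE t.transcript_id IS NULL")
  expect_equal(fk$n, 0L)
  meta <- store_query(path, "SELECT value FROM meta WHERE key='schema_version'")
  expect_match(meta$value, "store")
})

test_that("aggregation rejects unknown members and duplicate family ids", {
  path <- withr::local_tempfile(fileext = ".sqlite")
  bad <- family_record(2L, "(tX_sp1[&&NHX:S=sp1],t2_sp2[&&NHX:S=sp2]);",
                       data.frame(id = c("tX_sp1", "t2_sp2"),
                                  cigar = c("5M", "5M"),
                                  stringsAsFactors = FALSE))
  expect_error(aggregate_families(list(bad), toy_store(), path), "tX")
  expect_error(aggregate_families(list(toy_family(1L), toy_family(1L)),
                                  toy_store(), path), "duplicate family_id")
  expect_error(family_record(1L, "(a,b);",
                             data.frame(id = c("a", "z"), cigar = "M",
                                        stringsAsFactors = FALSE)),
               "do not match")
})

test_that("orphans are the edge-absent plus the discarded ids", {
  cds <- seq_set(c("a", "b", "c", "d"), rep("ATGAAA", 4), moltype = "nt")
  edges <- data.frame(a = "a", b = "b", weight = 50L,
                      stringsAsFactors = FALSE)
  orph <- find_orphans(cds$id, edges, "c", cds)
  expect_equal(orph$id, c("c", "d"))
  # no orphans when everything is in the graph
  all_edges <- data.frame(a = c("a", "c"), b = c("b", "d"), weight = 50L,
                          stringsAsFactors = FALSE)
  expect_equal(nrow(find_orphans(cds$id, all_edges, character(0), cds)), 0)
  # an id both edge-absent and discarded appears once
  orph2 <- find_orphans(cds$id, edges, c("c", "d"), cds)
  expect_equal(orph2$id, c("c", "d"))
  # no sequence is unaccounted for
  expect_setequal(union(orph$id, union(edges$a, edges$b)), cds$id)
})
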