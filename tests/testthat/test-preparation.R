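test_that("read_fasta normalizes, tokenizes headers and validates", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">t1", "acgt"), f)
  ss <- read_fasta(f, "nt")
  expect_equal(ss$id, "t1")
  expect_equal(ss$seq, "ACGT")

  writeLines(c(">t1 descr text", "ACG"), f)
  expect_equal(read_fasta(f, "nt")$id, "t1")

  writeLines(c(">t1", "ACGT", ">t1", "AAA"), f)
  expect_error(read_fasta(f, "nt"), "duplicate.*t1")

  writeLines(c(">t1", "ACGU"), f)
  expect_error(read_fasta(f, "nt"), "illegal.*t1")

  writeLines(character(0), f)
  expect_error(read_fasta(f, "nt"), "empty")
})

test_that("fasta write/read roundtrips a sequence set", {
  f <- withr::local_tempfile(fileext = ".fasta")
  ss <- seq_set(c("a", "b"), c("ATGAAA", "ATGCCC"), moltype = "nt")
  write_fasta(ss, f)
  back <- read_fasta(f, "nt")
  expect_equal(back$id, ss$id)
  expect_equal(back$seq, ss$seq)
})

gff_fixture <- function() {
  c("##gff-version 3",
    "chr1\ttest\tgene\t100\t500\t.\t+\t.\tID=g1;Name=MYGENE",
    "chr1\ttest\tmRNA\t100\t500\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\ttest\texon\t100\t199\t.\t+\t.\tID=t1.e1;Parent=t1",
    "chr1\ttest\texon\t300\t350\t.\t+\t.\tID=t1.e2;Parent=t1",
    "chr1\ttest\tCDS\t100\t199\t.\t+\t0\tID=t1.cds;Parent=t1",
    "chr1\ttest\tCDS\t300\t350\t.\t+\t0\tID=t1.cds;Parent=t1")
}

test_that("read_gff3 maps fields, types and 5'->3' CDS ranks", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff_fixture(), f)
  feats <- read_gff3(f, "homo_sapiens")
  g <- feats[feats$ftype == "gene", ]
  expect_equal(g$feature_id, "g1")
  expect_equal(c(g$start, g$end), c(100L, 500L))
  expect_equal(g$strand, "+")
  expect_equal(g$symbol, "MYGENE")
  expect_equal(feats$ftype[feats$feature_id == "t1"], "transcript")
  cds <- feats[feats$ftype == "cds_segment", ]
  expect_equal(cds$rank[order(cds$start)], c(1L, 2L))
  expect_true(all(feats$species == "homo_sapiens"))
})

test_that("read_gff3 ranks minus-strand CDS by descending start", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tt\tgene\t100\t500\t.\t-\t.\tID=g1",
               "chr1\tt\tmRNA\t100\t500\t.\t-\t.\tID=t1;Parent=g1",
               "chr1\tt\tCDS\t100\t199\t.\t-\t0\tParent=t1",
               "chr1\tt\tCDS\t300\t350\t.\t-\t0\tParent=t1"), f)
  feats <- read_gff3(f, "sp")
  cds <- feats[feats$ftype == "cds_segment", ]
  expect_equal(cds$rank[order(cds$start, decreasing = TRUE)], c(1L, 2L))
})

test_that("unresolvable Parent is rejected by name", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tt\tgene\t1\t90\t.\t+\t.\tID=g1",
               "chr1\tt\tmRNA\t1\t90\t.\t+\t.\tID=t1;Parent=g1",
               "chr1\tt\tCDS\t1\t90\t.\t+\t0\tParent=tX"), f)
  expect_error(read_gff3(f, "sp"), "tX")
})

test_that("feature_store enforces closure, coordinates and rank runs", {
  feats <- read_gff3({
    f <- withr::local_tempfile(fileext = ".gff3")
    writeLines(gff_fixture(), f)
    f
  }, "sp")
  st <- feature_store(feats)
  expect_s3_class(st, "feature_store")
  # regrouping by parent reconstructs the hierarchy
  expect_equal(genefamr:::fs_gene_of(st, "t1"), "g1")
  kids <- genefamr:::fs_children(st, "t1", "cds_segment")
  expect_equal(nrow(kids), 2)
  bad <- feats
  bad$end[1] <- 1L
  expect_error(feature_store(bad), "end < start")
  bad2 <- feats
  bad2$rank[bad2$ftype == "cds_segment"] <- c(1L, 3L)
  expect_error(feature_store(bad2), "non-consecutive")
})

test_that("JSON feature input is accepted as an alternative serialization", {
  f <- withr::local_tempfile(fileext = ".json")
  feats <- data.frame(feature_id = c("g1", "t1"),
                      ftype = c("gene", "transcript"),
                      parent_id = c("", "g1"), species = "sp", chrom = "chr1",
                      start = c(1L, 1L), end = c(9L, 9L), strand = "+",
                      rank = 1L, stringsAsFactors = FALSE)
  jsonlite::write_json(feats, f, dataframe = "rows")
  back <- read_features_json(f)
  st <- feature_store(back)
  expect_equal(genefamr:::fs_gene_of(st, "t1"), "g1")
})

test_that("header mangling appends the species label and demangles back", {
  ss <- seq_set("ENST0001", "ATGAAA", moltype = "nt")
  m <- mangle_headers(ss, "homo_sapiens")
  expect_equal(m$id, "ENST0001_homo_sapiens")
  expect_equal(m$species, "homo_sapiens")
  expect_error(mangle_headers(ss, ""), "non-empty")
  # the label must already be sanitized
  expect_error(mangle_headers(ss, "Homo sapiens"), "not sanitized")
})

test_that("mangle/demangle roundtrip holds for labels with underscores", {
  labels <- c("homo_sapiens", "sus_scrofa_domesticus", "sp1")
  ids <- c("t1", "t_2", "ENSX_00")
  for (lab in labels) {
    m <- paste0(ids, "_", lab)
    expect_equal(demangle_id(m, labels), ids)
    expect_equal(species_of_id(m, labels), rep(lab, length(ids)))
  }
  expect_error(species_of_id("t1_unknown", labels), "does not end")
})

test_that("sanitize_species lowercases and strips punctuation", {
  expect_equal(sanitize_species("Homo sapiens"), "homo_sapiens")
  expect_equal(sanitize_species("Canis lupus (familiaris)"),
               "canis_lupus_familiaris")
})

test_that("select_longest_cds keeps one longest CDS per gene", {
  feats <- data.frame(
    feature_id = c("g1", "t_a", "t_b", "g2", "t_c"),
    ftype = c("gene", "transcript", "transcript", "gene", "transcript"),
    parent_id = c("", "g1", "g1", "", "g2"),
    species = "sp", chrom = "chr1", start = 1L, end = 1000L, strand = "+",
    rank = 1L, stringsAsFactors = FALSE)
  st <- feature_store(feats)
  cds <- seq_set(c("t_a", "t_b", "t_c"),
                 c(strrep("ATG", 100), strrep("ATG", 150), "ATGAAA"),
                 moltype = "nt")
  out <- select_longest_cds(cds, st)
  expect_equal(sort(out$id), c("t_b", "t_c"))
  # tie-break: lexicographically smallest transcript id
  cds2 <- seq_set(c("t_b", "t_a", "t_c"),
                  c(strrep("ATG", 100), strrep("ATG", 100), "ATGAAA"),
                  moltype = "nt")
  out2 <- select_longest_cds(cds2, st)
  expect_equal(sort(out2$id), c("t_a", "t_c"))
  # output is a subset, exactly one per gene
  expect_true(all(out$id %in% cds$id))
  expect_error(select_longest_cds(
    seq_set("zz", "ATG", moltype = "nt"), st), "zz")
})
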