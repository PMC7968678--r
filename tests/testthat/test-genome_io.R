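test_that("native TSV gene tables read with 0-based half-open coordinates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tcontig_id\tgene_id\tstart\tend\tstrand",
               "G1\tc1\tgB\t100\t900\t+",
               "G1\tc1\tgA\t100\t400\t-",
               "G1\tc1\tgC\t1000\t2000\t+"), f)
  col <- read_gene_table(f, dialect = "tsv")
  expect_s3_class(col, "genome_collection")
  # identical starts ordered by (end, gene_id)
  expect_equal(col$genes$gene_id, c("gA", "gB", "gC"))
  expect_equal(col$genes$start[1], 100L)
  # dialect must be stated; converted tables are never reconverted
  expect_error(read_gene_table(f), "dialect")
  # malformed coordinate names its line
  writeLines(c("genome_id\tcontig_id\tgene_id\tstart\tend\tstrand",
               "G1\tc1\tg1\tabc\t900\t+"), f)
  expect_error(read_gene_table(f, dialect = "tsv"), "line 2")
})

test_that("GFF3 input is converted from 1-based inclusive exactly once", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tCDS\t1\t900\t.\t+\t0\tID=g1",
               "chr1\tsrc\tCDS\t1001\t2000\t.\t-\t0\tID=g2"), f)
  col <- read_gene_table(f, dialect = "gff3", genome_id = "G1")
  expect_equal(col$genes$start, c(0L, 1000L))
  expect_equal(col$genes$end, c(900L, 2000L))
  expect_equal(col$genes$strand, c("+", "-"))
})

test_that("empty or degenerate gene tables warn and validate", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("genome_id\tcontig_id\tgene_id\tstart\tend\tstrand", f)
  expect_warning(col <- read_gene_table(f, dialect = "tsv"), "no rows")
  expect_equal(nrow(col$genes), 0L)
  # end <= start rejected
  writeLines(c("genome_id\tcontig_id\tgene_id\tstart\tend\tstrand",
               "G1\tc1\tg1\t500\t500\t+"), f)
  expect_error(read_gene_table(f, dialect = "tsv"), "end <= start")
})

test_that("gene tables round-trip through the native writer", {
  sim <- tiny_sim()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(sim$collection, f)
  back <- read_gene_table(f, dialect = "tsv")
  expect_equal(back$genes, sim$collection$genes)
})

test_that("similarity hits parse the 12-column tabular dialect", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t80.0\t100\t5\t1\t1\t100\t1\t100\t1e-40\t200",
               "A\tB\t70.0\t100\t5\t1\t1\t100\t1\t100\t1e-10\t150"), f)
  h <- read_similarity_hits(f)
  expect_equal(nrow(h), 2L)  # duplicates kept in file order
  expect_equal(h$pct_identity[1], 80)
  expect_equal(h$e_value, c(1e-40, 1e-10))
  # downstream best-hit rule: min e-value, tie max bitscore
  b <- best_hits(h)
  expect_equal(nrow(b), 1L)
  expect_equal(b$e_value, 1e-40)
  # non-numeric e-value is a parse error
  writeLines("A\tB\t80.0\t0\t0\t0\t0\t0\t0\t0\tbad\t200", f)
  expect_error(read_similarity_hits(f), "non-numeric e-value")
  # empty file
  file.create(f)
  expect_warning(h0 <- read_similarity_hits(f), "empty")
  expect_equal(nrow(h0), 0L)
})

test_that("similarity hits round-trip through the writer", {
  sim <- tiny_sim()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_hits(sim$hits, f)
  back <- read_similarity_hits(f)
  expect_equal(back$query_id, sim$hits$query_id)
  expect_equal(back$e_value, sim$hits$e_value, tolerance = 1e-6)
})

test_that("GO annotations restrict to the vocabulary and count drops", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("P1\tGO:0030089",   # phycobilisome: in default vocabulary
               "P2\tGO:0008150",   # generic BP: out of vocabulary
               "P3\tGO:0009523",
               "P3\tGO:0008150"), f)
  ann <- read_go_annotations(f)
  expect_equal(sort(names(ann$annotations)), c("P1", "P3"))
  expect_equal(ann$annotations$P1, "GO:0030089")
  expect_equal(ann$n_dropped_terms, 2L)
  expect_equal(ann$excluded_proteins, "P2")  # only dropped terms -> no instance
  # malformed GO id
  writeLines("P1\tGO:123", f)
  expect_error(read_go_annotations(f), "malformed GO id")
})

test_that("ARFF writer/reader round-trips matrices losslessly", {
  X <- matrix(c(0L, 3L, 1L, 2L), 2, 2,
              dimnames = list(NULL, c("cl_a", "cl_b")))
  Y <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
              dimnames = list(NULL, c("GO:0009523", "GO:0030089")))
  f <- withr::local_tempfile(fileext = ".arff")
  write_arff(X, Y, f)
  lines <- readLines(f)
  expect_length(grep("^@attribute", lines), 4L)
  back <- read_arff(f)
  expect_equal(unname(back$features), unname(X))
  expect_equal(unname(back$labels), unname(Y))
  expect_equal(colnames(back$labels), colnames(Y))
  # invalid values rejected
  expect_error(write_arff(X + 2L, Y, f), "\\{0,1,2,3\\}")
  expect_error(write_arff(X, Y + 3L, f), "binary")
  # zero instances -> header-only file, warning
  expect_warning(
    write_arff(X[0, , drop = FALSE], Y[0, , drop = FALSE], f), "header-only")
  back0 <- read_arff(f)
  expect_equal(nrow(back0$features), 0L)
  expect_equal(colnames(back0$features), colnames(X))
})

test_that("ARFF round-trip holds on randomized matrices", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(1:12, 1); p <- sample(1:6, 1); L <- sample(1:4, 1)
    X <- matrix(sample(0:3, n * p, replace = TRUE), n, p,
                dimnames = list(NULL, paste0("c", seq_len(p))))
    Y <- matrix(sample(0:1, n * L, replace = TRUE), n, L,
                dimnames = list(NULL, sprintf("GO:%07d", seq_len(L))))
    f <- withr::local_tempfile(fileext = ".arff")
    write_arff(X, Y, f)
    back <- read_arff(f)
    expect_equal(unname(back$features), unname(X))
    expect_equal(unname(back$labels), unname(Y))
  }
})

test_that("collection constructor enforces its invariants", {
  g <- data.frame(gene_id = c("a", "a"), protein_id = c("p1", "p2"),
                  genome_id = "G1", contig_id = "c1",
                  start = c(0L, 10L), end = c(5L, 20L), strand = "+")
  expect_error(genome_collection(g), "duplicate")
  g$gene_id <- c("a", "b")
  g$protein_id <- c("p1", "p1")
  g$genome_id <- c("G1", "G2")
  expect_error(genome_collection(g), "more than one genome")
})
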