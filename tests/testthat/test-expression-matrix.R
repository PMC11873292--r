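test_that("MatrixMarket directory round-trips counts exactly, including ids", {
  dir <- withr::local_tempdir()
  # 3 genes x 2 cells on disk; entries (gene1, cell1) = 5, (gene2, cell2) = 1
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 2", "1 1 5", "2 2 1"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("gA", "gB", "gC"), file.path(dir, "genes.tsv"))
  writeLines(c("cell1", "cell2"), file.path(dir, "barcodes.tsv"))
  m <- read_counts(dir, "mtx-dir")
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(gene_ids(m), c("gA", "gB", "gC"))
  expect_equal(as.numeric(m$counts["cell1", "gA"]), 5)
  expect_equal(as.numeric(m$counts["cell2", "gB"]), 1)

  out <- file.path(dir, "copy")
  write_counts(m, out, "mtx-dir")
  expect_match(readLines(file.path(out, "matrix.mtx"))[1],
               "coordinate integer general")
  m2 <- read_counts(out, "mtx-dir")
  expect_equal(as.matrix(m2$counts), as.matrix(m$counts))
  expect_equal(cell_ids(m2), cell_ids(m))
})

test_that("dense TSV round-trips with gene ids in header order", {
  f <- withr::local_tempfile(fileext = ".tsv")
  cnt <- withr::with_seed(42, rand_counts(4, 3))
  m <- expr_matrix(cnt)
  write_counts(m, f, "dense-tsv")
  m2 <- read_counts(f, "dense-tsv")
  expect_equal(gene_ids(m2), colnames(cnt))
  expect_equal(as.matrix(m2$counts), as.matrix(m$counts))
})

test_that("round-trip identity holds on random sparse matrices (both formats)", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n_c <- sample(1:30, 1); n_g <- sample(1:40, 1)
      cnt <- matrix(stats::rbinom(n_c * n_g, 10, 0.1), n_c, n_g,
                    dimnames = list(sprintf("c%d", 1:n_c), sprintf("g%d", 1:n_g)))
    })
    m <- expr_matrix(cnt)
    dir <- withr::local_tempdir()
    write_counts(m, dir, "mtx-dir")
    expect_equal(as.matrix(read_counts(dir, "mtx-dir")$counts), as.matrix(m$counts))
    f <- withr::local_tempfile(fileext = ".tsv")
    write_counts(m, f, "dense-tsv")
    expect_equal(as.matrix(read_counts(f, "dense-tsv")$counts), as.matrix(m$counts))
  }
})

test_that("a large 10%-dense matrix survives the MatrixMarket round trip", {
  cnt <- withr::with_seed(0, {
    matrix(ifelse(runif(1000 * 2000) < 0.1,
                  sample.int(20, 1000 * 2000, replace = TRUE), 0),
           1000, 2000,
           dimnames = list(sprintf("c%04d", 1:1000), sprintf("g%04d", 1:2000)))
  })
  m <- expr_matrix(cnt)
  dir <- withr::local_tempdir()
  write_counts(m, dir, "mtx-dir")
  m2 <- read_counts(dir, "mtx-dir")
  expect_identical(as.matrix(m2$counts), as.matrix(m$counts))
  expect_identical(gene_ids(m2), gene_ids(m))
  expect_identical(cell_ids(m2), cell_ids(m))
})

test_that("an empty (0-cell) matrix round-trips", {
  cnt <- matrix(0, 0, 3, dimnames = list(character(0), c("a", "b", "c")))
  m <- expr_matrix(cnt)
  dir <- withr::local_tempdir()
  write_counts(m, dir, "mtx-dir")
  m2 <- read_counts(dir, "mtx-dir")
  expect_equal(dim(m2), c(0L, 3L))
  expect_equal(gene_ids(m2), c("a", "b", "c"))
})

test_that("invalid counts are rejected with the offending coordinate named", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 2 1", "2 1 -1"), file.path(dir, "matrix.mtx"))
  writeLines(c("gA", "gB"), file.path(dir, "genes.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  expect_error(read_counts(dir, "mtx-dir"), "non-negative.*c1.*gB")

  expect_error(expr_matrix(matrix(c(1, 0.5, 0, 2), 2, 2,
                                  dimnames = list(c("x", "y"), c("g1", "g2")))),
               "non-negative integer")
  expect_error(expr_matrix(matrix(0:3, 2, 2,
                                  dimnames = list(c("x", "x"), c("g1", "g2")))),
               "duplicate cell ids")
  expect_error(read_counts(file.path(dir, "nope"), "mtx-dir"), "missing file")
})

test_that("label reading orders clusters by first appearance and rejects duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1\tB", "c2\tA", "c3\tB", "c4\tA"), f)
  lab <- read_labels(f)
  expect_equal(lab$clusters, c("B", "A"))
  expect_equal(cluster_cells(lab, "A"), c("c2", "c4"))

  writeLines(c("c1\tB", "c1\tA"), f)
  expect_error(read_labels(f), "labeled twice")
  writeLines(character(0), f)
  expect_error(read_labels(f), "empty")
})

test_that("validate_labeling detects cells absent from the matrix", {
  m <- expr_matrix(withr::with_seed(7, rand_counts(3, 2)))
  lab <- cluster_labeling(c(c01 = "A", c02 = "A", c03 = "B"))
  expect_silent(validate_labeling(m, lab))
  lab2 <- cluster_labeling(c(c01 = "A", c02 = "A", c03 = "B", ghost = "B"))
  expect_error(validate_labeling(m, lab2), "not in matrix.*ghost")
  lab3 <- cluster_labeling(c(c01 = "A", c02 = "B"))
  expect_error(validate_labeling(m, lab3), "without label")
})
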