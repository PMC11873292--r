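test_that("normalization matches the closed form and the elementwise oracle", {
  # single cell, single gene: count 10 at depth 10, scaled to 10 000
  m1 <- expr_matrix(matrix(10, 1, 1, dimnames = list("c", "g")))
  nm1 <- normalize_counts(m1)
  expect_equal(as.numeric(nm1$values[1, 1]), log(1 + 10000))

  # zero counts stay zero regardless of depth
  cnt <- matrix(c(0, 5, 3, 4), 2, 2, dimnames = list(c("a", "b"), c("g1", "g2")))
  expect_equal(as.numeric(normalize_counts(expr_matrix(cnt))$values[1, 1]), 0)

  cnt <- withr::with_seed(5, rand_counts(20, 30, max_count = 8))
  nm <- normalize_counts(expr_matrix(cnt))
  expect_equal(as.matrix(nm$values), oracle_normalize(cnt), tolerance = 1e-12)
  nm2 <- normalize_counts(expr_matrix(cnt), log_base = 2)
  expect_equal(as.matrix(nm2$values), oracle_normalize(cnt, log_base = 2),
               tolerance = 1e-12)

  cnt[2, ] <- 0
  expect_error(normalize_counts(expr_matrix(cnt)), "zero-depth.*c02")
})

test_that("pct_expressing reproduces the fixture value and the per-cell loop", {
  fx <- build_rc_fixture()
  pct <- pct_expressing(fx$matrix, fx$labels, "RC")
  expect_equal(pct[["Apoe"]], 1324 / 1359)

  cnt <- withr::with_seed(8, rand_counts(15, 8))
  cnt[, 3] <- 0
  lab <- withr::with_seed(9, rand_labels(rownames(cnt), 3))
  m <- expr_matrix(cnt)
  labeling <- cluster_labeling(lab)
  for (cl in labeling$clusters)
    expect_equal(pct_expressing(m, labeling, cl),
                 oracle_pct_expressing(cnt, lab, cl))
  expect_equal(pct_expressing(m, labeling, labeling$clusters[1])[["g03"]], 0)
  expect_error(pct_expressing(m, labeling, "nope"), "unknown cluster")
})

test_that("pairwise logFC is zero under symmetry and antisymmetric by construction", {
  cnt <- withr::with_seed(21, rand_counts(10, 6))
  # duplicate the same cells into two clusters: identical distributions
  both <- rbind(cnt, cnt)
  rownames(both) <- sprintf("c%02d", 1:20)
  lab <- stats::setNames(rep(c("A", "B"), each = 10), rownames(both))
  nm <- normalize_counts(expr_matrix(both))
  labeling <- cluster_labeling(lab)
  expect_equal(unname(pairwise_logfc(nm, labeling, "A", "B")), rep(0, 6))
  ab <- pairwise_logfc(nm, labeling, "A", "B")
  ba <- pairwise_logfc(nm, labeling, "B", "A")
  expect_equal(ab, -ba)
  expect_error(pairwise_logfc(nm, labeling, "A", "A"), "must differ")
})

test_that("pairwise logFC matches the brute-force oracle on random instances", {
  for (seed in 1:10) {
    cnt <- withr::with_seed(seed, rand_counts(12, 7))
    lab <- withr::with_seed(seed + 100, rand_labels(rownames(cnt), 2))
    nm <- normalize_counts(expr_matrix(cnt))
    labeling <- cluster_labeling(lab)
    cls <- labeling$clusters
    expect_equal(pairwise_logfc(nm, labeling, cls[1], cls[2]),
                 oracle_pairwise_logfc(cnt, lab, cls[1], cls[2]),
                 tolerance = 1e-12)
  }
})

test_that("a planted fold change is recovered on the logFC scale", {
  devs <- vapply(1:20, function(seed) {
    spec <- synthetic_spec(
      clusters = c(A = 400, B = 400), n_genes = 500,
      baseline_mean = 1, dispersion = 2,
      planted_markers = list(planted_marker("mk", "A", 1.0, 8, 2)),
      seed = seed)
    sim <- generate_counts(spec)
    nm <- normalize_counts(sim$matrix)
    abs(pairwise_logfc(nm, sim$labels, "A", "B")[["mk"]] - log2(8))
  }, numeric(1))
  expect_true(all(devs <= 0.3))
})

test_that("screen thresholds are strict: logFC exactly 1 fails", {
  # equal depth 10 000 in every cell; gene gA has de-logged cluster means
  # 3 and 1, so logFC = log2((3+1)/(1+1)) = 1 exactly
  cnt <- rbind(matrix(rep(c(3, 9997), each = 4), 4, 2),
               matrix(rep(c(1, 9999), each = 4), 4, 2))
  dimnames(cnt) <- list(sprintf("c%d", 1:8), c("gA", "gB"))
  lab <- cluster_labeling(stats::setNames(rep(c("T", "O"), each = 4),
                                          rownames(cnt)))
  scr <- pan_marker_screen(expr_matrix(cnt), lab, "T")
  row <- scr[scr$gene_id == "gA", ]
  expect_equal(row$pct_in, 1)
  expect_equal(row$min_logfc, 1)
  expect_false(row$passes)
})

test_that("the planted pan-marker wins the screen; subset markers never pass", {
  spec <- synthetic_spec(seed = 4)   # default 5-cluster design
  sim <- generate_counts(spec)
  scr <- pan_marker_screen(sim$matrix, sim$labels, "RC")
  expect_equal(scr$gene_id[scr$rank == 1 & !is.na(scr$rank)], "panMarker")
  expect_false(any(scr$passes[scr$gene_id %in%
                                c("subsetA", "subsetB", "subsetC")]))
  expect_error(pan_marker_screen(
    build_rc_fixture()$matrix, build_rc_fixture()$labels, "RC"),
    ">= 2 clusters")
})

test_that("raising either threshold never adds a passing gene", {
  spec <- synthetic_spec(clusters = c(A = 80, B = 80), n_genes = 120,
                         planted_markers = list(
                           planted_marker("mk", "A", 0.95, 8, 0.5)),
                         seed = 6)
  sim <- generate_counts(spec)
  base <- pan_marker_screen(sim$matrix, sim$labels, "A",
                            min_pct = 0.5, min_logfc = 0.5)
  for (mp in c(0.6, 0.8, 0.95)) for (ml in c(0.5, 1, 2)) {
    tight <- pan_marker_screen(sim$matrix, sim$labels, "A",
                               min_pct = mp, min_logfc = ml)
    expect_true(all(tight$gene_id[tight$passes] %in% base$gene_id[base$passes]))
  }
})

test_that("the screen is invariant to cell and gene order", {
  cnt <- withr::with_seed(31, rand_counts(18, 9))
  lab <- withr::with_seed(32, rand_labels(rownames(cnt), 3))
  labeling <- cluster_labeling(lab)
  scr <- pan_marker_screen(expr_matrix(cnt), labeling, labeling$clusters[1],
                           min_pct = 0.2, min_logfc = 0.1)
  perm <- withr::with_seed(33, list(cells = sample(nrow(cnt)),
                                    genes = sample(ncol(cnt))))
  cnt2 <- cnt[perm$cells, perm$genes]
  lab2 <- cluster_labeling(lab[rownames(cnt2)],
                           clusters = labeling$clusters)
  scr2 <- pan_marker_screen(expr_matrix(cnt2), lab2, labeling$clusters[1],
                            min_pct = 0.2, min_logfc = 0.1)
  expect_equal(scr2, scr)
})

test_that("the full screen matches the brute-force oracle on small instances", {
  for (seed in 1:10) {
    cnt <- withr::with_seed(seed + 50, rand_counts(sample(6:20, 1),
                                                   sample(3:10, 1)))
    lab <- withr::with_seed(seed + 200, rand_labels(rownames(cnt),
                                                    sample(2:3, 1)))
    labeling <- cluster_labeling(lab)
    target <- labeling$clusters[1]
    scr <- pan_marker_screen(expr_matrix(cnt), labeling, target,
                             min_pct = 0.3, min_logfc = 0.2)
    orc <- oracle_screen(cnt, lab, target, min_pct = 0.3, min_logfc = 0.2)
    expect_equal(scr$gene_id, orc$gene_id)
    expect_equal(scr$pct_in, orc$pct_in, tolerance = 1e-12)
    expect_equal(scr$min_logfc, orc$min_logfc, tolerance = 1e-12)
    expect_equal(scr$passes, orc$passes)
  }
})
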