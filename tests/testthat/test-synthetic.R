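# The RC fixture rebuilds the published joint positivity table; every sum
# the publication prints must fall out of it exactly.

test_that("the RC fixture realizes all published marginals and overlaps", {
  fx <- build_rc_fixture()
  expect_equal(nrow(fx$matrix$counts), 1359L)
  flags <- as.matrix(fx$matrix$counts > 0)
  expect_equal(sum(flags[, "Apoe"]), 1324)
  expect_equal(sum(flags[, "Pthlh"]), 237)
  expect_equal(sum(flags[, "Axin2"]), 32)
  expect_equal(sum(flags[, "Foxa2"]), 57)
  expect_equal(sum(flags[, "Apoe"] & flags[, "Pthlh"]), 233)
  expect_equal(sum(flags[, "Apoe"] & flags[, "Axin2"]), 32)
  expect_equal(sum(flags[, "Apoe"] & flags[, "Foxa2"]), 51)
  sub <- flags[flags[, "Apoe"], c("Pthlh", "Axin2", "Foxa2")]
  k <- rowSums(sub)
  expect_equal(sum(k >= 1), 301)
  expect_equal(sum(k == 1), 286)
  expect_equal(sum(flags[, "Pthlh"] & flags[, "Axin2"] & flags[, "Foxa2"]), 0)
  # inclusion-exclusion with zero triples: pairwise overlap sum minus the
  # union gives the Apoe+ double-positive count
  expect_equal((233 + 32 + 51) - 301, sum(k == 2))
  expect_equal(sum(k == 2), 15)
})

test_that("fixture spec validation catches inconsistent tables", {
  expect_error(rc_fixture_spec(total_cells = 1000L), "sum to")
  jc <- c("+---" = 1024L, "++--" = 218L, "+-+-" = 32L, "+--+" = 36L,
          "++-+" = 15L, "-+--" = 4L, "---+" = 6L, "----" = 24L)
  expect_error(rc_fixture_spec(joint_counts = jc), "marginal violated for Apoe")
  expect_error(rc_fixture_spec(joint_counts = c("+-" = 1359L)), "sign strings")
})

test_that("generate_counts is bit-reproducible for a fixed seed", {
  mk <- list(planted_marker("mk", "A", 0.9, 8, 0.5))
  spec <- synthetic_spec(clusters = c(A = 50, B = 50), n_genes = 100,
                         planted_markers = mk, seed = 11)
  s1 <- generate_counts(spec)
  s2 <- generate_counts(spec)
  expect_identical(as.matrix(s1$matrix$counts), as.matrix(s2$matrix$counts))
  s3 <- generate_counts(synthetic_spec(clusters = c(A = 50, B = 50),
                                       n_genes = 100, planted_markers = mk,
                                       seed = 12))
  expect_false(identical(as.matrix(s1$matrix$counts), as.matrix(s3$matrix$counts)))
})

test_that("with no planted markers no gene passes the screen (null case)", {
  for (seed in 1:20) {
    spec <- synthetic_spec(clusters = c(A = 100, B = 100), n_genes = 200,
                           planted_markers = list(), seed = seed)
    sim <- generate_counts(spec)
    scr <- pan_marker_screen(sim$matrix, sim$labels, "A")
    expect_equal(sum(scr$passes), 0)
  }
})

test_that("a forced marker (positivity 1, background 0) separates clusters exactly", {
  spec <- synthetic_spec(
    clusters = c(A = 80, B = 80), n_genes = 50,
    planted_markers = list(planted_marker("forced", "A", 1.0, 16, 0)),
    seed = 3)
  sim <- generate_counts(spec)
  col <- as.numeric(sim$matrix$counts[, "forced"])
  in_a <- cell_ids(sim$matrix) %in% cluster_cells(sim$labels, "A")
  expect_true(all(col[in_a] > 0))
  expect_true(all(col[!in_a] == 0))
})

test_that("planted positivity is recovered within the binomial sampling bound", {
  devs <- vapply(1:20, function(seed) {
    spec <- synthetic_spec(
      clusters = c(A = 500, B = 100), n_genes = 20,
      planted_markers = list(planted_marker("mk", "A", 0.95, 16, 0.5)),
      seed = seed)
    sim <- generate_counts(spec)
    abs(pct_expressing(sim$matrix, sim$labels, "A")[["mk"]] - 0.95)
  }, numeric(1))
  expect_true(all(devs <= 0.03))
})

test_that("infeasible planted markers are rejected", {
  spec <- synthetic_spec(
    clusters = c(A = 10, B = 10), n_genes = 5,
    planted_markers = list(planted_marker("bad", "A", 0.99, 1, 0.1)),
    seed = 1)
  expect_error(generate_counts(spec), "infeasible")
  expect_error(synthetic_spec(
    clusters = c(A = 10, B = 10), n_genes = 5,
    planted_markers = list(planted_marker("mk", "Z", 0.5, 2, 1))),
    "unknown cluster")
})

test_that("flow-event generation respects fractions and rejects bad requests", {
  ev <- generate_flow_events(1000, c(SSC = 0.18), seed = 1)
  g <- evaluate_gates(ev$events, default_gating_tree(), "mCherry+")
  expect_lt(abs(g$pct[["SSC"]] - 18), 2.5)

  ev0 <- generate_flow_events(200, numeric(0), seed = 2)
  g0 <- evaluate_gates(ev0$events, default_gating_tree(), "mCherry+")
  expect_true(all(g0$assignment == "other"))

  expect_error(generate_flow_events(100, c(SSC = 0.6, BCSP = 0.6)),
               "sum to <= 1")
  expect_error(generate_flow_events(100, c(nope = 0.2)),
               "unknown population")
})
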