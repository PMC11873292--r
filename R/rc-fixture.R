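#' Joint positivity specification of the resting-chondrocyte fixture
#'
#' The published co-expression analysis of the 1 359-cell resting
#' chondrocyte (RC) cluster reports, for the four markers Apoe, Pthlh,
#' Axin2 and Foxa2, the per-marker positive-cell counts, the pairwise
#' overlaps with Apoe, the single-positive count among Apoe+ cells and the
#' absence of Pthlh+Axin2+Foxa2+ triples. Those published sums pin down
#' every reported quantity but not the full joint table: the split of the
#' 15 Apoe+ double-positive cells across marker pairs and the overlap
#' structure of the 10 Apoe- marker-positive cells are not published. The
#' default table places all 15 doubles in Pthlh&Foxa2 and keeps the Apoe-
#' positives disjoint; any consistent completion yields identical values
#' for every published quantity.
#'
#' Patterns are keyed by a +/- sign string over the markers in order, e.g.
#' `"+-+-"` = Apoe+ Pthlh- Axin2+ Foxa2-.
#'
#' @param total_cells total cells in the cluster.
#' @param joint_counts named integer vector, sign-pattern -> cell count.
#' @param markers marker names, in sign-string order.
#' @param expected_marginals optional named integer vector of single-marker
#'   positive totals to validate the joint table against.
#' @return an `rc_fixture_spec` list.
#' @export
rc_fixture_spec <- function(total_cells = 1359L,
                            joint_counts = c(
                              "+---" = 1023L,  # Apoe+ only
                              "++--" = 218L,   # Apoe+ Pthlh+
                              "+-+-" = 32L,    # Apoe+ Axin2+
                              "+--+" = 36L,    # Apoe+ Foxa2+
                              "++-+" = 15L,    # Apoe+ Pthlh+ Foxa2+
                              "-+--" = 4L,     # Apoe- Pthlh+
                              "---+" = 6L,     # Apoe- Foxa2+
                              "----" = 25L),   # all-negative
                            markers = c("Apoe", "Pthlh", "Axin2", "Foxa2"),
                            expected_marginals = c(Apoe = 1324L, Pthlh = 237L,
                                                   Axin2 = 32L, Foxa2 = 57L)) {
  pats <- names(joint_counts)
  if (is.null(pats) || any(nchar(pats) != length(markers)) ||
      any(!grepl("^[+-]+$", pats)))
    stop("joint_counts must be keyed by +/- sign strings over ",
         length(markers), " markers")
  if (anyDuplicated(pats)) stop("duplicate sign pattern")
  if (any(joint_counts < 0)) stop("negative pattern count")
  if (sum(joint_counts) != total_cells)
    stop(sprintf("joint counts sum to %d, not total_cells = %d",
                 sum(joint_counts), total_cells))
  if (!is.null(expected_marginals)) {
    for (mk in names(expected_marginals)) {
      j <- match(mk, markers)
      got <- sum(joint_counts[substr(pats, j, j) == "+"])
      if (got != expected_marginals[[mk]])
        stop(sprintf("marginal violated for %s: joint table implies %d, expected %d",
                     mk, got, expected_marginals[[mk]]))
    }
  }
  structure(list(total_cells = as.integer(total_cells),
                 joint_counts = joint_counts, markers = markers),
            class = "rc_fixture_spec")
}

#' Rebuild the resting-chondrocyte co-expression fixture
#'
#' Materializes the joint positivity table of [rc_fixture_spec()] as a
#' single-cluster count matrix over the four markers: positive entries get
#' count 1, negative entries 0 (positivity is defined as raw count > 0, so
#' magnitudes are irrelevant downstream).
#'
#' @param spec an [rc_fixture_spec()]; the default reproduces the published
#'   RC-cluster table.
#' @param cluster cluster name assigned to every cell.
#' @return list with `matrix` ([expr_matrix()]) and `labels`
#'   ([cluster_labeling()]).
#' @export
build_rc_fixture <- function(spec = rc_fixture_spec(), cluster = "RC") {
  stopifnot(inherits(spec, "rc_fixture_spec"))
  pats <- rep(names(spec$joint_counts), times = spec$joint_counts)
  flags <- do.call(rbind, lapply(strsplit(pats, ""),
                                 function(s) as.integer(s == "+")))
  cells <- sprintf("%s_%04d", cluster, seq_len(spec$total_cells))
  m <- expr_matrix(flags, gene_ids = spec$markers, cell_ids = cells)
  lab <- cluster_labeling(stats::setNames(rep(cluster, spec$total_cells), cells))
  list(matrix = m, labels = lab)
}
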