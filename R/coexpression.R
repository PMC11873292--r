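#' Raw-count positivity calling
#'
#' A cell is positive for a marker when its raw UMI count is greater than
#' 0 — no thresholds, no normalization.
#'
#' @param m an [expr_matrix()].
#' @param markers gene ids to call.
#' @return a `positivity_table`: logical `flags` matrix (cells x markers)
#'   plus ids.
#' @export
call_positivity <- function(m, markers) {
  validate_expr_matrix(m)
  missing <- setdiff(markers, gene_ids(m))
  if (length(missing))
    stop("unknown marker(s): ", paste(missing, collapse = ", "))
  flags <- as.matrix(m$counts[, markers, drop = FALSE] > 0)
  dimnames(flags) <- list(cell_ids(m), markers)
  structure(list(flags = flags, cell_ids = cell_ids(m), marker_ids = markers),
            class = "positivity_table")
}

pattern_key <- function(flags) {
  apply(flags, 1L, function(r) paste0(ifelse(r, "+", "-"), collapse = ""))
}

#' Marker set-overlap and conditional-positivity report
#'
#' Summarizes a positivity table the way the published co-expression
#' analysis summarizes the RC cluster: per-marker positive counts and
#' percentages (over all cells), the full joint sign-pattern table,
#' counts of cells positive for exactly k markers, and conditional
#' positivity percentages for every ordered marker pair (A | B = percent
#' of B-positive cells that are A-positive; undefined, reported `NA`, when
#' no cell is B-positive).
#'
#' When a `reference` marker is given (Apoe in the published analysis) the
#' k-positive counts and exclusivity summaries are restricted as in the
#' published analysis: `k_positive_counts` counts positives among the *other* markers
#' within reference-positive cells; `pct_ref_all_negative` is the percent
#' of reference-positive cells negative for all other markers; and
#' `pct_exactly_one_among_positive` is, among reference-positive cells
#' positive for at least one other marker, the percent positive for
#' exactly one.
#'
#' Percentages are emitted both raw and rounded to integer percent with
#' round-half-away-from-zero, the precision of the published figures.
#'
#' @param p a [call_positivity()] result.
#' @param reference optional marker name.
#' @return an `overlap_report` list; internal coherence (pattern sums,
#'   marginal consistency) is asserted on construction.
#' @export
overlap_analysis <- function(p, reference = NULL) {
  stopifnot(inherits(p, "positivity_table"))
  flags <- p$flags
  markers <- p$marker_ids
  if (length(markers) < 1L) stop("need >= 1 marker")
  if (!is.null(reference) && !reference %in% markers)
    stop("reference '", reference, "' is not a marker of the table")
  n <- nrow(flags)

  per_marker_count <- colSums(flags)
  per_marker_pct <- 100 * per_marker_count / n

  keys <- pattern_key(flags)
  pattern_counts <- table(keys)
  pattern_counts <- stats::setNames(as.integer(pattern_counts),
                                    names(pattern_counts))

  conditional_pct <- matrix(NA_real_, length(markers), length(markers),
                            dimnames = list(markers, markers))
  for (b in markers) {
    nb <- per_marker_count[[b]]
    if (nb > 0)
      conditional_pct[, b] <- 100 * colSums(flags[flags[, b], , drop = FALSE]) / nb
  }

  if (is.null(reference)) {
    k <- rowSums(flags)
    ref_count <- NA_integer_
    pct_ref_all_negative <- NA_real_
    pct_exactly_one_among_positive <- NA_real_
    k_range <- 0:length(markers)
  } else {
    others <- setdiff(markers, reference)
    refpos <- flags[, reference]
    ref_count <- sum(refpos)
    k <- rowSums(flags[refpos, others, drop = FALSE])
    k_range <- 0:length(others)
    pct_ref_all_negative <-
      if (ref_count > 0) 100 * sum(k == 0) / ref_count else NA_real_
    n_any <- sum(k >= 1)
    pct_exactly_one_among_positive <-
      if (n_any > 0) 100 * sum(k == 1) / n_any else NA_real_
  }
  k_positive_counts <- stats::setNames(
    vapply(k_range, function(i) sum(k == i), integer(1)),
    as.character(k_range))

  rep <- structure(list(
    n_cells = n,
    markers = markers,
    reference = reference,
    ref_count = ref_count,
    per_marker_count = stats::setNames(as.integer(per_marker_count), markers),
    per_marker_pct = per_marker_pct,
    per_marker_pct_rounded = round_half_away(per_marker_pct),
    pattern_counts = pattern_counts,
    k_positive_counts = k_positive_counts,
    conditional_pct = conditional_pct,
    conditional_pct_rounded = round_half_away(conditional_pct),
    pct_ref_all_negative = pct_ref_all_negative,
    pct_exactly_one_among_positive = pct_exactly_one_among_positive
  ), class = "overlap_report")
  validate_overlap_report(rep)
  rep
}

#' Round half away from zero
#'
#' Published percentages are integers rounded half-away-from-zero; base R's
#' `round()` rounds half to even, so 2.5 would go to 2 instead of 3.
#'
#' @param x numeric.
#' @param digits decimal digits.
#' @return rounded numeric, same shape.
#' @export
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> %d cells, markers: %s\n", x$n_cells,
              paste(x$markers, collapse = ", ")))
  cat("per-marker %:",
      paste(sprintf("%s %g%%", x$markers, x$per_marker_pct_rounded),
            collapse = ", "), "\n")
  if (!is.null(x$reference))
    cat(sprintf("reference %s: %d positive; %g%% negative for all others\n",
                x$reference, x$ref_count,
                round_half_away(x$pct_ref_all_negative)))
  invisible(x)
}

# Internal coherence: pattern counts sum to n; per-marker counts equal the
# pattern-table marginals; sum_k k * count(k-positive) equals the sum of
# per-marker counts (inclusion-exclusion bookkeeping) in the no-reference
# case.
validate_overlap_report <- function(x) {
  stopifnot(sum(x$pattern_counts) == x$n_cells)
  pats <- names(x$pattern_counts)
  for (j in seq_along(x$markers)) {
    marg <- sum(x$pattern_counts[substr(pats, j, j) == "+"])
    if (marg != x$per_marker_count[[x$markers[j]]])
      stop("pattern-table marginal mismatch for marker ", x$markers[j])
  }
  if (is.null(x$reference)) {
    lhs <- sum(as.integer(names(x$k_positive_counts)) * x$k_positive_counts)
    if (lhs != sum(x$per_marker_count))
      stop("k-positive counts inconsistent with per-marker counts")
    if (sum(x$k_positive_counts) != x$n_cells)
      stop("k-positive counts do not cover all cells")
  } else {
    if (sum(x$k_positive_counts) != x$ref_count)
      stop("k-positive counts do not cover reference-positive cells")
  }
  invisible(x)
}
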