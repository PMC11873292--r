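#' Growth-plate zone extents from per-cell axial positions
#'
#' Cells along the growth-plate axis carry a zone label (RZ resting, PZ
#' proliferative, HZ hypertrophic, e.g. from marker staining). Two zone
#' boundaries are fitted by exhaustive scan over candidate positions — the
#' midpoints between adjacent distinct sorted cell positions — minimizing
#' the number of label misclassifications under the rule
#' `position < b1 -> RZ, position < b2 -> PZ, else HZ`. Ties are resolved
#' toward the smaller RZ (smallest `b1`, then smallest `b2`). Each zone's
#' extent is reported as percent of the span between the first and last
#' cell; the three percentages sum to 100.
#'
#' @param positions numeric axial positions (micrometres or normalized).
#' @param zones character zone labels, same length.
#' @param zone_order the three zone labels in axial order.
#' @return list: `pct` (named, sums to 100), `boundaries` (b1, b2),
#'   `misclassified` (count at the optimum).
#' @export
zone_proportions <- function(positions, zones,
                             zone_order = c("RZ", "PZ", "HZ")) {
  stopifnot(length(positions) == length(zones), length(zone_order) == 3L)
  if (any(!is.finite(positions))) stop("non-finite position(s)")
  zones <- as.character(zones)
  bad <- setdiff(unique(zones), zone_order)
  if (length(bad)) stop("unknown zone label(s): ", paste(bad, collapse = ", "))
  for (z in zone_order)
    if (!any(zones == z)) stop("zone with 0 cells: ", z)

  u <- sort(unique(positions))
  if (length(u) < 3L)
    stop("need >= 3 distinct positions to place two boundaries")
  cand <- (u[-1] + u[-length(u)]) / 2

  best <- list(mis = Inf, b1 = NA_real_, b2 = NA_real_)
  for (b1 in cand) {
    for (b2 in cand[cand > b1]) {
      pred <- ifelse(positions < b1, zone_order[1],
                     ifelse(positions < b2, zone_order[2], zone_order[3]))
      mis <- sum(pred != zones)
      if (mis < best$mis) best <- list(mis = mis, b1 = b1, b2 = b2)
    }
  }
  span <- max(positions) - min(positions)
  pct <- 100 * c(best$b1 - min(positions),
                 best$b2 - best$b1,
                 max(positions) - best$b2) / span
  names(pct) <- zone_order
  list(pct = pct, boundaries = c(b1 = best$b1, b2 = best$b2),
       misclassified = best$mis)
}
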