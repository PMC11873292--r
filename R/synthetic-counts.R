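#' Planted marker description for the count simulator
#'
#' A planted marker is a gene whose in-cluster positivity (fraction of
#' target-cluster cells with raw count > 0) and fold change of the
#' target-cluster mean over every other cluster's mean are both controlled.
#' Pan-markers are planted with high positivity and large fold change;
#' subset markers with low positivity.
#'
#' @param gene_id gene identifier.
#' @param target_cluster cluster in which the marker is expressed.
#' @param in_cluster_positivity target fraction in \[0, 1\] of
#'   target-cluster cells with count > 0.
#' @param fold_change ratio >= 1 of the target-cluster mean count to every
#'   other cluster's mean count.
#' @param background_mean mean count (>= 0) of the marker in the other
#'   clusters.
#' @return a `planted_marker` list.
#' @export
planted_marker <- function(gene_id, target_cluster, in_cluster_positivity,
                           fold_change, background_mean) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            in_cluster_positivity >= 0, in_cluster_positivity <= 1,
            is.finite(fold_change), fold_change >= 1,
            is.finite(background_mean), background_mean >= 0)
  structure(list(gene_id = gene_id, target_cluster = target_cluster,
                 in_cluster_positivity = in_cluster_positivity,
                 fold_change = fold_change,
                 background_mean = background_mean),
            class = "planted_marker")
}

#' Simulation design for clustered negative-binomial counts
#'
#' Describes a clustered count matrix: background genes share one NB(mean,
#' size) law in every cluster (so no background gene is differentially
#' expressed); planted markers override that law in their target cluster.
#' The default design emulates the five growth-plate chondrocyte clusters
#' (resting, proliferative, prehypertrophic, hypertrophic,
#' mitochondrial-rich) with one planted pan-marker of the resting cluster
#' (positivity 0.95, fold change 16) and three planted subset markers at
#' positivity 0.17 / 0.02 / 0.04 — the positivity levels of the known
#' resting-zone stem-cell markers.
#'
#' @param clusters named integer vector: cells per cluster.
#' @param n_genes total genes including planted markers.
#' @param baseline_mean NB mean of background genes.
#' @param dispersion NB size parameter (larger = less overdispersed).
#' @param planted_markers list of [planted_marker()].
#' @param seed integer seed; the draw is fully determined by it.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(clusters = c(RC = 300, PC = 300, PHC = 300,
                                        HC = 300, MitoC = 300),
                           n_genes = 2000,
                           baseline_mean = 0.5,
                           dispersion = 2,
                           planted_markers = default_planted_markers(),
                           seed = 0L) {
  stopifnot(length(clusters) >= 1L, all(clusters >= 1L),
            !is.null(names(clusters)), !anyDuplicated(names(clusters)),
            n_genes >= length(planted_markers),
            is.finite(baseline_mean), baseline_mean > 0,
            is.finite(dispersion), dispersion > 0)
  for (pm in planted_markers) {
    stopifnot(inherits(pm, "planted_marker"))
    if (!pm$target_cluster %in% names(clusters))
      stop("planted marker '", pm$gene_id, "' targets unknown cluster '",
           pm$target_cluster, "'")
  }
  ids <- vapply(planted_markers, `[[`, character(1), "gene_id")
  if (anyDuplicated(ids)) stop("duplicate planted marker gene ids")
  structure(list(clusters = clusters, n_genes = n_genes,
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 planted_markers = planted_markers, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
default_planted_markers <- function() {
  list(planted_marker("panMarker", "RC", 0.95, 16, 0.5),
       planted_marker("subsetA",  "RC", 0.17, 16, 0.05),
       planted_marker("subsetB",  "RC", 0.02, 16, 0.05),
       planted_marker("subsetC",  "RC", 0.04, 16, 0.05))
}

# Mean of a zero-truncated NB with untruncated mean mu and given size.
ztnb_mean <- function(mu, size) mu / (1 - stats::dnbinom(0, mu = mu, size = size))

# Solve for the untruncated NB mean whose zero-truncated mean is m_pos.
# The zero-truncated mean is increasing in mu with infimum 1 as mu -> 0.
solve_ztnb_mu <- function(m_pos, size) {
  if (m_pos <= 1)
    stop("infeasible marker: required mean among positive cells ", signif(m_pos, 4),
         " <= 1 (fold_change x background_mean too small for the requested positivity)")
  stats::uniroot(function(mu) ztnb_mean(mu, size) - m_pos,
                 lower = 1e-9, upper = max(10 * m_pos, 10), tol = 1e-10)$root
}

# Draw n zero-truncated NB(mu, size) variates via inverse-CDF restricted
# to the positive part.
rztnb <- function(n, mu, size) {
  p0 <- stats::dnbinom(0, mu = mu, size = size)
  u <- stats::runif(n, min = p0, max = 1)
  stats::qnbinom(u, mu = mu, size = size)
}

#' Simulate a clustered count matrix with planted markers
#'
#' Background genes are drawn NB(baseline_mean, dispersion) identically in
#' every cluster. A planted marker is drawn NB(background_mean, dispersion)
#' in the non-target clusters; in the target cluster each cell is positive
#' with probability `in_cluster_positivity` and positive cells draw a
#' zero-truncated NB whose mean is set so that the realized target-cluster
#' mean equals `fold_change x background_mean` in expectation. The draw is
#' bit-reproducible given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `matrix` ([expr_matrix()]) and `labels`
#'   ([cluster_labeling()]).
#' @export
generate_counts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, generate_counts_impl(spec))
}

generate_counts_impl <- function(spec) {
  n_cells <- sum(spec$clusters)
  marker_ids <- vapply(spec$planted_markers, `[[`, character(1), "gene_id")
  n_bg <- spec$n_genes - length(marker_ids)
  genes <- c(marker_ids,
             if (n_bg > 0) sprintf("gene%04d", seq_len(n_bg)))
  cells <- sprintf("cell%05d", seq_len(n_cells))
  labels <- rep(names(spec$clusters), times = spec$clusters)

  counts <- matrix(stats::rnbinom(n_cells * spec$n_genes,
                                  mu = spec$baseline_mean,
                                  size = spec$dispersion),
                   nrow = n_cells, ncol = spec$n_genes)

  for (k in seq_along(spec$planted_markers)) {
    pm <- spec$planted_markers[[k]]
    in_target <- labels == pm$target_cluster
    n_t <- sum(in_target); n_o <- n_cells - n_t
    counts[!in_target, k] <-
      if (pm$background_mean > 0)
        stats::rnbinom(n_o, mu = pm$background_mean, size = spec$dispersion)
      else rep(0L, n_o)
    col <- integer(n_t)
    if (pm$in_cluster_positivity > 0) {
      pos <- stats::runif(n_t) < pm$in_cluster_positivity
      if (any(pos)) {
        # mean among positive cells; with no background the magnitude scale
        # is arbitrary and fold_change is used directly
        m_pos <- if (pm$background_mean > 0)
          pm$fold_change * pm$background_mean / pm$in_cluster_positivity
        else max(pm$fold_change, 2)
        mu <- solve_ztnb_mu(m_pos, spec$dispersion)
        col[pos] <- rztnb(sum(pos), mu, spec$dispersion)
      }
    }
    counts[in_target, k] <- col
  }

  m <- expr_matrix(counts, gene_ids = genes, cell_ids = cells)
  lab <- cluster_labeling(stats::setNames(labels, cells),
                          clusters = names(spec$clusters))
  list(matrix = m, labels = lab)
}
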