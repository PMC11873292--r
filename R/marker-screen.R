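#' Depth-normalized log expression
#'
#' Standard counts-per-scale_total log transform: each cell's counts are
#' scaled to a common total depth and log(1 + x) transformed,
#' `value[c, g] = log(1 + count[c, g] * scale_total / depth[c])` in the
#' given base. Used only to form cluster means for the fold-change
#' statistic; positivity is always computed on raw counts.
#'
#' @param m an [expr_matrix()].
#' @param scale_total target depth per cell (default 10 000, i.e. CP10K).
#' @param log_base logarithm base (default natural log).
#' @return a `norm_matrix`: sparse `values` (cells x genes) plus the
#'   transform parameters.
#' @export
normalize_counts <- function(m, scale_total = 1e4, log_base = exp(1)) {
  validate_expr_matrix(m)
  depth <- Matrix::rowSums(m$counts)
  if (any(depth == 0))
    stop("zero-depth cell(s): ",
         paste(utils::head(cell_ids(m)[depth == 0], 5), collapse = ", "))
  v <- Matrix::Diagonal(x = scale_total / depth) %*% m$counts
  v <- methods::as(v, "CsparseMatrix")
  v@x <- log1p(v@x) / log(log_base)
  dimnames(v) <- dimnames(m$counts)
  structure(list(values = v, scale_total = scale_total, log_base = log_base),
            class = "norm_matrix")
}

#' Fraction of expressing cells per gene within one cluster
#'
#' A cell expresses a gene when its raw count is greater than 0. This is
#' the ubiquity half of the pan-marker screen (threshold "> 90%" by
#' default downstream).
#'
#' @param m an [expr_matrix()].
#' @param labels a [cluster_labeling()] covering `m`.
#' @param cluster cluster name.
#' @return named numeric vector, gene -> fraction in \[0, 1\].
#' @export
pct_expressing <- function(m, labels, cluster) {
  validate_labeling(m, labels)
  cells <- cluster_cells(labels, cluster)
  sub <- m$counts[cells, , drop = FALSE]
  Matrix::colSums(sub > 0) / length(cells)
}

# Per-gene mean of de-logged normalized expression over a set of cells.
delog_cluster_mean <- function(nm, cells) {
  v <- nm$values[cells, , drop = FALSE]
  v@x <- expm1(v@x * log(nm$log_base))
  Matrix::colSums(v) / length(cells)
}

#' Pairwise log2 fold-change between two clusters
#'
#' Per gene, `log2((mean_target + pseudocount) / (mean_other +
#' pseudocount))`, where each mean is taken over the cluster's cells on
#' de-logged normalized expression (`base^value - 1`, i.e. depth-scaled
#' counts). This is the dominant single-cell convention for cluster
#' fold-changes; the specificity half of the screen thresholds the minimum
#' of this statistic over all other clusters.
#'
#' @param nm a [normalize_counts()] result.
#' @param labels a [cluster_labeling()].
#' @param target,other distinct cluster names.
#' @param pseudocount added to both means before the ratio.
#' @return named numeric vector, gene -> log2 fold-change.
#' @export
pairwise_logfc <- function(nm, labels, target, other, pseudocount = 1) {
  stopifnot(inherits(nm, "norm_matrix"))
  if (identical(target, other)) stop("target and other clusters must differ")
  mt <- delog_cluster_mean(nm, cluster_cells(labels, target))
  mo <- delog_cluster_mean(nm, cluster_cells(labels, other))
  log2((mt + pseudocount) / (mo + pseudocount))
}

#' Pan-marker screen: ubiquity and specificity per gene
#'
#' For every gene, computes the in-cluster positivity fraction (`pct_in`,
#' raw count > 0) and the pairwise log2 fold-change of the target cluster
#' against each other cluster; a gene passes when `pct_in >
#' min_pct` and the minimum pairwise fold-change exceeds `min_logfc`
#' (both strict, matching the published "> 90%" / "logFC > 1" criteria).
#' Passing genes are ranked by minimum fold-change descending, ties broken
#' by `pct_in` descending then gene id ascending.
#'
#' @param m an [expr_matrix()].
#' @param labels a [cluster_labeling()] with at least two clusters.
#' @param target cluster screened for markers.
#' @param min_pct positivity threshold (strict), default 0.90.
#' @param min_logfc minimum pairwise log2 fold-change threshold (strict),
#'   default 1.0.
#' @param scale_total,log_base,pseudocount normalization / fold-change
#'   parameters, see [normalize_counts()] and [pairwise_logfc()].
#' @return data.frame with one row per gene, sorted passing-first by the
#'   ranking key: `gene_id`, `pct_in`, one `logfc_<cluster>` column per
#'   other cluster, `min_logfc`, `passes`, `rank` (NA for non-passing).
#' @export
pan_marker_screen <- function(m, labels, target, min_pct = 0.90,
                              min_logfc = 1.0, scale_total = 1e4,
                              log_base = exp(1), pseudocount = 1) {
  validate_labeling(m, labels)
  others <- setdiff(labels$clusters, target)
  if (!target %in% labels$clusters) stop("unknown cluster: ", target)
  if (length(others) == 0L)
    stop("screen needs >= 2 clusters; labeling has only '", target, "'")
  pct <- pct_expressing(m, labels, target)
  nm <- normalize_counts(m, scale_total = scale_total, log_base = log_base)
  lfc <- vapply(others,
                function(o) pairwise_logfc(nm, labels, target, o, pseudocount),
                numeric(ncol(m$counts)))
  lfc <- matrix(lfc, ncol = length(others),
                dimnames = list(gene_ids(m), others))
  minl <- apply(lfc, 1L, min)
  passes <- pct > min_pct & minl > min_logfc
  res <- data.frame(gene_id = gene_ids(m), pct_in = unname(pct),
                    stringsAsFactors = FALSE)
  for (o in others) res[[paste0("logfc_", o)]] <- unname(lfc[, o])
  res$min_logfc <- unname(minl)
  res$passes <- unname(passes)
  ord <- order(!res$passes, -res$min_logfc, -res$pct_in, res$gene_id)
  res <- res[ord, , drop = FALSE]
  res$rank <- NA_integer_
  res$rank[res$passes] <- seq_len(sum(res$passes))
  rownames(res) <- NULL
  res
}
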