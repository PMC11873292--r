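# Independent brute-force oracles: deliberately naive loop implementations
# used to cross-check the vectorized package code on small random instances.

oracle_normalize <- function(counts, scale_total = 1e4, log_base = exp(1)) {
  out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (c in seq_len(nrow(counts))) {
    depth <- sum(counts[c, ])
    for (g in seq_len(ncol(counts)))
      out[c, g] <- log(1 + counts[c, g] * scale_total / depth, base = log_base)
  }
  out
}

oracle_pct_expressing <- function(counts, labels, cluster) {
  cells <- names(labels)[labels == cluster]
  out <- numeric(ncol(counts))
  names(out) <- colnames(counts)
  for (g in colnames(counts)) {
    npos <- 0
    for (c in cells) if (counts[c, g] > 0) npos <- npos + 1
    out[g] <- npos / length(cells)
  }
  out
}

oracle_pairwise_logfc <- function(counts, labels, target, other,
                                  scale_total = 1e4, pseudocount = 1) {
  norm <- oracle_normalize(counts, scale_total)
  delog <- exp(norm) - 1
  ct <- names(labels)[labels == target]
  co <- names(labels)[labels == other]
  out <- numeric(ncol(counts)); names(out) <- colnames(counts)
  for (g in colnames(counts)) {
    mt <- mean(delog[ct, g]); mo <- mean(delog[co, g])
    out[g] <- log2((mt + pseudocount) / (mo + pseudocount))
  }
  out
}

oracle_screen <- function(counts, labels, target, min_pct = 0.9,
                          min_logfc = 1.0) {
  pct <- oracle_pct_expressing(counts, labels, target)
  others <- setdiff(unique(unname(labels)), target)
  minl <- rep(Inf, ncol(counts)); names(minl) <- colnames(counts)
  for (o in others)
    minl <- pmin(minl, oracle_pairwise_logfc(counts, labels, target, o))
  passes <- pct > min_pct & minl > min_logfc
  df <- data.frame(gene_id = colnames(counts), pct_in = unname(pct),
                   min_logfc = unname(minl), passes = unname(passes),
                   stringsAsFactors = FALSE)
  df[order(!df$passes, -df$min_logfc, -df$pct_in, df$gene_id), ]
}

oracle_positivity <- function(counts, markers) {
  out <- matrix(FALSE, nrow(counts), length(markers),
                dimnames = list(rownames(counts), markers))
  for (c in rownames(counts))
    for (m in markers)
      out[c, m] <- counts[c, m] > 0
  out
}

oracle_overlap <- function(flags, reference = NULL) {
  n <- nrow(flags); markers <- colnames(flags)
  per_marker <- sapply(markers, function(m) sum(flags[, m]))
  keys <- character(n)
  for (i in seq_len(n))
    keys[i] <- paste0(ifelse(flags[i, ], "+", "-"), collapse = "")
  cond <- matrix(NA_real_, length(markers), length(markers),
                 dimnames = list(markers, markers))
  for (a in markers) for (b in markers)
    if (per_marker[b] > 0)
      cond[a, b] <- 100 * sum(flags[, a] & flags[, b]) / per_marker[b]
  if (!is.null(reference)) {
    others <- setdiff(markers, reference)
    k <- rowSums(flags[flags[, reference], others, drop = FALSE])
  } else k <- rowSums(flags)
  list(per_marker_count = per_marker,
       pattern_counts = table(keys),
       conditional_pct = cond,
       k = k)
}

oracle_zone <- function(positions, zones, zone_order = c("RZ", "PZ", "HZ")) {
  u <- sort(unique(positions))
  cand <- (u[-1] + u[-length(u)]) / 2
  best_mis <- Inf; best <- NULL
  for (i in seq_along(cand)) for (j in seq_along(cand)) {
    if (cand[j] <= cand[i]) next
    mis <- 0
    for (p in seq_along(positions)) {
      z <- if (positions[p] < cand[i]) zone_order[1]
      else if (positions[p] < cand[j]) zone_order[2]
      else zone_order[3]
      if (z != zones[p]) mis <- mis + 1
    }
    if (mis < best_mis) { best_mis <- mis; best <- c(cand[i], cand[j]) }
  }
  list(mis = best_mis, boundaries = best)
}

# Closed-form EdU flag for deterministic synchronized cycles: cycle length
# L, S phase the middle s-fraction of each cycle, pulse [0, 24*pulse_days),
# sampled at 24*(pulse_days + day). Mirrors the labeling and counting
# rules with explicit arithmetic instead of the renewal simulation.
oracle_edu_sync <- function(L, s, pulse_days, day, k) {
  pulse_end <- 24 * pulse_days
  t <- pulse_end + 24 * day
  n_cycles <- ceiling((t + L) / L) + 1
  entries <- ((seq_len(n_cycles) - 1) + (1 - s) / 2) * L
  divs <- seq_len(n_cycles) * L
  labeled <- which(entries >= 0 & entries < pulse_end)
  if (!length(labeled)) return(FALSE)
  jstar <- max(labeled)
  sum(divs > divs[jstar] & divs <= t) <= k
}

rand_counts <- function(n_cells, n_genes, max_count = 4, p_zero = 0.5) {
  cnt <- matrix(ifelse(runif(n_cells * n_genes) < p_zero, 0,
                       sample.int(max_count, n_cells * n_genes, replace = TRUE)),
                n_cells, n_genes)
  dimnames(cnt) <- list(sprintf("c%02d", seq_len(n_cells)),
                        sprintf("g%02d", seq_len(n_genes)))
  # avoid zero-depth cells (normalization precondition)
  zero <- rowSums(cnt) == 0
  cnt[zero, 1] <- 1
  cnt
}

rand_labels <- function(cell_names, n_clusters = 2) {
  repeat {
    lab <- sample(paste0("cl", seq_len(n_clusters)), length(cell_names),
                  replace = TRUE)
    if (length(unique(lab)) == n_clusters) break
  }
  stats::setNames(lab, cell_names)
}
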