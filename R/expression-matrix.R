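#' Cell-by-gene UMI count matrix
#'
#' Light container for raw unique-molecular-identifier (UMI) counts. The
#' in-memory convention is cells in rows and genes in columns; counts are
#' stored as a sparse [Matrix::dgCMatrix-class] with cell and gene
#' identifiers as dimnames. All entries must be non-negative integers —
#' positivity calling and the marker screen are defined on raw counts.
#'
#' @param counts numeric matrix or Matrix, cells x genes, non-negative
#'   integers.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   `colnames(counts)`).
#' @param cell_ids character vector of unique cell identifiers (defaults to
#'   `rownames(counts)`).
#' @return An object of class `expr_matrix` with element `counts`
#'   (sparse, cells x genes, dimnames set).
#' @export
expr_matrix <- function(counts, gene_ids = colnames(counts),
                        cell_ids = rownames(counts)) {
  if (is.null(gene_ids)) {
    if (ncol(counts) > 0) stop("gene_ids are required (none found on counts)")
    gene_ids <- character(0)
  }
  if (is.null(cell_ids)) {
    if (nrow(counts) > 0) stop("cell_ids are required (none found on counts)")
    cell_ids <- character(0)
  }
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  dimnames(m) <- list(trimws(as.character(cell_ids)),
                      trimws(as.character(gene_ids)))
  out <- structure(list(counts = m), class = "expr_matrix")
  validate_expr_matrix(out)
  out
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d cells x %d genes, %d non-zero counts\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$counts)

#' @rdname expr_matrix
#' @param m an `expr_matrix`.
#' @export
gene_ids <- function(m) {
  ids <- colnames(m$counts)
  if (is.null(ids)) character(0) else ids
}

#' @rdname expr_matrix
#' @export
cell_ids <- function(m) {
  ids <- rownames(m$counts)
  if (is.null(ids)) character(0) else ids
}

#' Validate an expression matrix
#'
#' Checks the container invariants: integer non-negative entries, identifier
#' uniqueness, identifier/shape consistency. Errors name the offending
#' entries by (cell, gene) coordinate.
#'
#' @param m object to validate.
#' @return `m`, invisibly, if valid.
#' @export
validate_expr_matrix <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  cnt <- m$counts
  cells <- rownames(cnt); genes <- colnames(cnt)
  if (anyDuplicated(genes))
    stop("duplicate gene ids: ", paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(cells))
    stop("duplicate cell ids: ", paste(unique(cells[duplicated(cells)]), collapse = ", "))
  bad <- which(cnt@x < 0 | cnt@x != round(cnt@x))
  if (length(bad)) {
    # locate the first offender in the column-compressed layout
    i <- cnt@i[bad[1]] + 1L
    j <- findInterval(bad[1] - 1L, cnt@p, left.open = FALSE)
    stop(sprintf(
      "counts must be non-negative integers; offending entry at (cell '%s', gene '%s') = %g (%d offending total)",
      cells[i], genes[j], cnt@x[bad[1]], length(bad)))
  }
  invisible(m)
}

#' Per-cell cluster assignment
#'
#' @param labels named character vector mapping cell_id -> cluster name.
#' @param clusters cluster names in canonical order; defaults to order of
#'   first appearance in `labels`.
#' @return object of class `cluster_labeling` with elements `labels` and
#'   `clusters`.
#' @export
cluster_labeling <- function(labels, clusters = unique(unname(labels))) {
  if (length(labels) == 0L) stop("labeling is empty")
  if (is.null(names(labels))) stop("labels must be named by cell_id")
  if (anyDuplicated(names(labels)))
    stop("cell labeled twice: ",
         paste(unique(names(labels)[duplicated(names(labels))]), collapse = ", "))
  labels <- stats::setNames(trimws(as.character(labels)), trimws(names(labels)))
  clusters <- as.character(clusters)
  if (anyDuplicated(clusters)) stop("duplicate cluster names")
  if (!setequal(clusters, unique(unname(labels))))
    stop("clusters must name exactly the clusters present in labels (every cluster needs >= 1 cell)")
  structure(list(labels = labels, clusters = clusters),
            class = "cluster_labeling")
}

#' @export
print.cluster_labeling <- function(x, ...) {
  tab <- table(factor(x$labels, levels = x$clusters))
  cat(sprintf("<cluster_labeling> %d cells in %d clusters\n",
              length(x$labels), length(x$clusters)))
  print(tab)
  invisible(x)
}

#' Cells belonging to one cluster
#' @param labeling a `cluster_labeling`.
#' @param cluster cluster name.
#' @return character vector of cell ids.
#' @export
cluster_cells <- function(labeling, cluster) {
  if (!cluster %in% labeling$clusters)
    stop("unknown cluster: ", cluster)
  names(labeling$labels)[labeling$labels == cluster]
}

#' Check that a labeling covers a matrix exactly
#'
#' Every cell of `m` must carry exactly one label and the labeling must not
#' name cells absent from `m`.
#'
#' @param m an `expr_matrix`.
#' @param labeling a `cluster_labeling`.
#' @return `TRUE` invisibly, or an error naming the mismatch.
#' @export
validate_labeling <- function(m, labeling) {
  cells <- cell_ids(m)
  missing <- setdiff(cells, names(labeling$labels))
  extra <- setdiff(names(labeling$labels), cells)
  if (length(missing))
    stop("cells without label: ", paste(utils::head(missing, 5), collapse = ", "))
  if (length(extra))
    stop("labels for cells not in matrix: ", paste(utils::head(extra, 5), collapse = ", "))
  invisible(TRUE)
}

# ---- I/O ------------------------------------------------------------------

read_tsv_column <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(character(0))
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Read a count matrix
#'
#' Two on-disk layouts are supported: the 10x-style MatrixMarket directory
#' (`matrix.mtx` in genes x cells orientation plus `genes.tsv` and
#' `barcodes.tsv`, transposed on read to the in-memory cells x genes
#' convention) and a dense TSV with gene ids as the header row and cell ids
#' in the first column.
#'
#' @param path directory (for `mtx-dir`) or file (for `dense-tsv`).
#' @param format `"mtx-dir"` or `"dense-tsv"`.
#' @return an [expr_matrix()].
#' @export
read_counts <- function(path, format = c("mtx-dir", "dense-tsv")) {
  format <- match.arg(format)
  if (format == "mtx-dir") {
    files <- file.path(path, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
    absent <- files[!file.exists(files)]
    if (length(absent))
      stop("missing file(s): ", paste(absent, collapse = ", "))
    mm <- Matrix::readMM(files[1])          # genes x cells on disk
    genes <- read_tsv_column(files[2])
    cells <- read_tsv_column(files[3])
    if (nrow(mm) != length(genes))
      stop(sprintf("genes.tsv has %d ids but matrix.mtx has %d rows",
                   length(genes), nrow(mm)))
    if (ncol(mm) != length(cells))
      stop(sprintf("barcodes.tsv has %d ids but matrix.mtx has %d columns",
                   length(cells), ncol(mm)))
    expr_matrix(Matrix::t(mm), gene_ids = genes, cell_ids = cells)
  } else {
    if (!file.exists(path)) stop("missing file: ", path)
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("dense TSV needs a cell-id column and >= 1 gene column")
    cells <- as.character(df[[1]])
    mat <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(mat) <- "double"
    expr_matrix(mat, gene_ids = colnames(df)[-1], cell_ids = cells)
  }
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]: `read_counts(write_counts(m))` reproduces `m`
#' exactly (ids, values and their order). The MatrixMarket file is written
#' in the 1-based `coordinate integer general` dialect, genes x cells.
#'
#' @param m an `expr_matrix`.
#' @param path output directory (`mtx-dir`) or file (`dense-tsv`).
#' @param format `"mtx-dir"` or `"dense-tsv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path, format = c("mtx-dir", "dense-tsv")) {
  format <- match.arg(format)
  validate_expr_matrix(m)
  if (format == "mtx-dir") {
    if (!dir.exists(path) && !dir.create(path, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create directory: ", path)
    gm <- methods::as(Matrix::t(m$counts), "CsparseMatrix")  # genes x cells
    ti <- gm@i + 1L
    tj <- rep.int(seq_len(ncol(gm)), diff(gm@p))
    writeLines(c("%%MatrixMarket matrix coordinate integer general",
                 sprintf("%d %d %d", nrow(gm), ncol(gm), length(ti)),
                 sprintf("%d %d %d", ti, tj, as.integer(gm@x))),
               file.path(path, "matrix.mtx"))
    writeLines(gene_ids(m), file.path(path, "genes.tsv"))
    writeLines(cell_ids(m), file.path(path, "barcodes.tsv"))
  } else {
    dense <- as.matrix(m$counts)
    df <- data.frame(cell_id = cell_ids(m), dense, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("cell_id", gene_ids(m))
    ok <- tryCatch({
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("cannot write file: ", path)
  }
  invisible(path)
}

#' Read per-cell cluster labels from a 2-column TSV
#'
#' @param path TSV with columns cell_id, cluster.
#' @param header whether the file carries a header row.
#' @return a [cluster_labeling()] with clusters ordered by first appearance.
#' @export
read_labels <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("missing file: ", path)
  info <- file.info(path)
  if (is.na(info$size) || info$size == 0) stop("empty labels file: ", path)
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) stop("empty labels file: ", path)
  if (ncol(df) != 2L) stop("labels TSV must have exactly 2 columns (cell_id, cluster)")
  cluster_labeling(stats::setNames(df[[2]], df[[1]]))
}

#' Write per-cell cluster labels
#' @param labeling a `cluster_labeling`.
#' @param path output TSV path.
#' @param header write a header row.
#' @export
write_labels <- function(labeling, path, header = FALSE) {
  df <- data.frame(cell_id = names(labeling$labels),
                   cluster = unname(labeling$labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}
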