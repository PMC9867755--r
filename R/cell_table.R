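#' Construct a cell table
#'
#' The pipeline's central object: an integer UMI count matrix (cells x genes)
#' with per-cell metadata (condition, developmental stage, cluster id,
#' optional cell type) and an optional 2D embedding.
#'
#' @param counts integer matrix or dgCMatrix, cells in rows, genes in columns.
#' @param gene_ids character vector of unique gene symbols, one per column.
#' @param cell_ids character vector of unique barcodes, one per row.
#' @param condition per-cell label, `"native"` or `"organoid"`.
#' @param stage per-cell developmental stage, one of `"I"`..`"IV"`.
#' @param cluster per-cell integer cluster id.
#' @param cell_type optional per-cell label among the 13 canonical types or
#'   `"NI"`; `NA` allowed when annotation has not run yet.
#' @param embedding optional numeric matrix (cells x 2) of finite 2D
#'   coordinates.
#'
#' @return An object of class `cell_table` with fields as above plus
#'   `n_cells` and `n_genes`.
#' @export
cell_table <- function(counts, gene_ids, cell_ids, condition, stage, cluster,
                       cell_type = NULL, embedding = NULL) {
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  n_cells <- nrow(counts)
  n_genes <- ncol(counts)
  if (length(gene_ids) != n_genes) {
    abort_validation("gene_ids length (", length(gene_ids),
                     ") != number of genes (", n_genes, ")")
  }
  if (anyDuplicated(gene_ids)) {
    abort_validation("gene symbols must be unique; duplicated: ",
                     paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (length(cell_ids) != n_cells) {
    abort_validation("cell_ids length (", length(cell_ids),
                     ") != number of cells (", n_cells, ")")
  }
  if (anyDuplicated(cell_ids)) abort_validation("cell barcodes must be unique")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != floor(x)))) {
    abort_validation("counts must be non-negative integers")
  }
  check_meta <- function(v, name, levels = NULL) {
    if (length(v) == 1L && n_cells > 1L) v <- rep(v, n_cells)
    if (length(v) != n_cells) {
      abort_validation(name, " length (", length(v), ") != number of cells (",
                       n_cells, ")")
    }
    v <- as.character(v)
    if (!is.null(levels)) {
      bad <- setdiff(unique(v[!is.na(v)]), levels)
      if (length(bad)) {
        abort_validation("unknown ", name, " label(s): ",
                         paste(bad, collapse = ", "))
      }
    }
    v
  }
  condition <- check_meta(condition, "condition", CONDITION_LEVELS)
  stage <- check_meta(stage, "stage", STAGE_LEVELS)
  if (length(cluster) == 1L && n_cells > 1L) cluster <- rep(cluster, n_cells)
  if (length(cluster) != n_cells) {
    abort_validation("cluster length != number of cells")
  }
  cluster <- as.integer(cluster)
  if (!is.null(cell_type)) {
    cell_type <- check_meta(cell_type, "cell_type", c(RETINAL_CELL_TYPES, "NI"))
  }
  if (!is.null(embedding)) {
    embedding <- as.matrix(embedding)
    if (nrow(embedding) != n_cells || ncol(embedding) != 2L) {
      abort_validation("embedding must be a cells x 2 matrix")
    }
    if (!all(is.finite(embedding))) {
      abort_validation("embedding coordinates must be finite")
    }
    dimnames(embedding) <- list(cell_ids, c("x", "y"))
  }
  rownames(counts) <- cell_ids
  colnames(counts) <- gene_ids
  structure(
    list(counts = counts, gene_ids = as.character(gene_ids),
         cell_ids = as.character(cell_ids), condition = condition,
         stage = stage, cluster = cluster, cell_type = cell_type,
         embedding = embedding, n_cells = n_cells, n_genes = n_genes),
    class = "cell_table"
  )
}

#' @export
print.cell_table <- function(x, ...) {
  cat("<cell_table> ", x$n_cells, " cells x ", x$n_genes, " genes\n", sep = "")
  cat("  conditions: ", paste(sprintf("%s=%d", names(table(x$condition)),
                                      table(x$condition)), collapse = ", "), "\n", sep = "")
  cat("  stages:     ", paste(sprintf("%s=%d", names(table(x$stage)),
                                      table(x$stage)), collapse = ", "), "\n", sep = "")
  cat("  embedding:  ", if (is.null(x$embedding)) "absent" else "present",
      "; cell types: ",
      if (is.null(x$cell_type)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

#' Subset a cell table by cell index
#'
#' @param table a [cell_table()].
#' @param idx integer or logical index over cells.
#' @return A `cell_table` with the selected cells.
#' @export
subset_cells <- function(table, idx) {
  stopifnot(inherits(table, "cell_table"))
  cell_table(table$counts[idx, , drop = FALSE], table$gene_ids,
             table$cell_ids[idx], table$condition[idx], table$stage[idx],
             table$cluster[idx],
             cell_type = if (is.null(table$cell_type)) NULL else table$cell_type[idx],
             embedding = if (is.null(table$embedding)) NULL else
               table$embedding[idx, , drop = FALSE])
}

#' Normalize counts to fraction of UMI
#'
#' Divides each cell's counts by that cell's total UMI count, the expression
#' unit used throughout the downstream statistics. Cells with zero total
#' counts keep an all-zero row and are flagged; they are excluded from every
#' downstream statistic.
#'
#' @param table a [cell_table()].
#' @return An `expression_matrix`: list with `values` (dense cells x genes
#'   matrix of fractions), `zero_count_cells` (barcodes of flagged cells) and
#'   `cell_ids`/`gene_ids`.
#' @export
normalize_fraction_umi <- function(table) {
  stopifnot(inherits(table, "cell_table"))
  if (table$n_genes < 1L) abort_validation("need at least one gene")
  totals <- Matrix::rowSums(table$counts)
  scale <- ifelse(totals > 0, 1 / totals, 0)
  values <- as.matrix(table$counts * scale)
  structure(
    list(values = values, cell_ids = table$cell_ids,
         gene_ids = table$gene_ids,
         zero_count_cells = table$cell_ids[totals == 0]),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " cells x ", ncol(x$values),
      " genes (fraction of UMI); ", length(x$zero_count_cells),
      " zero-count cell(s)\n", sep = "")
  invisible(x)
}
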