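#' Mean expression profile per gene across cell types
#'
#' For each requested gene and each cell type present, the mean
#' fraction-of-UMI over the cells of that type. Missing genes are dropped
#' with a logged name; types with zero cells are omitted and recorded.
#'
#' @param expr an `expression_matrix`.
#' @param cell_type per-cell labels.
#' @param genes a [gene_list()] of genes to profile.
#' @return A `profile_matrix`: list with `values` (genes x types),
#'   `dropped_genes`, `omitted_types`.
#' @export
mean_profile_matrix <- function(expr, cell_type, genes) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(genes, "gene_list"))
  present <- intersect(genes$genes, expr$gene_ids)
  dropped <- setdiff(genes$genes, expr$gene_ids)
  if (length(dropped)) {
    log_msg("profile genes absent from data, dropped: ",
            paste(dropped, collapse = ", "))
  }
  if (!length(present)) abort_validation("no requested gene present")
  keep <- !(expr$cell_ids %in% expr$zero_count_cells)
  vals <- expr$values[keep, present, drop = FALSE]
  labels <- cell_type[keep]
  types <- intersect(RETINAL_CELL_TYPES, unique(labels[!is.na(labels)]))
  omitted <- setdiff(RETINAL_CELL_TYPES, types)
  m <- sapply(types, function(ty)
    colMeans(vals[labels == ty, , drop = FALSE]))
  m <- matrix(m, nrow = length(present), ncol = length(types),
              dimnames = list(present, types))
  structure(list(values = m, dropped_genes = dropped,
                 omitted_types = omitted),
            class = "profile_matrix")
}

#' Correlate per-gene expression profiles between two datasets
#'
#' For each gene shared by both profile matrices, the Pearson (or Spearman)
#' correlation of its per-cell-type means over the cell-type columns common
#' to both. Genes with zero variance in either profile are excluded and
#' counted.
#'
#' @param a,b `profile_matrix` objects.
#' @param r_threshold report the count and percent of genes above this
#'   correlation (default 0.60).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `per_gene` (gene, r), `median_r`, `n_above`,
#'   `percent_above`, `n_zero_variance`, `common_types`.
#' @export
profile_correlation <- function(a, b, r_threshold = 0.60,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(a, "profile_matrix"), inherits(b, "profile_matrix"))
  types <- intersect(colnames(a$values), colnames(b$values))
  if (length(types) < 3L) {
    abort_validation("need >= 3 common cell-type columns, have ",
                     length(types))
  }
  genes <- intersect(rownames(a$values), rownames(b$values))
  if (!length(genes)) abort_validation("no common genes")
  av <- a$values[genes, types, drop = FALSE]
  bv <- b$values[genes, types, drop = FALSE]
  va <- apply(av, 1L, function(x) max(x) > min(x))
  vb <- apply(bv, 1L, function(x) max(x) > min(x))
  ok <- va & vb
  r <- rep(NA_real_, length(genes))
  r[ok] <- vapply(which(ok), function(i)
    cor(av[i, ], bv[i, ], method = method), numeric(1L))
  per_gene <- data.frame(gene = genes[ok], r = r[ok],
                         stringsAsFactors = FALSE)
  n_above <- sum(per_gene$r > r_threshold)
  list(per_gene = per_gene,
       median_r = if (nrow(per_gene)) median(per_gene$r) else NA_real_,
       n_above = n_above,
       percent_above = if (nrow(per_gene))
         100 * n_above / nrow(per_gene) else NA_real_,
       n_zero_variance = sum(!ok), common_types = types)
}
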