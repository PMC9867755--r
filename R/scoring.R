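#' Score marker signatures per cell or per cluster
#'
#' Expression is log-normalized as `log1p(norm_scale * fraction_of_UMI)`,
#' z-scored gene-wise across all cells (genes with zero variance contribute
#' z = 0, not NaN), and a signature's score is the mean z over its genes,
#' averaged within cluster when `by = "cluster"`.
#'
#' @param expr an `expression_matrix` from [normalize_fraction_umi()].
#' @param signatures named list of gene vectors (13 types, subpopulations,
#'   and/or cycle phases).
#' @param by `"cluster"` or `"cell"`.
#' @param cluster per-cell cluster ids (required when `by = "cluster"`).
#' @param norm_scale scale inside the log1p normalization (default 10,000).
#' @return A `score_matrix`: numeric matrix, rows = clusters or cells,
#'   columns = signatures. Missing signature genes are dropped with a
#'   warning; a signature with no gene present is an error.
#' @export
score_signatures <- function(expr, signatures, by = c("cluster", "cell"),
                             cluster = NULL, norm_scale = 1e4) {
  by <- match.arg(by)
  stopifnot(inherits(expr, "expression_matrix"))
  if (!length(signatures)) abort_validation("no signatures supplied")
  keep <- !(expr$cell_ids %in% expr$zero_count_cells)
  vals <- log1p(norm_scale * expr$values[keep, , drop = FALSE])
  mu <- colMeans(vals)
  sdv <- apply(vals, 2L, sd)
  z <- sweep(vals, 2L, mu, "-")
  nz <- sdv > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2L, sdv[nz], "/")
  z[, !nz] <- 0
  scores_cell <- sapply(names(signatures), function(nm) {
    genes <- intersect(signatures[[nm]], expr$gene_ids)
    missing <- setdiff(signatures[[nm]], expr$gene_ids)
    if (length(missing)) {
      warning("signature '", nm, "': ", length(missing),
              " gene(s) absent from the data", call. = FALSE)
    }
    if (!length(genes)) {
      abort_validation("signature '", nm, "' has no genes in the data")
    }
    rowMeans(z[, genes, drop = FALSE])
  })
  scores_cell <- matrix(scores_cell, ncol = length(signatures),
                        dimnames = list(expr$cell_ids[keep], names(signatures)))
  if (by == "cell") {
    return(structure(scores_cell, class = c("score_matrix", "matrix", "array"),
                     by = "cell"))
  }
  if (is.null(cluster)) abort_validation("cluster ids required for by='cluster'")
  cl <- as.character(cluster[keep])
  agg <- rowsum(scores_cell, cl) / as.vector(table(cl)[sort(unique(cl))])
  agg <- agg[order(suppressWarnings(as.numeric(rownames(agg))),
                   rownames(agg)), , drop = FALSE]
  structure(agg, class = c("score_matrix", "matrix", "array"), by = "cluster")
}

#' Assign cell types from signature scores
#'
#' Label = argmax over the 13 canonical type signatures; `"NI"` when the top
#' score is negative or the top-vs-second margin is below `margin_min`.
#' Exact ties go to the first signature in column order and are logged.
#'
#' @param scores a `score_matrix` (rows = clusters or cells).
#' @param margin_min minimum top-minus-second margin (default 0.05).
#' @param types which columns are cell-type signatures (defaults to the
#'   canonical 13 present in `scores`).
#' @return A data.frame with `id`, `label`, `top_score`, `margin`.
#' @export
assign_cell_types <- function(scores, margin_min = 0.05,
                              types = intersect(RETINAL_CELL_TYPES,
                                                colnames(scores))) {
  if (!length(types)) abort_validation("no cell-type signature columns found")
  s <- scores[, types, drop = FALSE]
  out <- data.frame(id = rownames(s), label = NA_character_,
                    top_score = NA_real_, margin = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(s))) {
    v <- s[i, ]
    top <- which.max(v)  # first index on ties
    sorted <- sort(v, decreasing = TRUE)
    margin <- if (length(v) > 1L) sorted[1L] - sorted[2L] else Inf
    if (length(v) > 1L && sorted[1L] == sorted[2L]) {
      log_msg("tie for row '", rownames(s)[i], "' broken by signature order (",
              types[top], ")")
    }
    out$top_score[i] <- v[top]
    out$margin[i] <- margin
    out$label[i] <- if (v[top] < 0 || margin < margin_min) "NI" else types[top]
  }
  out
}

#' Assign per-cell cell-cycle phase
#'
#' Per-cell S and G2-M signature scores; phase is the argmax when positive,
#' `"none"` otherwise.
#'
#' @param expr an `expression_matrix`.
#' @param signatures named list containing `S` and `G2-M` gene vectors.
#' @param norm_scale passed to [score_signatures()].
#' @return A data.frame with `cell_id` and `phase` in `{"S","G2-M","none"}`
#'   for every non-zero-count cell.
#' @export
assign_cycle_phase <- function(expr, signatures, norm_scale = 1e4) {
  need <- c("S", "G2-M")
  if (!all(need %in% names(signatures))) {
    abort_validation("signatures must contain 'S' and 'G2-M'")
  }
  s <- score_signatures(expr, signatures[need], by = "cell",
                        norm_scale = norm_scale)
  top <- max.col(s, ties.method = "first")
  phase <- ifelse(s[cbind(seq_len(nrow(s)), top)] > 0, need[top], "none")
  data.frame(cell_id = rownames(s), phase = phase, stringsAsFactors = FALSE)
}
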