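#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration of the rank-sum null distribution when both groups have
#' <= 10 values (valid under ties); otherwise the normal approximation with
#' the tie-corrected variance. All-identical input returns p = 1.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return Two-sided p-value in (0, 1]; symmetric in group order.
#' @export
rank_sum_test <- function(a, b) {
  if (!length(a) || !length(b)) abort_validation("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  if (max(c(a, b)) == min(c(a, b))) return(1)
  if (na <= 10L && nb <= 10L) {
    combs <- combn(n, na)
    sums <- colSums(matrix(r[combs], nrow = na))
    dev <- abs(sums - mu)
    p <- mean(dev >= abs(w - mu) - 1e-12)
    return(min(1, p))
  }
  ties <- table(r)
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

# vectorized normal-approximation rank-sum p-values over the columns of a
# matrix; used by the DE drivers where groups are large
rank_sum_p_columns <- function(mat, idx_a) {
  n <- nrow(mat)
  na <- length(idx_a); nb <- n - na
  vapply(seq_len(ncol(mat)), function(j) {
    x <- mat[, j]
    if (max(x) == min(x)) return(1)
    r <- rank(x)
    w <- sum(r[idx_a])
    mu <- na * (n + 1) / 2
    tl <- rle(sort(x))$lengths
    sigma2 <- na * nb / 12 * ((n + 1) - sum(tl^3 - tl) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    min(1, 2 * pnorm(-abs((w - mu) / sqrt(sigma2))))
  }, numeric(1L))
}

# rank each column once and test every type against the rest on the shared
# pooled ranks (the pool is all cells for each type-vs-rest contrast)
rank_sum_p_type_vs_rest <- function(mat, labels, types) {
  n <- nrow(mat)
  ranks <- matrix(0, n, ncol(mat))
  tie_term <- numeric(ncol(mat))
  constant <- logical(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    constant[j] <- max(x) == min(x)
    ranks[, j] <- rank(x)
    tl <- rle(sort(x))$lengths
    tie_term[j] <- sum(tl^3 - tl) / (n * (n - 1))
  }
  out <- matrix(1, length(types), ncol(mat), dimnames = list(types, NULL))
  for (ty in types) {
    idx <- which(labels == ty)
    na <- length(idx); nb <- n - na
    if (!na || !nb) next
    w <- colSums(ranks[idx, , drop = FALSE])
    mu <- na * (n + 1) / 2
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    p <- 2 * pnorm(-abs((w - mu) / sqrt(pmax(sigma2, .Machine$double.eps))))
    p[constant | sigma2 <= 0] <- 1
    out[ty, ] <- pmin(1, p)
  }
  out
}

#' Benjamini-Hochberg q-values
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return Step-up adjusted q-values, `q >= p` elementwise.
#' @export
adjust_fdr <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE)) {
    abort_validation("p-values must be in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Cell-type-specifying genes
#'
#' For each cell type, every gene is tested (rank-sum) in cells of that type
#' against all other cells; a gene is "cell-type-specifying" when its
#' natural-log fold change of mean fraction-of-UMI (type vs rest, with
#' pseudocount) is >= `logfc_min` and p <= `p_max`. BH q-values are computed
#' within each type's family and reported alongside.
#'
#' @param expr an `expression_matrix`.
#' @param cell_type per-cell labels (same order as `expr$cell_ids`).
#' @param cfg a [pipeline_config()].
#' @return data.frame of records: gene, cell_type, contrast
#'   (`"type_vs_rest"`), log_fold_change, p_value, q_value. Types with < 3
#'   cells are skipped with a warning. Zero-count cells are excluded.
#' @export
cell_type_specifying <- function(expr, cell_type, cfg = pipeline_config()) {
  stopifnot(inherits(expr, "expression_matrix"))
  keep <- !(expr$cell_ids %in% expr$zero_count_cells)
  vals <- expr$values[keep, , drop = FALSE]
  labels <- cell_type[keep]
  types <- intersect(c(RETINAL_CELL_TYPES, "NI"),
                     unique(labels[!is.na(labels)]))
  types <- setdiff(types, "NI")
  if (length(types) < 2L) abort_validation("need at least 2 cell types")
  eps <- cfg$pseudocount
  usable <- types[vapply(types, function(ty) sum(labels == ty) >= 3L,
                         logical(1L))]
  for (ty in setdiff(types, usable)) {
    warning("cell type ", ty, " has < 3 cells; skipped", call. = FALSE)
  }
  p_all <- rank_sum_p_type_vs_rest(vals, labels, usable)
  recs <- list()
  for (ty in usable) {
    in_ty <- which(labels == ty)
    mean_in <- colMeans(vals[in_ty, , drop = FALSE])
    mean_out <- colMeans(vals[-in_ty, , drop = FALSE])
    lfc <- log((mean_in + eps) / (mean_out + eps))
    p <- p_all[ty, ]
    q <- adjust_fdr(p)
    pass <- lfc >= cfg$logfc_min & p <= cfg$p_max
    if (any(pass)) {
      recs[[ty]] <- data.frame(
        gene = expr$gene_ids[pass], cell_type = ty,
        contrast = "type_vs_rest", log_fold_change = lfc[pass],
        p_value = p[pass], q_value = q[pass], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(gene = character(0), cell_type = character(0),
               contrast = character(0), log_fold_change = numeric(0),
               p_value = numeric(0), q_value = numeric(0))
  rownames(out) <- NULL
  out
}

#' Per-cell-type condition contrasts
#'
#' Within each cell type present in both conditions, every gene is tested
#' two-sided between native and organoid cells; genes are split by the sign
#' of the native-vs-organoid log fold change, BH-adjusted within each
#' (cell type, direction) family, and kept at q <= `q_max`. The contrast
#' label is `"native_gt_organoid"` or `"organoid_gt_native"`.
#'
#' @param expr an `expression_matrix`.
#' @param cell_type per-cell labels.
#' @param condition per-cell condition labels.
#' @param cfg a [pipeline_config()].
#' @return data.frame of records (gene, cell_type, contrast,
#'   log_fold_change of native over organoid means, p_value, q_value).
#'   Types present in one condition only (or with < 3 cells on a side) are
#'   skipped with a warning.
#' @export
condition_contrast <- function(expr, cell_type, condition,
                               cfg = pipeline_config()) {
  stopifnot(inherits(expr, "expression_matrix"))
  keep <- !(expr$cell_ids %in% expr$zero_count_cells)
  vals <- expr$values[keep, , drop = FALSE]
  labels <- cell_type[keep]
  cond <- condition[keep]
  types <- setdiff(intersect(c(RETINAL_CELL_TYPES, "NI"),
                             unique(labels[!is.na(labels)])), "NI")
  eps <- cfg$pseudocount
  recs <- list()
  for (ty in types) {
    in_ty <- which(labels == ty)
    nat <- in_ty[cond[in_ty] == "native"]
    org <- in_ty[cond[in_ty] == "organoid"]
    if (length(nat) < 3L || length(org) < 3L) {
      warning("cell type ", ty,
              " lacks >= 3 cells in both conditions; skipped", call. = FALSE)
      next
    }
    sub <- vals[c(nat, org), , drop = FALSE]
    p <- rank_sum_p_columns(sub, seq_along(nat))
    lfc <- log((colMeans(vals[nat, , drop = FALSE]) + eps) /
                 (colMeans(vals[org, , drop = FALSE]) + eps))
    for (dir in c("native_gt_organoid", "organoid_gt_native")) {
      sel <- if (dir == "native_gt_organoid") lfc > 0 else lfc < 0
      if (!any(sel)) next
      q <- adjust_fdr(p[sel])
      pass <- q <= cfg$q_max
      if (any(pass)) {
        recs[[paste(ty, dir)]] <- data.frame(
          gene = expr$gene_ids[sel][pass], cell_type = ty, contrast = dir,
          log_fold_change = lfc[sel][pass], p_value = p[sel][pass],
          q_value = q[pass], stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(gene = character(0), cell_type = character(0),
               contrast = character(0), log_fold_change = numeric(0),
               p_value = numeric(0), q_value = numeric(0))
  rownames(out) <- NULL
  out
}

#' Transcription-factor specificity annotation
#'
#' Among cell-type-specifying genes that belong to a supplied TF list, the
#' specificity fold is the top per-type mean fraction-of-UMI divided by the
#' best mean among the remaining types (pseudocount added); a TF is flagged
#' when the fold is >= `fold`.
#'
#' @param expr an `expression_matrix`.
#' @param cell_type per-cell labels.
#' @param specifying data.frame from [cell_type_specifying()].
#' @param tf_list a [gene_list()] of transcription factors.
#' @param fold flag threshold (default 1.5).
#' @param pseudocount added to both means.
#' @return data.frame: gene, is_tf, top_type, specificity_fold, flagged.
#' @export
tf_specificity <- function(expr, cell_type, specifying, tf_list, fold = 1.5,
                           pseudocount = 1e-9) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(tf_list, "gene_list"))
  genes <- intersect(unique(specifying$gene), tf_list$genes)
  if (!length(genes)) {
    return(data.frame(gene = character(0), is_tf = logical(0),
                      top_type = character(0), specificity_fold = numeric(0),
                      flagged = logical(0)))
  }
  prof <- mean_profile_matrix(expr, cell_type, gene_list("tf", genes))
  m <- prof$values
  out <- data.frame(gene = rownames(m), is_tf = TRUE,
                    top_type = NA_character_, specificity_fold = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    top <- which.max(v)
    second <- max(v[-top])
    out$top_type[i] <- colnames(m)[top]
    out$specificity_fold[i] <- (v[top] + pseudocount) / (second + pseudocount)
  }
  out$flagged <- out$specificity_fold >= fold
  out
}

#' Bootstrap percentile confidence interval for a mean
#'
#' @param values numeric vector (>= 1 value).
#' @param n_boot bootstrap resamples (default 1000).
#' @param level confidence level (default 0.99: quantiles 0.005 and 0.995).
#' @param seed integer seed.
#' @return Named numeric vector `(mean, lo, hi)`.
#' @export
bootstrap_mean_ci <- function(values, n_boot = 1000L, level = 0.99,
                              seed = 1L) {
  if (!length(values)) abort_validation("need at least one value")
  set.seed(stage_seed(seed, "bootstrap"))
  n <- length(values)
  means <- rowMeans(matrix(sample(values, n * n_boot, replace = TRUE),
                           nrow = n_boot))
  alpha <- (1 - level) / 2
  qs <- quantile(means, c(alpha, 1 - alpha), names = FALSE)
  c(mean = mean(values), lo = qs[1L], hi = qs[2L])
}
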