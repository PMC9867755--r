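# fixtures are built in code at test time

# tiny 10x-style bundle on disk; counts is a cells x genes base matrix
write_mtx_fixture <- function(dir, counts, gene_ids, barcodes, meta) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(Matrix::Matrix(counts, sparse = TRUE)),
                  file.path(dir, "matrix.mtx"))
  writeLines(gene_ids, file.path(dir, "genes.tsv"))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dir
}

# minimal valid cell table straight from components
make_table <- function(counts, condition, stage,
                       cluster = seq_len(nrow(counts)),
                       cell_type = NULL, embedding = NULL,
                       gene_ids = sprintf("g%03d", seq_len(ncol(counts)))) {
  cell_table(counts, gene_ids, sprintf("bc%03d", seq_len(nrow(counts))),
             condition, stage, cluster, cell_type = cell_type,
             embedding = embedding)
}

# expression_matrix directly from a dense fraction matrix (rows sum to 1)
make_expr <- function(values, gene_ids = sprintf("g%03d", seq_len(ncol(values))),
                      cell_ids = sprintf("bc%03d", seq_len(nrow(values)))) {
  structure(list(values = `dimnames<-`(values, list(cell_ids, gene_ids)),
                 cell_ids = cell_ids, gene_ids = gene_ids,
                 zero_count_cells = character(0)),
            class = "expression_matrix")
}

# ---- independent oracles -------------------------------------------------

# O(N^2) brute-force mean distance to n nearest neighbours
brute_knn_mean <- function(points, query, n_max) {
  d <- unname(as.matrix(dist(points)))
  t(vapply(query, function(q) {
    dd <- sort(d[q, -q])
    cumsum(dd[seq_len(n_max)]) / seq_len(n_max)
  }, numeric(n_max)))
}

# exhaustive hypergeometric upper tail by enumerating all draws (N <= 15)
enum_hypergeom_upper <- function(k, n, K, N) {
  draws <- combn(N, n)
  marked <- seq_len(K)
  hits <- colSums(matrix(draws %in% marked, nrow = n))
  mean(hits >= k)
}

# exact two-sided rank-sum p by enumerating group assignments
enum_rank_sum <- function(a, b) {
  na <- length(a); n <- na + length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  sums <- colSums(matrix(r[combn(n, na)], nrow = na))
  mean(abs(sums - mu) >= abs(w - mu) - 1e-12)
}

# mean silhouette over points given integer cluster labels
silhouette_mean <- function(x, labels) {
  d <- as.matrix(dist(x))
  mean(vapply(seq_len(nrow(x)), function(i) {
    own <- which(labels == labels[i] & seq_along(labels) != i)
    a <- if (length(own)) mean(d[i, own]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(d[i, labels == cl]), numeric(1L)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1L)))
}

# hex colour string -> numeric RGB vector
hex_to_rgb <- function(hex) {
  vapply(c(2L, 4L, 6L), function(i)
    strtoi(substr(hex, i, i + 1L), base = 16L), numeric(1L))
}

default_sim_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_retina(synth_config(seed = 42L))
    cache
  }
})
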