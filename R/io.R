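#' Read a 10x-style MTX bundle plus per-cell metadata into a cell table
#'
#' The MatrixMarket file stores genes x rows, cells x columns (10x v2
#' convention) and is transposed on load. Metadata is a TSV with a header and
#' columns `barcode`, `condition`, `stage`, `cluster`, and optionally
#' `cell_type`, `x`, `y`.
#'
#' @param matrix_path path to the MatrixMarket `.mtx` file (genes x cells).
#' @param genes_path path to a TSV of gene ids (first column used as symbol;
#'   a second column, if present, is ignored).
#' @param barcodes_path path to a one-column file of cell barcodes.
#' @param metadata_path path to the per-cell metadata TSV.
#' @return A validated [cell_table()].
#' @export
load_cell_table <- function(matrix_path, genes_path, barcodes_path,
                            metadata_path) {
  m <- Matrix::readMM(matrix_path)
  genes_tab <- read.delim(genes_path, header = FALSE,
                          stringsAsFactors = FALSE)
  gene_ids <- as.character(genes_tab[[1L]])
  barcodes <- as.character(read.delim(barcodes_path, header = FALSE,
                                      stringsAsFactors = FALSE)[[1L]])
  if (nrow(m) != length(gene_ids)) {
    stop("format error: MTX declares ", nrow(m), " genes but genes file has ",
         length(gene_ids), call. = FALSE)
  }
  if (ncol(m) != length(barcodes)) {
    stop("format error: MTX declares ", ncol(m), " cells but barcodes file has ",
         length(barcodes), call. = FALSE)
  }
  meta <- read.delim(metadata_path, header = TRUE, stringsAsFactors = FALSE)
  required <- c("barcode", "condition", "stage", "cluster")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("format error: metadata lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  missing_bc <- setdiff(barcodes, meta$barcode)
  if (length(missing_bc)) {
    abort_validation("metadata missing barcode(s): ",
                     paste(head(missing_bc, 5L), collapse = ", "),
                     if (length(missing_bc) > 5L) " ...")
  }
  meta <- meta[match(barcodes, meta$barcode), , drop = FALSE]
  emb <- NULL
  if (all(c("x", "y") %in% names(meta))) {
    emb <- cbind(x = as.numeric(meta$x), y = as.numeric(meta$y))
  }
  cell_table(Matrix::t(m), gene_ids, barcodes,
             condition = meta$condition, stage = meta$stage,
             cluster = meta$cluster,
             cell_type = if ("cell_type" %in% names(meta)) meta$cell_type,
             embedding = emb)
}

#' Write a cell table as an MTX bundle plus metadata TSV
#'
#' Inverse of [load_cell_table()]: writes `matrix.mtx` (genes x cells),
#' `genes.tsv`, `barcodes.tsv` and `metadata.tsv` under `dir`.
#'
#' @param table a [cell_table()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the four file paths.
#' @export
write_cell_table <- function(table, dir) {
  stopifnot(inherits(table, "cell_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv",
                            "metadata.tsv"))
  Matrix::writeMM(Matrix::t(table$counts), paths[1L])
  writeLines(table$gene_ids, paths[2L])
  writeLines(table$cell_ids, paths[3L])
  meta <- data.frame(barcode = table$cell_ids, condition = table$condition,
                     stage = table$stage, cluster = table$cluster,
                     stringsAsFactors = FALSE)
  if (!is.null(table$cell_type)) meta$cell_type <- table$cell_type
  if (!is.null(table$embedding)) {
    meta$x <- table$embedding[, 1L]
    meta$y <- table$embedding[, 2L]
  }
  write.table(meta, paths[4L], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a one-gene-per-line list
#'
#' @param path file with one gene symbol per line; blank lines and lines
#'   starting with `#` are skipped.
#' @param name list name (defaults to the file name).
#' @return A `gene_list`: list with `name` and unique `genes`.
#' @export
read_gene_list <- function(path, name = basename(path)) {
  lines <- trimws(readLines(path))
  genes <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_list(name, genes)
}

#' Construct a gene list
#'
#' @param name list name.
#' @param genes character vector of gene symbols; duplicates collapsed.
#' @return A `gene_list` object.
#' @export
gene_list <- function(name, genes) {
  genes <- unique(as.character(genes))
  if (!length(genes)) abort_validation("gene list '", name, "' is empty")
  structure(list(name = name, genes = genes), class = "gene_list")
}

#' Read a Broad-dialect GMT file into a gene set collection
#'
#' Each line: set name, description, then member genes, tab-separated.
#' Duplicate genes within a set are collapsed; empty sets are dropped with a
#' warning.
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`: named list of character vectors with a
#'   `description` attribute per set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    # count fields by tabs: strsplit drops trailing empties, but a line
    # "SET\tdesc\t" is a legal (empty) three-field record
    n_fields <- nchar(gsub("[^\t]", "", lines[[i]])) + 1L
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (n_fields < 3L) {
      stop("format error in GMT line ", i, ": expected >= 3 tab-separated ",
           "fields, got ", n_fields, call. = FALSE)
    }
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) {
      warning("GMT set '", fields[1L], "' has no genes; dropped",
              call. = FALSE)
      next
    }
    sets[[fields[1L]]] <- structure(genes, description = fields[2L])
  }
  if (anyDuplicated(names(sets))) {
    abort_validation("duplicate set names in GMT: ",
                     paste(unique(names(sets)[duplicated(names(sets))]),
                           collapse = ", "))
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a gene set collection as GMT
#'
#' @param sets named list of character vectors (or a `gene_set_collection`).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description") %||% "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
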