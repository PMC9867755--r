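test_that("MTX bundle round-trips through load_cell_table exactly", {
  counts <- matrix(c(0, 1, 2, 5, 0, 3), nrow = 3)
  meta <- data.frame(barcode = c("bcA", "bcB", "bcC"),
                     condition = c("native", "native", "organoid"),
                     stage = c("I", "II", "IV"), cluster = c(1L, 1L, 2L),
                     cell_type = c("NE", "RGC", "NI"),
                     x = c(0.5, -1, 2), y = c(1, 0, -3))
  dir <- write_mtx_fixture(withr::local_tempdir(), counts,
                           c("Pax6", "Rax"), meta$barcode, meta)
  tab <- load_cell_table(file.path(dir, "matrix.mtx"),
                         file.path(dir, "genes.tsv"),
                         file.path(dir, "barcodes.tsv"),
                         file.path(dir, "metadata.tsv"))
  expect_equal(tab$n_cells, 3L)
  expect_equal(tab$n_genes, 2L)
  expect_equal(as.matrix(tab$counts), counts, ignore_attr = TRUE)
  expect_equal(tab$condition, meta$condition)
  expect_equal(tab$stage, meta$stage)
  expect_equal(tab$cell_type, meta$cell_type)
  expect_equal(unname(tab$embedding[, "x"]), meta$x)

  # write_cell_table is its inverse
  out <- file.path(dir, "rt")
  write_cell_table(tab, out)
  tab2 <- load_cell_table(file.path(out, "matrix.mtx"),
                          file.path(out, "genes.tsv"),
                          file.path(out, "barcodes.tsv"),
                          file.path(out, "metadata.tsv"))
  expect_equal(as.matrix(tab2$counts), as.matrix(tab$counts))
  expect_equal(tab2$condition, tab$condition)
  expect_equal(tab2$cluster, tab$cluster)
  expect_equal(tab2$embedding, tab$embedding)
})

test_that("loader rejects inconsistent bundles with informative errors", {
  counts <- matrix(1:6, nrow = 3)
  meta <- data.frame(barcode = c("bcA", "bcB", "bcC"),
                     condition = "native", stage = "I", cluster = 1L)
  dir <- write_mtx_fixture(withr::local_tempdir(), counts,
                           c("Pax6", "Rax"), meta$barcode, meta)

  # metadata missing one barcode, named in the error
  write.table(meta[meta$barcode != "bcB", ], file.path(dir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_cell_table(file.path(dir, "matrix.mtx"),
                               file.path(dir, "genes.tsv"),
                               file.path(dir, "barcodes.tsv"),
                               file.path(dir, "metadata.tsv")),
               "bcB")

  # barcode count disagreeing with the MTX header
  write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(c("bcA", "bcB"), file.path(dir, "barcodes.tsv"))
  expect_error(load_cell_table(file.path(dir, "matrix.mtx"),
                               file.path(dir, "genes.tsv"),
                               file.path(dir, "barcodes.tsv"),
                               file.path(dir, "metadata.tsv")),
               "format error")

  # unknown condition label
  writeLines(c("bcA", "bcB", "bcC"), file.path(dir, "barcodes.tsv"))
  meta_bad <- meta
  meta_bad$condition[2] <- "retina"
  write.table(meta_bad, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(load_cell_table(file.path(dir, "matrix.mtx"),
                               file.path(dir, "genes.tsv"),
                               file.path(dir, "barcodes.tsv"),
                               file.path(dir, "metadata.tsv")),
               "retina")
})

test_that("cell_table enforces its invariants", {
  counts <- matrix(0:3, nrow = 2)
  expect_error(make_table(matrix(c(-1, 0, 1, 2), 2), c("native", "native"),
                          c("I", "I")), "non-negative")
  expect_error(cell_table(counts, c("a", "a"), c("b1", "b2"),
                          c("native", "native"), c("I", "I"), c(1L, 1L)),
               "unique")
  expect_error(make_table(counts, c("native", "native"), c("I", "V")),
               "stage")
  expect_error(make_table(counts, c("native", "native"), c("I", "I"),
                          embedding = matrix(c(0, Inf, 0, 0), 2)), "finite")
})

test_that("fraction-of-UMI normalization divides by cell totals and flags zero cells", {
  counts <- rbind(c(2, 8, 0), c(0, 0, 0), c(1, 1, 2))
  tab <- make_table(counts, rep("native", 3), rep("I", 3))
  expr <- normalize_fraction_umi(tab)
  expect_equal(unname(expr$values[1, ]), c(0.2, 0.8, 0))
  expect_equal(unname(expr$values[2, ]), c(0, 0, 0))
  expect_equal(unname(expr$values[3, ]), c(0.25, 0.25, 0.5))
  expect_equal(expr$zero_count_cells, "bc002")
  sums <- rowSums(expr$values)
  expect_equal(sums[c(1, 3)], c(1, 1), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("GMT parsing collapses duplicates, drops empty sets, flags bad lines", {
  path <- withr::local_tempfile()
  writeLines(c("S1\tdesc\tA\tB\tB", "S2\tdesc\tC\tD"), path)
  sets <- read_gmt(path)
  expect_length(sets, 2L)
  expect_equal(sort(unclass(sets$S1)), c("A", "B"), ignore_attr = TRUE)

  writeLines(c("S1\tonlytwo"), path)
  expect_error(read_gmt(path), "line 1")

  writeLines(c("S1\tdesc\tA", "EMPTY\tdesc\t"), path)
  expect_warning(sets <- read_gmt(path), "EMPTY")
  expect_length(sets, 1L)

  # round trip through write_gmt
  write_gmt(list(S1 = c("A", "B"), S2 = "C"), path)
  back <- read_gmt(path)
  expect_equal(lapply(back, as.character), list(S1 = c("A", "B"), S2 = "C"))
})

test_that("gene list reader skips comments and deduplicates", {
  path <- withr::local_tempfile()
  writeLines(c("# tf list", "Pax6", "Rax", "Pax6", ""), path)
  gl <- read_gene_list(path, name = "tf")
  expect_equal(gl$genes, c("Pax6", "Rax"))
  expect_error(gene_list("empty", character(0)), "empty")
})
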