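test_that("read_mtx_triplet round-trips a hand-written triplet", {
  dir <- write_mtx_fixture(withr::local_tempdir(), 3, 2,
                           entries = rbind(c(1, 1, 5), c(3, 2, 1)))
  m <- read_mtx_triplet(file.path(dir, "matrix.mtx"),
                        file.path(dir, "features.tsv"),
                        file.path(dir, "barcodes.tsv"))
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(rownames(m), c("g1", "g2", "g3"))
  expect_equal(colnames(m), c("b1", "b2"))
  expected <- matrix(0, 3, 2, dimnames = dimnames(m))
  expected[1, 1] <- 5; expected[3, 2] <- 1
  expect_equal(as.matrix(m), expected)

  # empty matrix with declared shape
  dir2 <- write_mtx_fixture(withr::local_tempdir(), 2, 2,
                            entries = matrix(0, 0, 3))
  m2 <- read_mtx_triplet(file.path(dir2, "matrix.mtx"),
                         file.path(dir2, "features.tsv"),
                         file.path(dir2, "barcodes.tsv"))
  expect_equal(dim(m2), c(2L, 2L))
  expect_equal(sum(m2), 0)
})

test_that("read_mtx_triplet rejects malformed triplets, naming the file", {
  dir <- write_mtx_fixture(withr::local_tempdir(), 3, 3,
                           entries = rbind(c(1, 1, 2)),
                           barcodes = c("b1", "b2"))  # 2 barcodes, 3 declared
  expect_error(
    read_mtx_triplet(file.path(dir, "matrix.mtx"),
                     file.path(dir, "features.tsv"),
                     file.path(dir, "barcodes.tsv")),
    "barcodes.tsv")
  expect_error(read_mtx_triplet("nope.mtx", "nope.tsv", "nope.tsv"),
               "not found")

  # non-integer entries
  dir3 <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 2 1", "1 1 2.5"), file.path(dir3, "matrix.mtx"))
  writeLines(c("g1", "g2"), file.path(dir3, "features.tsv"))
  writeLines(c("b1", "b2"), file.path(dir3, "barcodes.tsv"))
  expect_error(
    read_mtx_triplet(file.path(dir3, "matrix.mtx"),
                     file.path(dir3, "features.tsv"),
                     file.path(dir3, "barcodes.tsv")),
    "non-integer")
})

test_that("as_count_matrix enforces the container invariants", {
  m <- toy_counts()
  expect_s4_class(as_count_matrix(m), "dgCMatrix")
  neg <- m; neg[1, 1] <- -1
  expect_error(as_count_matrix(neg), "negative")
  frac <- m; frac[1, 1] <- 1.5
  expect_error(as_count_matrix(frac), "non-integer")
  dupg <- m; rownames(dupg)[2] <- rownames(dupg)[1]
  expect_warning(ok <- as_count_matrix(dupg), "duplicate gene IDs")
  expect_false(anyDuplicated(rownames(ok)) > 0)
  dupb <- m; colnames(dupb)[2] <- colnames(dupb)[1]
  expect_error(as_count_matrix(dupb), "duplicate barcodes")
  expect_error(as_count_matrix(unname(m)), "gene IDs")
})

test_that("read_spatial_positions validates and reconciles with counts", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(barcode = paste0("b", 1:4), x = c(-1, 0, 1, 2),
                    y = 1:4, section = "S1", condition = c("A", "A", "B", "B"))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_spatial_positions(path)
  expect_equal(nrow(got), 4L)
  expect_equal(got$barcode, tab$barcode)

  counts <- toy_counts(4, 3, barcodes = paste0("b", 1:3))
  expect_warning(got2 <- read_spatial_positions(path, counts), "dropped")
  expect_equal(nrow(got2), 3L)

  dup <- tab; dup$barcode[2] <- "b1"
  write.table(dup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_spatial_positions(path), "duplicate")

  bad <- tab; bad$x[1] <- NA
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_spatial_positions(path), "coordinate")

  noc <- tab[, setdiff(names(tab), "condition")]
  write.table(noc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_spatial_positions(path), "condition")
})

test_that("qc_filter_cells applies strict boundary semantics", {
  # 300 genes so a 200-gene cell is constructible
  n_genes <- 300
  genes <- c(sprintf("g%d", seq_len(n_genes - 1)), "mt-nd1")
  make_cell <- function(n_detected) {
    v <- integer(n_genes)
    v[seq_len(n_detected)] <- 1L
    v
  }
  # boundary cell: exactly 200 genes detected (199 nuclear + 1 mito) and
  # exactly 5% mitochondrial reads (11 of 220)
  boundary <- integer(n_genes)
  boundary[1:199] <- 1L
  boundary[1:10] <- 2L          # nuclear total 209
  boundary[n_genes] <- 11L      # mito 11; 11 / 220 = 0.05
  m <- cbind(low = make_cell(150), boundary = boundary,
             clean = make_cell(250))
  rownames(m) <- genes
  qc <- compute_qc_metrics(m)
  expect_equal(qc$n_genes_detected[qc$barcode == "boundary"], 200L)
  expect_equal(qc$mito_fraction[qc$barcode == "boundary"], 0.05)

  out <- qc_filter_cells(m)
  expect_equal(colnames(out$counts), c("boundary", "clean"))
  expect_equal(rownames(out$counts), genes)  # gene set unchanged

  # all compliant -> identity
  clean <- m[, c("boundary", "clean")]
  out2 <- qc_filter_cells(clean)
  expect_equal(as.matrix(out2$counts), as.matrix(as_count_matrix(clean)))

  expect_warning(qc_filter_cells(m[, "low", drop = FALSE]), "no cells")
})

test_that("qc_filter_genes and qc_filter_spatial_barcodes use strict bounds", {
  m <- matrix(0L, 3, 4,
              dimnames = list(c("in2", "in3", "in4"), paste0("c", 1:4)))
  m["in2", 1:2] <- 1L
  m["in3", 1:3] <- 1L
  m["in4", 1:4] <- 1L
  out <- qc_filter_genes(m, min_observations = 3)
  expect_equal(rownames(out), c("in3", "in4"))
  expect_equal(rownames(qc_filter_genes(m, min_observations = 0)),
               rownames(m))

  sp <- matrix(0L, 2, 3,
               dimnames = list(c("g1", "g2"), c("shallow", "edge", "deep")))
  sp[1, ] <- c(4999L, 5000L, 9000L)
  out2 <- qc_filter_spatial_barcodes(sp)
  expect_equal(colnames(out2), c("edge", "deep"))
  expect_equal(colnames(qc_filter_spatial_barcodes(sp, min_umis = 0)),
               colnames(sp))
})

test_that("QC filters are idempotent and order-independent", {
  m <- toy_counts(50, 30, seed = 42)
  m[, 1:5] <- 0L; m[1:5, ] <- 0L
  m[1, 1] <- 1L  # gene seen once, cell with one gene
  meta <- compute_qc_metrics(m)

  f1 <- qc_filter_cells(m, meta, min_genes = 10, max_mito = 0.5)
  f2 <- qc_filter_cells(f1$counts, f1$meta, min_genes = 10, max_mito = 0.5)
  expect_equal(as.matrix(f2$counts), as.matrix(f1$counts))
  g1 <- qc_filter_genes(m, 5)
  expect_equal(as.matrix(qc_filter_genes(g1, 5)), as.matrix(g1))
  s1 <- qc_filter_spatial_barcodes(m, 50)
  expect_equal(as.matrix(qc_filter_spatial_barcodes(s1, 50)),
               as.matrix(s1))

  # cells-then-genes and genes-then-cells agree when meta carries the QC
  # covariates (gene filtering must not change stored n_genes_detected)
  a <- qc_filter_genes(qc_filter_cells(m, meta, 10, 0.5)$counts, 5)
  b <- qc_filter_cells(qc_filter_genes(m, 5), meta, 10, 0.5)$counts
  expect_equal(colnames(a), colnames(b))
})

test_that("normalize_log1p_cpm matches hand-computed values", {
  m <- matrix(c(3L, 1L), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
  f <- normalize_log1p_cpm(m)
  expect_equal(unname(as.matrix(f)[1, ]), c(log(1 + 7500), log(1 + 2500)))
  expect_equal(attr(f, "kind"), "log_normalized_counts")

  # zero count stays zero; single expressed gene saturates at log(1 + 1e4)
  m2 <- matrix(c(0L, 7L), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
  f2 <- as.matrix(normalize_log1p_cpm(m2))
  expect_equal(unname(f2[1, ]), c(0, log(1 + 1e4)))
  m3 <- matrix(c(0L, 123L), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
  expect_equal(as.matrix(normalize_log1p_cpm(m3)),
               f2, ignore_attr = TRUE)

  zero <- matrix(c(1L, 0L), 1, 2,
                 dimnames = list("g1", c("ok", "empty")))
  expect_error(normalize_log1p_cpm(zero), "empty")

  # invariance to scaling a column by a positive integer
  m4 <- toy_counts(20, 5, seed = 3)
  m5 <- m4; m5[, 2] <- m5[, 2] * 7L
  expect_equal(as.matrix(normalize_log1p_cpm(m4)),
               as.matrix(normalize_log1p_cpm(m5)), tolerance = 1e-12)
})

test_that("mirror_x reflects x and leaves everything else alone", {
  co <- data.frame(barcode = c("a", "b", "c"), x = c(-1.2, 0, 2.5),
                   y = c(3.0, 0, -4), section = "S1")
  got <- mirror_x(co)
  expect_equal(got$x, c(1.2, 0, 2.5))
  expect_equal(got$y, co$y)
  expect_equal(got$section, co$section)
  pos <- data.frame(barcode = "a", x = 1, y = 1)
  expect_equal(mirror_x(pos), pos)
})

test_that("scores tables round-trip losslessly at 1e-6", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(unit_id = c("u1", "u2"),
                   mean_auc = c(0.1234567, 0.9876543),
                   n_repeats = c(50L, 50L), sd_auc = c(0.01, 0.02))
  write_scores_table(df, path)
  back <- read_scores_table(path)
  expect_equal(nrow(back), 2L)
  expect_equal(back$mean_auc, df$mean_auc, tolerance = 1e-6)
  expect_equal(back$unit_id, df$unit_id)

  empty <- df[0, ]
  write_scores_table(empty, path)
  expect_equal(length(readLines(path)), 1L)  # header only
  expect_error(write_scores_table(df, file.path(withr::local_tempdir(),
                                                "no/such/dir/x.tsv")),
               "cannot write")
})

test_that("count matrices survive an mtx write/read round trip", {
  m <- as_count_matrix(toy_counts(15, 8, seed = 9))
  dir <- withr::local_tempdir()
  write_mtx_triplet(m, dir)
  back <- read_mtx_triplet(file.path(dir, "matrix.mtx"),
                           file.path(dir, "features.tsv"),
                           file.path(dir, "barcodes.tsv"))
  expect_equal(as.matrix(back), as.matrix(m))
})
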