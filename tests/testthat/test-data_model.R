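# domain types, format round-trips, preprocessing recipes

test_that("constructors enforce the core invariants", {
  expect_error(omic_matrix(matrix(c(1, -1, 0, 2), 2, 2)), "negative")
  expect_error(omic_matrix(matrix(c(1, NA, 0, 2), 2, 2)), "non-finite")
  expect_error(omic_matrix(matrix(1, 2, 2), feature_ids = c("a", "a")),
               "duplicate")
  a <- omic_matrix(matrix(1, 3, 4), name = "A")
  b99 <- omic_matrix(matrix(1, 2, 3), name = "B")
  expect_error(multi_omics(list(a, b99)), "aligned")
  # barcode order mismatch is an alignment error, not a silent reorder
  m1 <- matrix(1, 2, 3, dimnames = list(NULL, c("c1", "c2", "c3")))
  m2 <- matrix(1, 2, 3, dimnames = list(NULL, c("c2", "c1", "c3")))
  expect_error(multi_omics(list(omic_matrix(m1), omic_matrix(m2))),
               "order|differ")
  expect_error(plnmfg_hyperparameters(gamma = 1), "gamma")
  expect_error(plnmfg_hyperparameters(tol = 0), "tol")
})

test_that("mtx and csv round-trips are value-preserving", {
  for (seed in 1:3) {
    x <- random_dataset(seed, v = 2, n = 10, d = c(7, 4))
    x$true_labels <- sample(1:3, 10, replace = TRUE)
    for (fmt in c("mtx", "csv")) {
      dir <- file.path(tempfile(), fmt)
      write_multi_omics(x, dir, format = fmt)
      y <- read_multi_omics(dir, format = fmt)
      expect_equal(length(y$omics), 2L)
      expect_identical(y$cell_ids, x$cell_ids)
      expect_identical(y$true_labels, as.integer(x$true_labels))
      for (i in 1:2)
        expect_equal(as.matrix(y$omics[[i]]$values),
                     as.matrix(x$omics[[i]]$values),
                     ignore_attr = TRUE, tolerance = 1e-12)
    }
  }
})

test_that("h5 round-trip is bitwise value-preserving", {
  x <- random_dataset(11, v = 1, n = 5, d = 10)
  dir <- tempfile()
  write_multi_omics(x, dir, format = "h5")
  y <- read_multi_omics(dir, format = "h5")
  expect_identical(y$cell_ids, x$cell_ids)
  expect_equal(as.matrix(y$omics[[1]]$values), as.matrix(x$omics[[1]]$values),
               ignore_attr = TRUE, tolerance = 0)
})

test_that("mtx round-trip preserves the sparsity pattern exactly", {
  set.seed(5)
  m <- Matrix::rsparsematrix(20, 8, density = 0.2)
  m@x <- abs(m@x)
  x <- multi_omics(list(omic_matrix(m, name = "sp")))
  dir <- tempfile()
  write_multi_omics(x, dir, format = "mtx")
  y <- read_multi_omics(dir, format = "mtx")
  ms <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  my <- y$omics[[1]]$values
  expect_identical(my@i, ms@i)
  expect_identical(my@p, ms@p)
  expect_equal(my@x, ms@x, tolerance = 1e-12)
})

test_that("reader rejects misaligned omics and negative entries", {
  x <- random_dataset(2, v = 2, n = 8, d = c(5, 3))
  dir <- tempfile()
  write_multi_omics(x, dir, format = "mtx")
  # drop one barcode from the second omic
  bc <- file.path(dir, "om2", "barcodes.tsv")
  writeLines(readLines(bc)[-8], bc)
  mm <- readLines(file.path(dir, "om2", "matrix.mtx"))
  expect_error(read_multi_omics(dir, format = "mtx"), "match|align|cells")
  # negative entry in a csv is a validation error
  dir2 <- tempfile()
  write_multi_omics(random_dataset(3, v = 1, n = 4, d = 3), dir2,
                    format = "csv")
  f <- file.path(dir2, "om1.csv")
  tab <- utils::read.csv(f, check.names = FALSE)
  tab[1, 2] <- -1.0
  utils::write.csv(tab, f, row.names = FALSE)
  expect_error(read_multi_omics(dir2, format = "csv"), "negative")
})

test_that("rna_lognorm matches the closed form on a toy matrix", {
  # both cells have library size 2 = the median, so scaling is identity and
  # every count of 1 becomes log1p(1)
  m <- matrix(c(1, 1, 1, 1), 2, 2)
  x <- multi_omics(list(omic_matrix(m, name = "r", modality = "rna")))
  y <- preprocess_omics(x, "rna_lognorm", rescale = FALSE)
  expect_equal(as.matrix(y$omics[[1]]$values),
               matrix(log1p(1), 2, 2), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("preprocessing preserves shape and non-negativity; none is identity", {
  x <- random_dataset(7, v = 2, n = 9, d = c(6, 4))
  idn <- preprocess_omics(x, "none", rescale = FALSE)
  expect_equal(as.matrix(idn$omics[[1]]$values),
               as.matrix(x$omics[[1]]$values), tolerance = 0)
  for (rec in c("rna_lognorm", "adt_clr_clip", "atac_tfidf")) {
    y <- suppressMessages(preprocess_omics(x, rec))
    for (i in 1:2) {
      expect_equal(dim(y$omics[[i]]$values), dim(x$omics[[i]]$values))
      expect_gte(min(y$omics[[i]]$values), 0)
    }
  }
  expect_error(preprocess_omics(x, "bogus"), "unknown")
})

test_that("all-zero cell columns survive preprocessing with a warning", {
  m <- matrix(stats::runif(20, 1, 2), 4, 5)
  m[, 3] <- 0
  x <- multi_omics(list(omic_matrix(m, modality = "rna")))
  expect_warning(y <- preprocess_omics(x), "all-zero")
  expect_equal(ncol(y$omics[[1]]$values), 5L)
})
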