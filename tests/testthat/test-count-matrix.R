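test_that("count_matrix enforces its invariants", {
  m <- matrix(1:6, 3, 2, dimnames = list(c("a", "b", "a"), c("s1", "s2")))
  expect_error(count_matrix(m), "duplicate gene ID: a")
  m2 <- matrix(c(1, -1, 2, 3), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(count_matrix(m2), "non-negative integers")
  m3 <- matrix(c(1.5, 1, 2, 3), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(count_matrix(m3), "non-negative integers")
  # metadata rows are reordered to match column order
  meta <- data.frame(sample_id = c("s2", "s1"), timepoint_hr = c(1, 0),
                     condition = "x", replicate = 1:2)
  cm <- count_matrix(matrix(0:3, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2"))), meta)
  expect_equal(cm$sample_meta$sample_id, c("s1", "s2"))
  expect_equal(cm$sample_meta$timepoint_hr, c(0, 1))
})

test_that("TSV and MTX round trips reproduce the matrix exactly", {
  cm <- random_counts(30, 6, seed = 1)
  cm$sample_meta$timepoint_hr <- rep(c(0, 1, 3), each = 2)
  cm$sample_meta$condition <- "BMP4"
  cm$sample_meta$replicate <- rep(1:2, 3)
  d <- withr::local_tempdir()
  tsv <- file.path(d, "counts.tsv"); meta <- file.path(d, "samples.csv")
  write_count_matrix(cm, tsv, format = "tsv", meta = meta)
  back <- read_count_matrix(tsv, format = "tsv", meta = meta)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$sample_meta, cm$sample_meta)
  mtx <- file.path(d, "counts.mtx")
  write_count_matrix(cm, mtx, format = "mtx")
  back2 <- read_count_matrix(mtx, format = "mtx")
  expect_equal(back2$counts, cm$counts)
  expect_equal(back2$sample_meta$timepoint_hr, cm$sample_meta$timepoint_hr)
})

test_that("malformed inputs give parse errors naming the problem", {
  d <- withr::local_tempdir()
  p <- file.path(d, "dup.tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), p)
  expect_error(read_count_matrix(p), "line 3.*duplicate gene ID 'g1'")
  p2 <- file.path(d, "frac.tsv")
  writeLines(c("gene_id\ts1", "g1\t1.5"), p2)
  expect_error(read_count_matrix(p2), "line 2.*non-integer")
  # MTX with a coordinate outside the declared 3 x 2 shape
  p3 <- file.path(d, "bad.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 2", "1 1 5", "10 1 7"), p3)
  writeLines("gene_id\ng1\ng2\ng3", file.path(d, "genes.csv"))
  writeLines("sample_id\ns1\ns2", file.path(d, "samples.csv"))
  expect_error(read_count_matrix(p3, format = "mtx"), "parse error")
})

test_that("expression filters apply both rules in order and are idempotent", {
  cm <- toy_counts(rbind(c(0, 9, 5), c(12, 0, 0), c(40, 0, 0)),
                   genes = c("never10", "max12", "max40"))
  out <- suppressMessages(filter_low_expression(cm))
  expect_equal(out$gene_ids, "max40")
  expect_equal(unname(attr(out, "filter_log")),
               c(1, 1))  # one gene per rule
  for (seed in 1:3) {
    cm <- random_counts(200, 5, seed = seed, lambda = 25)
    once <- suppressMessages(filter_low_expression(cm))
    twice <- suppressMessages(filter_low_expression(once))
    expect_identical(twice$counts, once$counts)
  }
  tiny <- toy_counts(matrix(c(1, 1), 1, 2))
  expect_warning(suppressMessages(filter_low_expression(tiny)), "no genes pass")
})

test_that("median-ratio size factors match the closed form and DESeq2", {
  toy <- toy_counts(cbind(A = c(10, 20, 30), B = c(20, 40, 60)))
  sf <- size_factors_median_ratio(toy)
  expect_equal(round(unname(sf), 4), c(0.7071, 1.4142))
  # identical samples
  same <- toy_counts(cbind(A = c(5, 8, 13), B = c(5, 8, 13)))
  expect_equal(unname(size_factors_median_ratio(same)), c(1, 1))
  # all-zero gene is excluded from the reference set
  withzero <- toy_counts(rbind(c(10, 20), c(30, 60), c(0, 0)))
  without <- toy_counts(rbind(c(10, 20), c(30, 60)))
  expect_equal(unname(size_factors_median_ratio(withzero)),
               unname(size_factors_median_ratio(without)))
  # scaling equivariance: multiplying one sample by c scales its factor by c
  # relative to every other factor (factors are defined up to a common scale)
  cm <- random_counts(50, 4, seed = 3, lambda = 40)
  cm$counts <- cm$counts + 1  # all-positive toy
  sf0 <- size_factors_median_ratio(count_matrix(cm$counts))
  scaled <- cm$counts; scaled[, 2] <- scaled[, 2] * 3
  sf1 <- size_factors_median_ratio(count_matrix(scaled))
  expect_equal(unname((sf1[2] / sf1[-2]) / (sf0[2] / sf0[-2])), rep(3, 3))
  # no all-positive gene
  disjoint <- toy_counts(rbind(c(1, 0), c(0, 1)))
  expect_error(size_factors_median_ratio(disjoint), "normalization error")
  # independent implementation agrees (tolerance covers the even-sized
  # reference set, where the two middle ratios are interpolated
  # arithmetically here and geometrically in log space there)
  ds <- DESeq2::estimateSizeFactorsForMatrix(cm$counts)
  expect_equal(unname(size_factors_median_ratio(cm)), unname(ds), tolerance = 1e-4)
})

test_that("normalization divides exactly and size factors are idempotent on exact ratios", {
  cm <- toy_counts(cbind(A = c(20, 4), B = c(10, 2)))
  norm <- normalize_counts(cm, c(A = 2, B = 1))
  expect_equal(unname(norm$values[, "A"]), c(10, 2))
  expect_equal(unname(norm$values[, "B"]), c(10, 2))
  # log2 view of value 7 with pseudocount 1 is 3
  cm7 <- toy_counts(cbind(A = c(7, 7), B = c(7, 7)))
  expect_true(all(log2_values(normalize_counts(cm7, c(A = 1, B = 1))) == 3))
  # sf all 1: values equal counts
  expect_equal(normalize_counts(cm, c(A = 1, B = 1))$values, cm$counts)
  expect_error(normalize_counts(cm, c(A = 2)), "missing for sample")
  # exact-ratio toy: an already-normalized matrix has size factors all 1
  toy <- toy_counts(cbind(A = c(10, 20, 30), B = c(20, 40, 60)))
  sf <- size_factors_median_ratio(toy)
  renorm <- normalize_counts(toy, sf)$values
  geo <- exp(rowMeans(log(renorm)))
  sf2 <- apply(renorm / geo, 2, median)
  expect_equal(unname(sf2), c(1, 1))
})

test_that("variable-gene selection matches brute-force variance ranking", {
  cm <- random_counts(50, 8, seed = 11)
  norm <- unit_norm(cm)
  lv <- log2_values(norm)
  v <- apply(lv, 1, var)
  expected <- rownames(lv)[order(-v, rownames(lv))]
  expect_identical(select_variable_genes(norm, 50), expected)
  expect_identical(select_variable_genes(norm, 7), expected[1:7])
  # constant gene is never selected before a non-constant one
  m <- rbind(const = rep(5, 4), varies = c(1, 50, 3, 200))
  colnames(m) <- paste0("s", 1:4)
  norm2 <- unit_norm(count_matrix(m))
  expect_identical(select_variable_genes(norm2, 1), "varies")
  expect_error(select_variable_genes(norm2, 0), "positive")
  expect_error(select_variable_genes(norm2, 3), "exceeds")
})

test_that("sample PCA matches an SVD oracle up to the fixed sign convention", {
  cm <- random_counts(10, 6, seed = 21)
  norm <- unit_norm(cm)
  res <- pca_embed(norm, n_components = 4)
  # oracle: full SVD of the centered sample x gene matrix
  x <- scale(t(log2_values(norm)), center = TRUE, scale = FALSE)
  s <- svd(x)
  oracle_scores <- s$u %*% diag(s$d)
  for (j in 1:4) {
    ratio <- res$coordinates[, j] / oracle_scores[, j]
    expect_equal(abs(unname(ratio)), rep(1, 6), tolerance = 1e-8)
    # sign convention: largest-magnitude loading positive
    expect_gt(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
  }
  ve <- res$variance_explained
  expect_true(all(diff(ve) <= 1e-12))
  expect_lte(sum(ve), 1 + 1e-12)
  # identical samples get identical coordinates
  m <- cbind(s1 = c(1, 5, 9), s2 = c(1, 5, 9), s3 = c(7, 2, 4))
  rownames(m) <- paste0("g", 1:3)
  res2 <- pca_embed(unit_norm(count_matrix(m)), n_components = 2)
  expect_equal(res2$coordinates[1, ], res2$coordinates[2, ])
  one <- count_matrix(matrix(1:3, 3, 1, dimnames = list(paste0("g", 1:3), "s1")))
  expect_error(pca_embed(unit_norm(one), n_components = 1), "at least 2 samples")
})
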