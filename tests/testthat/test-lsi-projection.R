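test_that("IDF follows its formula at both support extremes", {
  m <- rbind(everywhere = c(5, 3, 8, 2),
             nowhere = c(0, 0, 0, 0),
             some = c(4, 0, 0, 0))
  colnames(m) <- paste0("c", 1:4)
  model <- fit_lsi(m, n_components = 2)
  n <- 4
  expect_equal(unname(model$idf["everywhere"]), log(1 + n / (1 + n)))
  expect_equal(unname(model$idf["nowhere"]), log(1 + n))
  expect_equal(unname(model$idf["some"]), log(1 + n / 2))
  expect_equal(unname(model$idf["everywhere"]), min(model$idf))
  # components are orthonormal
  expect_equal(crossprod(model$components), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
  # a cell with zero total is named
  m0 <- m; m0[, 2] <- 0
  expect_error(fit_lsi(m0, n_components = 2), "zero total.*c2")
})

test_that("re-transforming the reference reproduces its latent geometry", {
  lsi <- small_atlas_lsi()
  atlas <- small_atlas()$atlas
  coords <- suppressMessages(transform_lsi(lsi, atlas$counts))
  expect_equal(dim(coords), c(300, 20))
  d_ref <- dist(lsi$ref_coords)
  d_new <- dist(coords)
  expect_lt(max(abs(d_new - d_ref)) / max(d_ref), 1e-6)
  # singular values non-increasing
  expect_true(all(diff(lsi$singular_values) <= 1e-8))
  # a query equal to one reference cell lands on that cell's coordinates
  one <- atlas$counts[, 17, drop = FALSE]
  q <- suppressMessages(transform_lsi(lsi, one))
  expect_equal(unname(q[1, ]), unname(lsi$ref_coords[17, ]), tolerance = 1e-8)
  # TF scale-invariance: doubling a column changes nothing
  q2 <- suppressMessages(transform_lsi(lsi, one * 2))
  expect_equal(q2, q, tolerance = 1e-10)
  # zero gene overlap is an error
  alien <- matrix(5, 3, 1, dimnames = list(c("x1", "x2", "x3"), "q"))
  expect_error(suppressMessages(transform_lsi(lsi, alien)), "zero total")
})

test_that("pseudo-cell downsampling is multinomial at the requested depth", {
  set.seed(81)
  bulk <- setNames(rpois(2000, rexp(2000, 1 / 50)), sprintf("G%06d", 1:2000))
  pcs <- downsample_pseudocells(bulk, n_cells = 100, depth = 1e4, seed = 13)
  expect_true(all(colSums(pcs$counts) == 1e4))
  expect_equal(dim(pcs$counts), c(2000, 100))
  # deterministic per (seed, cell index)
  again <- downsample_pseudocells(bulk, n_cells = 100, depth = 1e4, seed = 13)
  expect_identical(pcs$counts, again$counts)
  shifted <- downsample_pseudocells(bulk, n_cells = 100, depth = 1e4, seed = 14)
  expect_identical(shifted$counts[, 1], pcs$counts[, 2])  # stream = seed + index
  # expectation: depth * bulk proportion; mean over cells tracks it closely
  prop <- bulk / sum(bulk)
  emp <- rowMeans(pcs$counts)
  expect_gt(cor(emp, prop), 0.99)
  big <- order(-prop)[1:10]
  expect_true(all(abs(emp[big] - 1e4 * prop[big]) / (1e4 * prop[big]) < 0.1))
  expect_error(downsample_pseudocells(bulk, depth = 0), "positive")
})

test_that("embedding transfer copies exact matches and averages equidistant ties", {
  ref_lsi <- rbind(c(0, 0), c(2, 0), c(10, 10))
  ref_emb <- rbind(c(-1, -1), c(5, 5), c(9, 9))
  # exact match in LSI space copies the embedding row
  q <- umap_transfer(ref_lsi, ref_emb, matrix(c(2, 0), 1), k_neighbors = 2)
  expect_equal(unname(q[1, ]), c(5, 5))
  # equidistant between two cells with k = 2: arithmetic mean
  q2 <- umap_transfer(ref_lsi, ref_emb, matrix(c(1, 0), 1), k_neighbors = 2)
  expect_equal(unname(q2[1, ]), c(2, 2))
  expect_error(umap_transfer(ref_lsi[0, ], ref_emb[0, ], matrix(0, 1, 2)),
               "empty")
  expect_error(umap_transfer(ref_lsi, ref_emb, matrix(0, 1, 2), k_neighbors = 9),
               "k_neighbors")
})

test_that("pseudo-cells from a cluster land near their own cluster center", {
  gen <- small_atlas()
  atlas <- gen$atlas
  lsi <- small_atlas_lsi()
  centers <- attr(atlas, "cluster_centers")
  bulk <- generate_bulk_from_cluster(atlas, "TBXTlow", 1, 1e6, seed = 21)
  pcs <- downsample_pseudocells(bulk$counts[, 1], n_cells = 100, depth = 2000,
                                seed = 23)
  q_lsi <- suppressMessages(transform_lsi(lsi, pcs$counts))
  q_emb <- umap_transfer(lsi$ref_coords, atlas$embedding, q_lsi)
  d_to <- function(pts, ctr) sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  own <- d_to(q_emb, centers["TBXTlow", ])
  others <- sapply(setdiff(rownames(centers), "TBXTlow"),
                   function(cl) d_to(q_emb, centers[cl, ]))
  expect_gte(mean(own < apply(others, 1, min)), 0.95)
})

test_that("medoid matches hand computation and the exhaustive oracle", {
  pts <- rbind(c(0, 0), c(1, 0), c(3, 0))
  med <- medoid(pts)
  expect_equal(med$index, 2L)
  expect_equal(unname(med$point), c(1, 0))
  single <- medoid(matrix(c(4, 7), 1))
  expect_equal(single$index, 1L)
  expect_equal(unname(single$point), c(4, 7))
  expect_error(medoid(matrix(0, 0, 2)), "empty")
  set.seed(91)
  for (i in 1:200) {
    n <- sample(2:100, 1)
    pts <- matrix(rnorm(2 * n), n, 2)
    expect_identical(medoid(pts)$index, medoid_oracle(pts))
  }
})

test_that("nearest reference cell matches a brute-force scan with tie-breaks", {
  atlas <- small_atlas()$atlas
  hit <- nearest_reference_cell(atlas, atlas$embedding[42, ])
  expect_equal(hit$cell_id, atlas$cell_ids[42])
  expect_equal(hit$distance, 0)
  two <- reference_atlas(
    matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("c1", "c2"))),
    c(c1 = "A", c2 = "B"),
    rbind(c1 = c(0, 0), c2 = c(10, 0)))
  hit2 <- nearest_reference_cell(two, c(1, 0))
  expect_equal(hit2$cell_id, "c1")
  expect_equal(hit2$distance, 1)
  set.seed(92)
  queries <- cbind(runif(1000, -5, 45), runif(1000, -3, 3))
  for (i in seq_len(nrow(queries))) {
    mine <- nearest_reference_cell(atlas, queries[i, ])
    oracle <- nearest_oracle(atlas$embedding, queries[i, ])
    expect_identical(mine$cell_id, atlas$cell_ids[oracle$index])
  }
})

test_that("end-to-end sample mapping is deterministic and tracks near-identity input", {
  gen <- small_atlas()
  atlas <- gen$atlas
  # a bulk that is an exact copy of one reference cell's counts
  cell <- 17
  counts <- atlas$counts[, cell, drop = FALSE]
  colnames(counts) <- "copycat"
  bulk <- count_matrix(counts)
  proj <- suppressMessages(map_samples_to_atlas(
    atlas, bulk, n_cells = 1, depth = sum(counts), seed = 31))
  expect_equal(proj$transferred_label, unname(atlas$labels[cell]))
  sep <- atlas_config(n_cells = 300, n_genes = 600, n_markers_per_cluster = 25,
                      cell_depth_mean = 2000, seed = 5)$cluster_separation
  centers <- attr(atlas, "cluster_centers")
  own <- centers[atlas$labels[cell], ]
  expect_lt(sqrt((proj$medoid_x - own[1])^2 + (proj$medoid_y - own[2])^2), sep)
  # determinism: identical inputs and seed give identical results
  proj2 <- suppressMessages(map_samples_to_atlas(
    atlas, bulk, n_cells = 1, depth = sum(counts), seed = 31))
  expect_identical(proj, proj2)
  # disjoint gene universes abort
  alien <- count_matrix(matrix(5L, 2, 1, dimnames = list(c("zz1", "zz2"), "q")))
  expect_error(map_samples_to_atlas(atlas, alien), "no gene overlap")
})
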