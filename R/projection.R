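#' Downsample a bulk profile into pseudo-single-cells
#'
#' Each pseudo-cell is an independent multinomial draw of `depth` reads over
#' the bulk gene proportions; the stream of pseudo-cell `i` is seeded with
#' `seed + i`, so cells are deterministic per (seed, cell index).
#'
#' @param bulk_column Named non-negative integer vector (one bulk sample).
#' @param n_cells Number of pseudo-cells (default 100).
#' @param depth Reads per pseudo-cell.
#' @param seed Integer base seed.
#' @param sample_id Optional source sample ID recorded with the set.
#' @return An object of class `pseudo_cell_set` with `counts`
#'   (gene x n_cells, each column summing to `depth`), `depth`, `seed`,
#'   `source_sample_id`.
#' @export
downsample_pseudocells <- function(bulk_column, n_cells = 100, depth, seed = 1,
                                   sample_id = NULL) {
  if (depth <= 0) stop("depth must be a positive integer")
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (is.null(names(bulk_column))) stop("bulk_column must be a named gene vector")
  if (sum(bulk_column) == 0) stop("bulk column has zero total counts")
  prob <- bulk_column / sum(bulk_column)
  counts <- matrix(0L, length(bulk_column), n_cells,
                   dimnames = list(names(bulk_column),
                                   sprintf("pc%03d", seq_len(n_cells))))
  for (i in seq_len(n_cells)) {
    set.seed(seed + i)
    counts[, i] <- stats::rmultinom(1, depth, prob)
  }
  structure(list(counts = counts, n_cells = n_cells, depth = depth,
                 seed = seed, source_sample_id = sample_id),
            class = "pseudo_cell_set")
}

#' Transfer query points into a reference 2-D embedding
#'
#' Each query point receives the inverse-distance-weighted average of its
#' `k_neighbors` nearest reference cells' embedding coordinates, with
#' distances measured in LSI space. An exact match (distance ~0) copies that
#' reference cell's coordinates.
#'
#' @param ref_lsi Reference cell x k LSI coordinates.
#' @param ref_embedding Reference cell x 2 embedding coordinates (same row
#'   order).
#' @param query_lsi Query m x k LSI coordinates.
#' @param k_neighbors Number of neighbors (default 15).
#' @return m x 2 matrix of transferred coordinates.
#' @export
umap_transfer <- function(ref_lsi, ref_embedding, query_lsi, k_neighbors = 15) {
  ref_lsi <- as.matrix(ref_lsi); query_lsi <- as.matrix(query_lsi)
  ref_embedding <- as.matrix(ref_embedding)
  if (nrow(ref_lsi) == 0) stop("reference is empty")
  if (nrow(ref_lsi) != nrow(ref_embedding))
    stop("ref_lsi and ref_embedding must have the same number of cells")
  if (k_neighbors > nrow(ref_lsi)) stop("k_neighbors exceeds the number of reference cells")
  # squared distances via the expansion |q - r|^2 = |q|^2 + |r|^2 - 2 q.r
  d2 <- outer(rowSums(query_lsi^2), rowSums(ref_lsi^2), "+") -
    2 * query_lsi %*% t(ref_lsi)
  d2[d2 < 0] <- 0
  out <- matrix(0, nrow(query_lsi), 2)
  rownames(out) <- rownames(query_lsi)
  colnames(out) <- colnames(ref_embedding)
  for (i in seq_len(nrow(query_lsi))) {
    nn <- order(d2[i, ])[seq_len(k_neighbors)]
    d <- sqrt(d2[i, nn])
    if (d[1] < 1e-10) {
      out[i, ] <- ref_embedding[nn[1], ]
    } else {
      w <- 1 / d
      out[i, ] <- colSums(ref_embedding[nn, , drop = FALSE] * w) / sum(w)
    }
  }
  out
}

#' Medoid of a 2-D point set
#'
#' The member point minimizing the sum of Euclidean distances to all members;
#' ties are broken by lowest index.
#'
#' @param points m x 2 numeric matrix, m >= 1.
#' @return List with `index` and `point` (length-2 vector).
#' @export
medoid <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("empty point set")
  if (nrow(points) == 1) return(list(index = 1L, point = points[1, ]))
  sums <- rowSums(as.matrix(stats::dist(points)))
  idx <- unname(which.min(sums))  # which.min takes the first minimum: lowest index
  list(index = idx, point = points[idx, ])
}

#' Nearest reference cell to a point in embedding space
#'
#' @param atlas A [reference_atlas()].
#' @param point Length-2 coordinate.
#' @return List with `cell_id`, `label`, `distance`; ties broken by lowest
#'   cell index.
#' @export
nearest_reference_cell <- function(atlas, point) {
  stopifnot(inherits(atlas, "reference_atlas"))
  emb <- atlas$embedding
  d <- sqrt((emb[, 1] - point[1])^2 + (emb[, 2] - point[2])^2)
  idx <- which.min(d)
  list(cell_id = atlas$cell_ids[idx],
       label = unname(atlas$labels[idx]),
       distance = unname(d[idx]))
}

#' Map bulk samples onto a single-cell reference atlas
#'
#' End-to-end transcriptomic-similarity assignment: each bulk sample is
#' downsampled to `n_cells` pseudo-single-cells, projected into the
#' reference LSI space, transferred into the reference 2-D embedding by
#' weighted k-nearest-neighbor interpolation, represented by the medoid of
#' its pseudo-cells, and assigned the identity of the most similar reference
#' cell by Euclidean distance in embedding space.
#'
#' @param atlas A [reference_atlas()]; an LSI model is fitted on the fly
#'   when `atlas$lsi` is NULL.
#' @param bulk A [count_matrix] of bulk samples.
#' @param n_cells Pseudo-cells per sample (default 100).
#' @param depth Reads per pseudo-cell; default = median reference per-cell
#'   total, so pseudo-cells are statistically comparable to reference cells.
#' @param n_components LSI dimensions when fitting (default 30).
#' @param k_neighbors Neighbors for the embedding transfer (default 15).
#' @param seed Integer seed; sample j uses base seed `seed + (j-1) * n_cells`.
#' @return A `projection_result` data.frame: `sample_id`, `medoid_x`,
#'   `medoid_y`, `nearest_cell_id`, `transferred_label`, `distance`, `seed`.
#'   Per-pseudo-cell transferred coordinates are kept in the
#'   `pseudo_coords` attribute for QC, and run parameters in `params`.
#' @export
map_samples_to_atlas <- function(atlas, bulk, n_cells = 100, depth = NULL,
                                 n_components = 30, k_neighbors = 15, seed = 1) {
  stopifnot(inherits(atlas, "reference_atlas"), inherits(bulk, "count_matrix"))
  if (length(intersect(atlas$gene_ids, bulk$gene_ids)) == 0)
    stop("no gene overlap between bulk and atlas")
  model <- atlas$lsi
  if (is.null(model)) model <- fit_lsi(atlas, n_components = n_components)
  if (is.null(depth)) depth <- round(stats::median(colSums(atlas$counts)))
  ref_coords <- model$ref_coords
  n <- length(bulk$sample_ids)
  res <- data.frame(sample_id = bulk$sample_ids,
                    medoid_x = NA_real_, medoid_y = NA_real_,
                    nearest_cell_id = NA_character_,
                    transferred_label = NA_character_,
                    distance = NA_real_, seed = seed,
                    stringsAsFactors = FALSE)
  qc <- vector("list", n)
  names(qc) <- bulk$sample_ids
  for (j in seq_len(n)) {
    sid <- bulk$sample_ids[j]
    step <- function(expr) tryCatch(expr, error = function(e)
      stop("sample '", sid, "': ", conditionMessage(e), call. = FALSE))
    pcs <- step(downsample_pseudocells(bulk$counts[, sid], n_cells = n_cells,
                                       depth = depth,
                                       seed = seed + (j - 1L) * n_cells,
                                       sample_id = sid))
    q_lsi <- step(suppressMessages(transform_lsi(model, pcs$counts)))
    q_emb <- step(umap_transfer(ref_coords, atlas$embedding, q_lsi, k_neighbors))
    med <- medoid(q_emb)
    hit <- nearest_reference_cell(atlas, med$point)
    res$medoid_x[j] <- med$point[1]
    res$medoid_y[j] <- med$point[2]
    res$nearest_cell_id[j] <- hit$cell_id
    res$transferred_label[j] <- hit$label
    res$distance[j] <- hit$distance
    qc[[j]] <- q_emb
  }
  class(res) <- c("projection_result", "data.frame")
  attr(res, "pseudo_coords") <- qc
  attr(res, "params") <- list(n_cells = n_cells, depth = depth,
                              n_components = n_components,
                              k_neighbors = k_neighbors, seed = seed)
  res
}

#' Read / write a reference atlas (MTX + CSV sidecars)
#'
#' Counts as Matrix Market coordinate integers, `genes.csv` (column
#' `gene_id`) and `cells.csv` (columns `cell_id,label,x,y`) in the same
#' directory.
#'
#' @param dir Directory holding `counts.mtx`, `genes.csv`, `cells.csv`.
#' @return A [reference_atlas()].
#' @export
read_reference_atlas <- function(dir) {
  mtx <- file.path(dir, "counts.mtx")
  gf <- file.path(dir, "genes.csv"); cf <- file.path(dir, "cells.csv")
  for (f in c(mtx, gf, cf)) if (!file.exists(f)) stop("atlas file not found: ", f)
  counts <- as.matrix(Matrix::readMM(mtx))
  genes <- utils::read.csv(gf, stringsAsFactors = FALSE)
  cells <- utils::read.csv(cf, stringsAsFactors = FALSE)
  rownames(counts) <- genes$gene_id
  colnames(counts) <- cells$cell_id
  emb <- as.matrix(cells[, c("x", "y")])
  rownames(emb) <- cells$cell_id
  reference_atlas(counts, stats::setNames(cells$label, cells$cell_id), emb)
}

#' @rdname read_reference_atlas
#' @param atlas A [reference_atlas()] to write.
#' @export
write_reference_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "reference_atlas"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(atlas$counts, sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  utils::write.csv(data.frame(gene_id = atlas$gene_ids),
                   file.path(dir, "genes.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(cell_id = atlas$cell_ids,
                              label = unname(atlas$labels),
                              x = atlas$embedding[, 1], y = atlas$embedding[, 2]),
                   file.path(dir, "cells.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}
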