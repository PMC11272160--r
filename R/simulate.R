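#' Time-course simulation configuration
#'
#' Design constants for the synthetic BMP4 time course: triplicate bulk
#' samples at 0, 0.5, 1, 3, 6, 12, 24 and 48 hr with genes activating in
#' planted temporal waves under negative-binomial noise (variance
#' `mu + dispersion * mu^2`) and per-sample log-normal library-size factors.
#'
#' @param timepoints_hr Sampling grid in hours, strictly increasing,
#'   starting at 0.
#' @param n_replicates Replicates per timepoint.
#' @param n_genes_total Total number of simulated genes.
#' @param n_genes_per_stage Named counts of genes planted per wave; the
#'   remainder are flat background genes.
#' @param activation_fold Multiplicative mean increase after onset (> 1).
#' @param baseline_mean_log_mu,baseline_mean_log_sigma Log-normal parameters
#'   of the per-gene baseline mean counts.
#' @param nb_dispersion NB dispersion alpha (0 gives Poisson noise).
#' @param libsize_log_sigma SD of per-sample log-normal size factors (mean 0
#'   in log space, so the expected geometric mean is 1).
#' @param onset_map Named onset hour per wave; every onset must be a grid
#'   timepoint.
#' @param activation_shape "step" switches the mean to baseline x fold at
#'   every timepoint >= onset; "sigmoid" ramps it logistically with
#'   half-activation at the onset hour.
#' @param seed Integer seed; identical configs reproduce identical data.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(timepoints_hr = c(0, 0.5, 1, 3, 6, 12, 24, 48),
                       n_replicates = 3,
                       n_genes_total = 2000,
                       n_genes_per_stage = c(immediate = 100, early = 100,
                                             `intermediate-1` = 100,
                                             `intermediate-2` = 100, late = 100),
                       activation_fold = 8,
                       baseline_mean_log_mu = log(100),
                       baseline_mean_log_sigma = 1,
                       nb_dispersion = 0.05,
                       libsize_log_sigma = 0.15,
                       onset_map = c(immediate = 1, early = 3,
                                     `intermediate-1` = 12,
                                     `intermediate-2` = 24, late = 48),
                       activation_shape = c("step", "sigmoid"),
                       seed = 1) {
  activation_shape <- match.arg(activation_shape)
  if (length(timepoints_hr) < 2 || any(diff(timepoints_hr) <= 0))
    stop("configuration error in timepoints_hr: must be strictly increasing")
  if (timepoints_hr[1] != 0)
    stop("configuration error in timepoints_hr: grid must start at 0")
  if (n_replicates < 1) stop("configuration error in n_replicates: must be >= 1")
  if (is.null(names(n_genes_per_stage)) || any(names(n_genes_per_stage) == ""))
    stop("configuration error in n_genes_per_stage: stage labels required")
  if (sum(n_genes_per_stage) > n_genes_total)
    stop("configuration error in n_genes_per_stage: staged genes exceed n_genes_total")
  if (!all(names(n_genes_per_stage) %in% names(onset_map)))
    stop("configuration error in onset_map: missing onset for stage(s) ",
         paste(setdiff(names(n_genes_per_stage), names(onset_map)), collapse = ", "))
  if (!all(onset_map %in% timepoints_hr))
    stop("configuration error in onset_map: onset hour(s) ",
         paste(onset_map[!onset_map %in% timepoints_hr], collapse = ", "),
         " not in timepoints_hr")
  if (activation_fold <= 1)
    stop("configuration error in activation_fold: must be > 1")
  if (nb_dispersion < 0)
    stop("configuration error in nb_dispersion: must be >= 0")
  if (libsize_log_sigma < 0)
    stop("configuration error in libsize_log_sigma: must be >= 0")
  structure(list(timepoints_hr = timepoints_hr, n_replicates = n_replicates,
                 n_genes_total = n_genes_total,
                 n_genes_per_stage = n_genes_per_stage,
                 activation_fold = activation_fold,
                 baseline_mean_log_mu = baseline_mean_log_mu,
                 baseline_mean_log_sigma = baseline_mean_log_sigma,
                 nb_dispersion = nb_dispersion,
                 libsize_log_sigma = libsize_log_sigma,
                 onset_map = onset_map,
                 activation_shape = activation_shape,
                 seed = as.integer(seed)),
            class = "sim_config")
}

rnb <- function(n, mu, dispersion) {
  if (dispersion == 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a time-course bulk count matrix with planted waves
#'
#' Each staged gene's NB mean is `baseline * activation_fold` at all
#' timepoints at or after its wave's onset hour and `baseline` before
#' (step shape); background genes stay at baseline throughout. Column sums
#' vary by drawn per-sample size factors.
#'
#' @param config A [sim_config].
#' @return List with `counts` (a [count_matrix]; sample metadata carries the
#'   timepoints) and `truth` (data.frame `gene_id,stage` covering every gene
#'   exactly once, with `background` for unstaged genes).
#' @export
generate_time_course <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes_total
  tps <- config$timepoints_hr
  nrep <- config$n_replicates
  gene_ids <- sprintf("G%06d", seq_len(G))
  stages <- rep("background", G)
  i <- 1L
  for (s in names(config$n_genes_per_stage)) {
    k <- config$n_genes_per_stage[[s]]
    if (k > 0) stages[i:(i + k - 1L)] <- s
    i <- i + k
  }
  baseline <- stats::rlnorm(G, config$baseline_mean_log_mu, config$baseline_mean_log_sigma)
  n_samples <- length(tps) * nrep
  sf <- stats::rlnorm(n_samples, 0, config$libsize_log_sigma)
  sample_tp <- rep(tps, each = nrep)
  sample_rep <- rep(seq_len(nrep), times = length(tps))
  sample_ids <- sprintf("t%ghr_r%d", sample_tp, sample_rep)

  # per-gene multiplicative activation profile over the grid
  fold_at <- function(stage, t) {
    if (stage == "background") return(1)
    onset <- config$onset_map[[stage]]
    if (config$activation_shape == "step") {
      if (t >= onset) config$activation_fold else 1
    } else {
      rate <- 4 / max(onset, 0.5)  # logistic ramp, half-activation at onset
      1 + (config$activation_fold - 1) / (1 + exp(-rate * (t - onset)))
    }
  }
  fold_mat <- matrix(1, G, length(tps))
  for (s in unique(stages)) {
    rows <- stages == s
    fold_mat[rows, ] <- matrix(vapply(tps, function(t) fold_at(s, t), 0),
                               nrow = sum(rows), ncol = length(tps), byrow = TRUE)
  }
  counts <- matrix(0, G, n_samples, dimnames = list(gene_ids, sample_ids))
  for (j in seq_len(n_samples)) {
    mu <- baseline * fold_mat[, match(sample_tp[j], tps)] * sf[j]
    counts[, j] <- rnb(G, mu, config$nb_dispersion)
  }
  meta <- data.frame(sample_id = sample_ids, timepoint_hr = sample_tp,
                     condition = "BMP4", replicate = sample_rep,
                     stringsAsFactors = FALSE)
  list(counts = count_matrix(counts, meta),
       truth = data.frame(gene_id = gene_ids, stage = stages,
                          stringsAsFactors = FALSE))
}

#' Synthetic single-cell atlas configuration
#'
#' Parameters of the synthetic annotated reference: clusters laid in order
#' along a 1-D differentiation trajectory in a latent 2-D embedding, each
#' cluster with its own exclusive marker genes on top of a shared baseline
#' program. Embedding coordinates are synthesized (cluster center + Gaussian
#' jitter), never fit.
#'
#' @param n_cells Total number of cells.
#' @param clusters Ordered cluster labels along the trajectory.
#' @param cells_per_cluster Named cell counts; defaults to an equal split
#'   (remainder to the last cluster). Must sum to `n_cells`.
#' @param cell_depth_mean Mean per-cell library size (reads).
#' @param cluster_separation Distance between adjacent cluster centers in the
#'   latent 2-D embedding.
#' @param within_cluster_sd Gaussian jitter SD around each center.
#' @param n_genes Number of genes in the atlas.
#' @param n_markers_per_cluster Cluster-exclusive marker genes per cluster
#'   (zero expression in all other clusters).
#' @param marker_mean Relative expression weight of a marker in its own
#'   cluster, on the scale of the shared baseline weights.
#' @param nb_dispersion NB dispersion of per-cell counts.
#' @param seed Integer seed.
#' @return An object of class `atlas_config`.
#' @export
atlas_config <- function(n_cells = 1500,
                         clusters = c("Epiblast", "PrimitiveStreak", "TBXTlow",
                                      "Amnion", "NascentMesoderm"),
                         cells_per_cluster = NULL,
                         cell_depth_mean = 5000,
                         cluster_separation = 10,
                         within_cluster_sd = 0.5,
                         n_genes = 2000,
                         n_markers_per_cluster = 50,
                         marker_mean = 20,
                         nb_dispersion = 0.3,
                         seed = 1) {
  if (anyDuplicated(clusters)) stop("configuration error in clusters: labels must be unique")
  if (is.null(cells_per_cluster)) {
    k <- length(clusters)
    base <- n_cells %/% k
    cells_per_cluster <- stats::setNames(rep(base, k), clusters)
    cells_per_cluster[k] <- n_cells - base * (k - 1)
  }
  if (!setequal(names(cells_per_cluster), clusters) ||
      sum(cells_per_cluster) != n_cells)
    stop("configuration error in cells_per_cluster: sizes must cover every cluster and sum to n_cells")
  if (cluster_separation <= 0)
    stop("configuration error in cluster_separation: must be > 0")
  if (within_cluster_sd <= 0)
    stop("configuration error in within_cluster_sd: must be > 0")
  if (n_markers_per_cluster * length(clusters) >= n_genes)
    stop("configuration error in n_markers_per_cluster: markers exceed n_genes")
  structure(list(n_cells = n_cells, clusters = clusters,
                 cells_per_cluster = cells_per_cluster[clusters],
                 cell_depth_mean = cell_depth_mean,
                 cluster_separation = cluster_separation,
                 within_cluster_sd = within_cluster_sd,
                 n_genes = n_genes,
                 n_markers_per_cluster = n_markers_per_cluster,
                 marker_mean = marker_mean,
                 nb_dispersion = nb_dispersion,
                 seed = as.integer(seed)),
            class = "atlas_config")
}

#' Annotated reference atlas container
#'
#' @param counts Gene x cell matrix of non-negative integers.
#' @param labels Named character vector: cell ID -> cluster label.
#' @param embedding Cell x 2 numeric matrix of 2-D coordinates, rownames =
#'   cell IDs.
#' @param lsi Optional fitted [fit_lsi()] model.
#' @return An object of class `reference_atlas`.
#' @export
reference_atlas <- function(counts, labels, embedding, lsi = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("atlas counts must have gene rownames and cell colnames")
  cells <- colnames(counts)
  if (!setequal(names(labels), cells))
    stop("labels must be defined for every cell")
  if (!setequal(rownames(embedding), cells) || ncol(embedding) != 2)
    stop("embedding must be a cell x 2 matrix covering every cell")
  structure(list(counts = counts,
                 gene_ids = rownames(counts),
                 cell_ids = cells,
                 labels = labels[cells],
                 embedding = embedding[cells, , drop = FALSE],
                 lsi = lsi),
            class = "reference_atlas")
}

#' @exportS3Method base::print
print.reference_atlas <- function(x, ...) {
  cat("reference_atlas:", length(x$gene_ids), "genes x", length(x$cell_ids), "cells\n")
  print(table(x$labels))
  invisible(x)
}

#' Simulate an annotated single-cell reference atlas
#'
#' Per-cell counts are drawn NB around cluster-specific mean programs
#' (shared log-normal baseline plus cluster-exclusive markers); embedding
#' coordinates are the cluster center on a line (spacing
#' `cluster_separation`) plus Gaussian jitter, so no embedding algorithm is
#' required.
#'
#' @param config An [atlas_config].
#' @return List with `atlas` (a [reference_atlas]) and `truth` (data.frame
#'   `cell_id,cluster`).
#' @export
generate_reference_atlas <- function(config) {
  stopifnot(inherits(config, "atlas_config"))
  set.seed(config$seed)
  G <- config$n_genes
  K <- length(config$clusters)
  nm <- config$n_markers_per_cluster
  gene_ids <- sprintf("G%06d", seq_len(G))
  # program weights: rows genes, cols clusters
  base_w <- stats::rlnorm(G, log(1), 1)
  base_w[seq_len(K * nm)] <- 0  # marker slots start silent everywhere
  prog <- matrix(base_w, G, K, dimnames = list(gene_ids, config$clusters))
  for (k in seq_len(K)) {
    rows <- ((k - 1) * nm + 1):(k * nm)
    prog[rows, k] <- config$marker_mean
  }
  cell_cluster <- rep(config$clusters, times = config$cells_per_cluster)
  n_cells <- length(cell_cluster)
  cell_ids <- sprintf("C%05d", seq_len(n_cells))
  depth <- stats::rlnorm(n_cells, log(config$cell_depth_mean), 0.2)
  counts <- matrix(0, G, n_cells, dimnames = list(gene_ids, cell_ids))
  for (j in seq_len(n_cells)) {
    p <- prog[, cell_cluster[j]]
    mu <- p / sum(p) * depth[j]
    counts[, j] <- rnb(G, mu, config$nb_dispersion)
  }
  centers <- cbind(x = (seq_len(K) - 1) * config$cluster_separation, y = 0)
  rownames(centers) <- config$clusters
  embedding <- centers[cell_cluster, , drop = FALSE] +
    matrix(stats::rnorm(2 * n_cells, 0, config$within_cluster_sd), n_cells, 2)
  rownames(embedding) <- cell_ids
  colnames(embedding) <- c("x", "y")
  labels <- stats::setNames(cell_cluster, cell_ids)
  atlas <- reference_atlas(counts, labels, embedding)
  attr(atlas, "cluster_centers") <- centers
  list(atlas = atlas,
       truth = data.frame(cell_id = cell_ids, cluster = cell_cluster,
                          stringsAsFactors = FALSE))
}

#' Synthesize bulk samples from one atlas cluster
#'
#' Each sample is an independent multinomial draw of `depth` reads over the
#' cluster's pooled gene proportions; the source cluster is recorded in the
#' sample metadata `condition` column.
#'
#' @param atlas A [reference_atlas].
#' @param cluster Cluster label present in the atlas.
#' @param n_samples Number of bulk samples.
#' @param depth Reads per sample.
#' @param seed Integer seed.
#' @return A [count_matrix] whose columns each sum to exactly `depth`.
#' @export
generate_bulk_from_cluster <- function(atlas, cluster, n_samples, depth, seed = 1) {
  stopifnot(inherits(atlas, "reference_atlas"))
  if (!cluster %in% atlas$labels)
    stop("unknown cluster: ", cluster)
  set.seed(seed)
  pooled <- rowSums(atlas$counts[, atlas$labels == cluster, drop = FALSE])
  prob <- pooled / sum(pooled)
  counts <- stats::rmultinom(n_samples, depth, prob)
  rownames(counts) <- atlas$gene_ids
  colnames(counts) <- sprintf("%s_bulk%02d", cluster, seq_len(n_samples))
  meta <- data.frame(sample_id = colnames(counts), timepoint_hr = NA_real_,
                     condition = cluster, replicate = seq_len(n_samples),
                     stringsAsFactors = FALSE)
  count_matrix(counts, meta)
}
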