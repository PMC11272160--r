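# Shared fixtures and independent oracles. Heavy simulated objects are
# memoized so one test_dir() run generates them once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

toy_counts <- function(mat, genes = NULL, samples = NULL, meta = NULL) {
  if (is.null(genes))
    genes <- if (is.null(rownames(mat))) sprintf("g%02d", seq_len(nrow(mat)))
             else rownames(mat)
  if (is.null(samples))
    samples <- if (is.null(colnames(mat))) sprintf("s%02d", seq_len(ncol(mat)))
               else colnames(mat)
  dimnames(mat) <- list(genes, samples)
  count_matrix(mat, meta)
}

random_counts <- function(n_genes, n_samples, seed, lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples)
  toy_counts(m)
}

# norm_matrix with size factors 1 (values = counts), for exact arithmetic
unit_norm <- function(cm) normalize_counts(cm, setNames(rep(1, length(cm$sample_ids)),
                                                        cm$sample_ids))

# --- independent oracles -----------------------------------------------------

# literal BH step-up definition: q_i = min over j with p_(j) >= p_(i) of
# p_(j) * n / j, clipped at 1 (O(n^2), no cummin shortcut)
bh_oracle <- function(p) {
  n <- length(p)
  ps <- sort(p)
  cand <- ps * n / seq_len(n)
  vapply(p, function(pi) min(1, min(cand[ps >= pi])), 0)
}

# exhaustive medoid: explicit double loop over the distance sums
medoid_oracle <- function(points) {
  m <- nrow(points)
  sums <- numeric(m)
  for (i in seq_len(m))
    for (j in seq_len(m))
      sums[i] <- sums[i] + sqrt(sum((points[i, ] - points[j, ])^2))
  which.min(sums)
}

# brute-force nearest neighbour scan
nearest_oracle <- function(embedding, point) {
  best <- 1L; bestd <- Inf
  for (i in seq_len(nrow(embedding))) {
    d <- sqrt(sum((embedding[i, ] - point)^2))
    if (d < bestd) { bestd <- d; best <- i }
  }
  list(index = best, distance = bestd)
}

# --- memoized simulated objects ---------------------------------------------

default_time_course <- function() cached("tc", generate_time_course(sim_config(seed = 101)))

default_cascade <- function() cached("cascade", {
  sim <- default_time_course()
  filt <- suppressMessages(filter_low_expression(sim$counts))
  norm <- normalize_counts(filt)
  contrasts <- consecutive_contrasts(norm)
  list(sim = sim, norm = norm, contrasts = contrasts,
       assignment = assign_stages(contrasts))
})

# small atlas for unit tests (cheap SVD), full atlas for acceptance checks
small_atlas <- function() cached("small_atlas",
  generate_reference_atlas(atlas_config(n_cells = 300, n_genes = 600,
                                        n_markers_per_cluster = 25,
                                        cell_depth_mean = 2000, seed = 5)))

small_atlas_lsi <- function() cached("small_lsi", fit_lsi(small_atlas()$atlas, n_components = 20))

full_atlas <- function() cached("full_atlas",
  generate_reference_atlas(atlas_config(seed = 7)))

full_projection <- function() cached("full_proj", {
  atlas <- full_atlas()$atlas
  clusters <- unique(atlas$labels)
  mats <- lapply(seq_along(clusters), function(i)
    generate_bulk_from_cluster(atlas, clusters[i], 4, 1e6, seed = 300 + i))
  bulk <- count_matrix(do.call(cbind, lapply(mats, `[[`, "counts")),
                       do.call(rbind, lapply(mats, `[[`, "sample_meta")))
  proj <- suppressMessages(map_samples_to_atlas(atlas, bulk, seed = 42))
  list(bulk = bulk, proj = proj)
})
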