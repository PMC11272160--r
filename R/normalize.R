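#' Remove genes below the detection filters
#'
#' Two filters applied in order: (1) drop genes where no sample reaches
#' `min_any_sample` reads; (2) drop genes whose maximum count across samples
#' is less than or equal to `max_le`. Counts of removed genes are reported
#' via `message()` and stored in the `filter_log` attribute.
#'
#' @param x A [count_matrix].
#' @param min_any_sample Keep a gene only if at least one sample has this
#'   many reads (default 10).
#' @param max_le Drop genes whose maximum count is `<= max_le` (default 30).
#' @return A filtered [count_matrix]; empty results trigger a warning.
#' @export
filter_low_expression <- function(x, min_any_sample = 10, max_le = 30) {
  stopifnot(inherits(x, "count_matrix"))
  mx <- apply(x$counts, 1, max)
  keep1 <- mx >= min_any_sample
  n_removed1 <- sum(!keep1)
  mx2 <- mx[keep1]
  keep2 <- mx2 > max_le
  n_removed2 <- sum(!keep2)
  genes <- x$gene_ids[keep1][keep2]
  message("filter_low_expression: removed ", n_removed1, " genes with all samples < ",
          min_any_sample, " reads, then ", n_removed2, " genes with max <= ", max_le)
  if (length(genes) == 0) warning("no genes pass the expression filters")
  out <- count_matrix(x$counts[genes, , drop = FALSE], x$sample_meta)
  attr(out, "filter_log") <- c(removed_below_min = n_removed1, removed_max_le = n_removed2)
  out
}

#' Median-of-ratios size factors
#'
#' DESeq2-style normalization: the reference expression of each gene is its
#' geometric mean over samples, computed only for genes with strictly
#' positive counts in every sample; the size factor of a sample is the median
#' over those genes of count / reference.
#'
#' @param x A [count_matrix].
#' @return Named numeric vector of strictly positive size factors, one per
#'   sample.
#' @export
size_factors_median_ratio <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  counts <- x$counts
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos))
    stop("normalization error: no gene has positive counts in every sample; ",
         "pre-filter low-expression genes or check the input")
  logc <- log(counts[all_pos, , drop = FALSE])
  loggeo <- rowMeans(logc)  # log geometric mean, stable in log space
  sf <- apply(exp(logc - loggeo), 2, stats::median)
  names(sf) <- x$sample_ids
  sf
}

#' Normalized expression matrix
#'
#' Divides each sample's counts by its size factor. A log2 view with a
#' pseudocount is available through [log2_values()].
#'
#' @param x A [count_matrix].
#' @param sf Named size factors covering every sample; computed with
#'   [size_factors_median_ratio()] when omitted.
#' @return An object of class `norm_matrix` with fields `values` (gene x
#'   sample floats), `size_factors` and `sample_meta`.
#' @export
normalize_counts <- function(x, sf = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(sf)) sf <- size_factors_median_ratio(x)
  missing <- setdiff(x$sample_ids, names(sf))
  if (length(missing) > 0)
    stop("size factors missing for sample(s): ", paste(missing, collapse = ", "))
  if (any(sf[x$sample_ids] <= 0)) stop("size factors must be strictly positive")
  values <- sweep(x$counts, 2, sf[x$sample_ids], "/")
  structure(list(values = values,
                 gene_ids = x$gene_ids,
                 sample_ids = x$sample_ids,
                 size_factors = sf[x$sample_ids],
                 sample_meta = x$sample_meta),
            class = "norm_matrix")
}

#' @exportS3Method base::print
print.norm_matrix <- function(x, ...) {
  cat("norm_matrix:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  invisible(x)
}

#' Log2 view of a normalized matrix
#'
#' @param norm A `norm_matrix`.
#' @param pseudocount Added before the log (default 1, so zeros stay 0).
#' @return Gene x sample matrix of `log2(value + pseudocount)`.
#' @export
log2_values <- function(norm, pseudocount = 1) {
  stopifnot(inherits(norm, "norm_matrix"))
  log2(norm$values + pseudocount)
}

#' Most variable genes
#'
#' Ranks genes by the variance of their log2 normalized values across
#' samples, descending; ties are broken by gene ID in lexicographic order.
#'
#' @param norm A `norm_matrix`.
#' @param n Number of genes to return.
#' @return Character vector of `n` gene IDs.
#' @export
select_variable_genes <- function(norm, n) {
  stopifnot(inherits(norm, "norm_matrix"))
  if (n <= 0) stop("n must be a positive integer")
  if (n > length(norm$gene_ids)) stop("n exceeds the number of genes")
  lv <- log2_values(norm)
  v <- apply(lv, 1, stats::var)
  ord <- order(-v, norm$gene_ids)
  norm$gene_ids[ord][seq_len(n)]
}

#' PCA of samples on selected genes
#'
#' Principal component analysis of samples (observations) on gene-centered
#' log2 normalized values. Signs are fixed so that within each component the
#' largest-magnitude gene loading is positive.
#'
#' @param norm A `norm_matrix`.
#' @param genes Genes to use (subset of the matrix genes).
#' @param n_components Number of components to return.
#' @return List with `coordinates` (sample x component matrix),
#'   `variance_explained` (non-increasing fractions) and `loadings`
#'   (gene x component).
#' @export
pca_embed <- function(norm, genes = NULL, n_components = 2) {
  stopifnot(inherits(norm, "norm_matrix"))
  if (is.null(genes)) genes <- norm$gene_ids
  if (!all(genes %in% norm$gene_ids))
    stop("unknown gene(s): ", paste(setdiff(genes, norm$gene_ids)[1:5], collapse = ", "))
  lv <- log2_values(norm)[genes, , drop = FALSE]
  n_samp <- ncol(lv)
  if (n_samp < 2) stop("PCA requires at least 2 samples")
  if (n_components > min(length(genes), n_samp))
    stop("n_components exceeds min(#genes, #samples)")
  pc <- stats::prcomp(t(lv), center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  rot <- pc$rotation[, k, drop = FALSE]
  scores <- pc$x[, k, drop = FALSE]
  for (j in k) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  total_var <- sum(pc$sdev^2)
  list(coordinates = scores,
       variance_explained = pc$sdev[k]^2 / total_var,
       loadings = rot)
}
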