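#' Fit a TF-IDF / LSI model on a reference atlas
#'
#' Latent semantic indexing of the reference counts: term frequency
#' `TF[g,c] = count / column total`, inverse document frequency
#' `IDF[g] = log(1 + n_cells / (1 + n cells expressing g))`,
#' `X = log1p(TF * IDF * scale_constant)`, then a truncated SVD of the
#' cell x gene matrix `t(X) = U D V'`. The right-singular vectors `V`
#' (gene x k) are the components; reference cells embed at `U D = t(X) V`.
#' By convention the first component may carry library-depth signal in
#' chromatin data and can be dropped with `drop_first`; it is kept by
#' default.
#'
#' @param atlas A [reference_atlas()] (or a gene x cell count matrix).
#' @param n_components Number of latent dimensions k (default 30).
#' @param scale_constant TF-IDF scaling before `log1p` (default 1e4).
#' @param drop_first Drop the first component after fitting (default FALSE).
#' @return An object of class `lsi_model` with fields `gene_ids`, `idf`,
#'   `components` (gene x k, orthonormal), `singular_values` (non-increasing),
#'   `scale_constant`, `n_components`, and `ref_coords` (cell x k embedding of
#'   the reference).
#' @export
fit_lsi <- function(atlas, n_components = 30, scale_constant = 1e4,
                    drop_first = FALSE) {
  counts <- if (inherits(atlas, "reference_atlas")) atlas$counts else as.matrix(atlas)
  if (length(counts) == 0) stop("atlas counts are empty")
  n_cells <- ncol(counts)
  if (n_components > min(nrow(counts), n_cells))
    stop("n_components exceeds min(#genes, #cells)")
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("cell(s) with zero total counts: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  idf <- log(1 + n_cells / (1 + rowSums(counts > 0)))
  tf <- sweep(counts, 2, totals, "/")
  x <- log1p(tf * idf * scale_constant)
  k_fit <- if (drop_first) n_components + 1 else n_components
  s <- svd(t(x), nu = k_fit, nv = k_fit)
  keep <- if (drop_first) 2:k_fit else 1:k_fit
  components <- s$v[, keep, drop = FALSE]
  rownames(components) <- rownames(counts)
  ref_coords <- s$u[, keep, drop = FALSE] %*% diag(s$d[keep], length(keep))
  rownames(ref_coords) <- colnames(counts)
  structure(list(gene_ids = rownames(counts),
                 idf = stats::setNames(idf, rownames(counts)),
                 components = components,
                 singular_values = s$d[keep],
                 scale_constant = scale_constant,
                 n_components = n_components,
                 drop_first = drop_first,
                 ref_coords = ref_coords),
            class = "lsi_model")
}

#' @exportS3Method base::print
print.lsi_model <- function(x, ...) {
  cat("lsi_model:", length(x$gene_ids), "genes,", x$n_components, "components\n")
  cat("singular values:", paste(signif(utils::head(x$singular_values, 5), 4),
                                collapse = ", "),
      if (length(x$singular_values) > 5) "..." else "", "\n")
  invisible(x)
}

#' Project query count profiles into a fitted LSI space
#'
#' Builds the query TF-IDF with the model's IDF and scale constant and
#' projects onto the model components. Query genes are reconciled with the
#' model's feature order: genes absent from the query are zero-filled, extra
#' query genes are dropped, and both counts are reported via `message()`.
#' Because TF divides by the column total, the coordinates are invariant to
#' rescaling a query column.
#'
#' @param model An `lsi_model`.
#' @param counts Gene x m count matrix with gene rownames.
#' @return m x k coordinate matrix.
#' @export
transform_lsi <- function(model, counts) {
  stopifnot(inherits(model, "lsi_model"))
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("query counts must have gene rownames")
  common <- intersect(model$gene_ids, rownames(counts))
  dropped <- setdiff(rownames(counts), model$gene_ids)
  filled <- setdiff(model$gene_ids, rownames(counts))
  if (length(dropped) > 0 || length(filled) > 0)
    message("transform_lsi: dropped ", length(dropped),
            " query genes absent from the model; zero-filled ", length(filled))
  q <- matrix(0, length(model$gene_ids), ncol(counts),
              dimnames = list(model$gene_ids, colnames(counts)))
  q[common, ] <- counts[common, , drop = FALSE]
  totals <- colSums(q)
  if (any(totals == 0))
    stop("query column(s) with zero total after gene reconciliation: ",
         paste(which(totals == 0), collapse = ", "))
  tf <- sweep(q, 2, totals, "/")
  x <- log1p(tf * model$idf * model$scale_constant)
  coords <- t(x) %*% model$components
  rownames(coords) <- colnames(counts)
  coords
}

#' @export
predict.lsi_model <- function(object, newdata, ...) transform_lsi(object, newdata)
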