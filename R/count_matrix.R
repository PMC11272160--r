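#' Count matrix with sample metadata
#'
#' Container for a gene x sample matrix of non-negative integer read counts,
#' plus per-sample metadata (timepoint in hours, condition, replicate).
#' Genes are always rows and samples always columns.
#'
#' @param counts Integer matrix with unique rownames (gene IDs) and unique
#'   colnames (sample IDs); all entries must be non-negative integers.
#' @param sample_meta Optional data.frame with columns `sample_id`,
#'   `timepoint_hr` (numeric, may be NA), `condition` (character) and
#'   `replicate` (integer). Defaults to a skeleton with NA timepoints.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, sample_meta = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ID: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ID: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample_id = colnames(counts),
                              timepoint_hr = NA_real_,
                              condition = NA_character_,
                              replicate = NA_integer_,
                              stringsAsFactors = FALSE)
  }
  if (!all(c("sample_id") %in% names(sample_meta)))
    stop("sample_meta must contain a sample_id column")
  for (col in c("timepoint_hr", "condition", "replicate"))
    if (is.null(sample_meta[[col]])) sample_meta[[col]] <- NA
  sample_meta$timepoint_hr <- as.numeric(sample_meta$timepoint_hr)
  sample_meta$replicate <- as.integer(sample_meta$replicate)
  if (!setequal(sample_meta$sample_id, colnames(counts)))
    stop("sample_meta sample_id set must match counts columns")
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample_id), , drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(list(counts = counts,
                 gene_ids = rownames(counts),
                 sample_ids = colnames(counts),
                 sample_meta = sample_meta),
            class = "count_matrix")
}

#' @exportS3Method base::print
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  tp <- x$sample_meta$timepoint_hr
  if (!all(is.na(tp)))
    cat("timepoints (hr):", paste(sort(unique(tp[!is.na(tp)])), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix from TSV or Matrix Market files
#'
#' TSV layout: first column `gene_id`, remaining columns one per sample.
#' MTX layout: a Matrix Market coordinate integer file plus `genes.csv`
#' (column `gene_id`) and `samples.csv` (column `sample_id`, optionally
#' `timepoint_hr`, `condition`, `replicate`) sidecars in the same directory.
#' Sample metadata for TSV input is read from `meta` when given.
#'
#' @param path Path to the TSV or `.mtx` file.
#' @param format Either "tsv" or "mtx".
#' @param meta Optional path to a sample-metadata CSV with columns
#'   `sample_id,timepoint_hr,condition,replicate`.
#' @return A [count_matrix].
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx"), meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(df)[1] != "gene_id")
      stop("parse error at line 1: first column must be 'gene_id', got '", names(df)[1], "'")
    dup <- duplicated(df$gene_id)
    if (any(dup))
      stop("parse error at line ", which(dup)[1] + 1L,
           ": duplicate gene ID '", df$gene_id[which(dup)[1]], "'")
    m <- as.matrix(df[, -1, drop = FALSE])
    bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop("parse error at line ", bad[1, 1] + 1L, ": non-integer or negative count for gene '",
           df$gene_id[bad[1, 1]], "'")
    rownames(m) <- df$gene_id
  } else {
    m <- tryCatch(as.matrix(Matrix::readMM(path)),
                  error = function(e) stop("parse error in MTX file '", path, "': ",
                                           conditionMessage(e)))
    dir <- dirname(path)
    gf <- file.path(dir, "genes.csv"); sf <- file.path(dir, "samples.csv")
    if (!file.exists(gf) || !file.exists(sf))
      stop("MTX input requires genes.csv and samples.csv sidecars in ", dir)
    genes <- utils::read.csv(gf, stringsAsFactors = FALSE)
    samples <- utils::read.csv(sf, stringsAsFactors = FALSE)
    if (nrow(genes) != nrow(m) || nrow(samples) != ncol(m))
      stop("parse error: sidecar dimensions (", nrow(genes), " genes, ", nrow(samples),
           " samples) do not match MTX shape ", nrow(m), " x ", ncol(m))
    rownames(m) <- genes$gene_id
    colnames(m) <- samples$sample_id
    if (is.null(meta) && ncol(samples) > 1) return(count_matrix(m, samples))
  }
  md <- NULL
  if (!is.null(meta)) {
    if (!file.exists(meta)) stop("metadata file not found: ", meta)
    md <- utils::read.csv(meta, stringsAsFactors = FALSE)
  }
  count_matrix(m, md)
}

#' Write a count matrix to TSV or Matrix Market files
#'
#' @param x A [count_matrix].
#' @param path Output path (TSV file or `.mtx` file; MTX sidecars
#'   `genes.csv`/`samples.csv` are written next to it).
#' @param format Either "tsv" or "mtx".
#' @param meta Optional path for the sample-metadata CSV (TSV format only;
#'   MTX always embeds metadata in `samples.csv`).
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, format = c("tsv", "mtx"), meta = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(gene_id = x$gene_ids, x$counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(meta))
      utils::write.csv(x$sample_meta, meta, row.names = FALSE, quote = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), path)
    dir <- dirname(path)
    utils::write.csv(data.frame(gene_id = x$gene_ids), file.path(dir, "genes.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(x$sample_meta, file.path(dir, "samples.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
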