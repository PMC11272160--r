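#' Temporal wave map
#'
#' Ordered map from wave label to the set of timepoints (hours) whose
#' consecutive-contrast significance first defines that wave. The default
#' follows the sampled grid: a gene first significantly upregulated by 0.5 or
#' 1 hr is `immediate`, by 3 or 6 hr `early`, by 12 hr `intermediate-1`, by
#' 24 hr `intermediate-2`, and by 48 hr `late`.
#'
#' @param map Named list, wave label -> numeric vector of timepoints (hours).
#'   Sets must be disjoint and ordered along the time axis.
#' @return An object of class `stage_map`.
#' @export
stage_map <- function(map = list(immediate = c(0.5, 1), early = c(3, 6),
                                 `intermediate-1` = 12, `intermediate-2` = 24,
                                 late = 48)) {
  tps <- unlist(map, use.names = FALSE)
  if (anyDuplicated(tps))
    stop("configuration error in stage_map: timepoint sets must be disjoint")
  if (any(tps <= 0))
    stop("configuration error in stage_map: only non-zero timepoints define waves")
  if (is.unsorted(tps))
    stop("configuration error in stage_map: wave order must follow the time axis")
  structure(map, class = "stage_map")
}

#' Consecutive-timepoint differential expression
#'
#' One [de_test()] per adjacent timepoint pair in temporal order, with the
#' later timepoint as group B (so positive fold change = upregulation over
#' the previous timepoint). On the default 8-point grid this yields the
#' contrasts 0 to 0.5, 0.5 to 1, 1 to 3, 3 to 6, 6 to 12, 12 to 24, 24 to 48 hr.
#'
#' @param norm A `norm_matrix` whose sample metadata carries `timepoint_hr`.
#' @param th A [de_thresholds] (stored with the result for downstream use).
#' @return List of `de_table` objects, one per contrast, named
#'   `"<t_prev>-><t_next>"`; each carries a `timepoint_later` attribute.
#' @export
consecutive_contrasts <- function(norm, th = de_thresholds()) {
  stopifnot(inherits(norm, "norm_matrix"))
  meta <- norm$sample_meta
  if (all(is.na(meta$timepoint_hr)))
    stop("sample metadata carries no timepoints")
  tps <- sort(unique(meta$timepoint_hr[!is.na(meta$timepoint_hr)]))
  if (length(tps) < 2) stop("need at least 2 timepoints")
  groups <- lapply(tps, function(t) meta$sample_id[!is.na(meta$timepoint_hr) &
                                                     meta$timepoint_hr == t])
  sizes <- lengths(groups)
  if (any(sizes < 2))
    stop("timepoint(s) with fewer than 2 replicates: ",
         paste(tps[sizes < 2], collapse = ", "))
  out <- vector("list", length(tps) - 1)
  names(out) <- sprintf("%g->%g", tps[-length(tps)], tps[-1])
  for (i in seq_along(out)) {
    tab <- de_test(norm, groups[[i]], groups[[i + 1]],
                   contrast = names(out)[i])
    attr(tab, "timepoint_later") <- tps[i + 1]
    out[[i]] <- tab
  }
  attr(out, "thresholds") <- th
  out
}

#' Assign genes to temporal activation waves
#'
#' For each gene, finds the earliest consecutive contrast whose later
#' timepoint shows significant upregulation (`fdr < fdr_max`,
#' `log2_fc > log2(min_abs_fold)`), then maps that timepoint to a wave label
#' through the [stage_map()]. Genes never significant are `unassigned`.
#'
#' @param contrasts Ordered list of `de_table`s from [consecutive_contrasts()],
#'   sharing one gene universe.
#' @param smap A [stage_map()].
#' @param th A [de_thresholds].
#' @return A `stage_assignment` data.frame: `gene_id`, `stage`,
#'   `first_significant_timepoint_hr` (NA when unassigned),
#'   `log2_fc_at_first`, `fdr_at_first`.
#' @export
assign_stages <- function(contrasts, smap = stage_map(), th = de_thresholds()) {
  stopifnot(length(contrasts) >= 1)
  genes <- contrasts[[1]]$gene_id
  for (tab in contrasts)
    if (!identical(tab$gene_id, genes))
      stop("contrast tables must share one gene universe in the same order")
  laters <- vapply(contrasts, function(tab) attr(tab, "timepoint_later"), 0)
  tp_to_stage <- function(t) {
    for (s in names(smap)) if (t %in% smap[[s]]) return(s)
    stop("configuration error: timepoint ", t, " hr not covered by the stage map")
  }
  stage_of_contrast <- vapply(laters, tp_to_stage, "")
  sig <- vapply(contrasts, function(tab)
    tab$fdr < th$fdr_max & tab$log2_fc > log2(th$min_abs_fold), logical(length(genes)))
  if (is.null(dim(sig))) sig <- matrix(sig, nrow = length(genes))
  first <- apply(sig, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  stage <- ifelse(is.na(first), "unassigned", stage_of_contrast[first])
  lfc <- fdr <- tp1 <- rep(NA_real_, length(genes))
  hit <- which(!is.na(first))
  for (i in hit) {
    tab <- contrasts[[first[i]]]
    lfc[i] <- tab$log2_fc[i]
    fdr[i] <- tab$fdr[i]
    tp1[i] <- laters[first[i]]
  }
  out <- data.frame(gene_id = genes, stage = stage,
                    first_significant_timepoint_hr = tp1,
                    log2_fc_at_first = lfc, fdr_at_first = fdr,
                    stringsAsFactors = FALSE)
  class(out) <- c("stage_assignment", "data.frame")
  attr(out, "stage_map") <- smap
  out
}

#' Stringent post-filter on wave assignments
#'
#' The published gene lists were additionally pruned by an unspecified
#' stringent filter; this package offers an explicit, documented stand-in.
#' Mode `"sustained"` keeps a staged gene only if its mean log2 expression at
#' every timepoint at or after first activation stays above the pre-activation
#' baseline mean + 1 (i.e. the gene stays at least twofold up); failures are
#' demoted to `unassigned`. Mode `"none"` is the identity.
#'
#' @param assignment A `stage_assignment`.
#' @param norm The `norm_matrix` the assignment was computed from.
#' @param mode `"sustained"` or `"none"`.
#' @return A `stage_assignment`; demoted genes listed in the
#'   `stringent_removed` attribute, and the mode recorded in the
#'   `stringent_mode` attribute.
#' @export
stringent_filter <- function(assignment, norm, mode = c("sustained", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") {
    attr(assignment, "stringent_mode") <- "none"
    return(assignment)
  }
  stopifnot(inherits(norm, "norm_matrix"))
  lv <- log2_values(norm)
  meta <- norm$sample_meta
  tps <- sort(unique(meta$timepoint_hr[!is.na(meta$timepoint_hr)]))
  removed <- character(0)
  for (i in which(assignment$stage != "unassigned")) {
    g <- assignment$gene_id[i]
    if (!g %in% norm$gene_ids) next
    t1 <- assignment$first_significant_timepoint_hr[i]
    pre <- meta$sample_id[meta$timepoint_hr < t1]
    baseline <- mean(lv[g, pre])
    ok <- TRUE
    for (t in tps[tps >= t1]) {
      post <- meta$sample_id[meta$timepoint_hr == t]
      if (mean(lv[g, post]) <= baseline + 1) { ok <- FALSE; break }
    }
    if (!ok) {
      assignment$stage[i] <- "unassigned"
      assignment$first_significant_timepoint_hr[i] <- NA_real_
      assignment$log2_fc_at_first[i] <- NA_real_
      assignment$fdr_at_first[i] <- NA_real_
      removed <- c(removed, g)
    }
  }
  attr(assignment, "stringent_removed") <- removed
  attr(assignment, "stringent_mode") <- "sustained"
  assignment
}

#' Row Z-scored expression profiles
#'
#' Per-gene standardization of log2 normalized values for heatmap display:
#' `(value - row mean) / row SD`. Constant rows become all zeros and are
#' listed in the `constant_genes` attribute.
#'
#' @param norm A `norm_matrix`.
#' @param genes Genes to include (default all).
#' @return Gene x sample matrix of row Z-scores.
#' @export
zscore_profiles <- function(norm, genes = NULL) {
  stopifnot(inherits(norm, "norm_matrix"))
  if (is.null(genes)) genes <- norm$gene_ids
  lv <- log2_values(norm)[genes, , drop = FALSE]
  mu <- rowMeans(lv)
  sd <- apply(lv, 1, stats::sd)
  const <- sd == 0
  sd[const] <- 1
  z <- (lv - mu) / sd
  z[const, ] <- 0
  attr(z, "constant_genes") <- genes[const]
  z
}

#' Write a stage assignment as TSV
#'
#' @param assignment A `stage_assignment`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_stage_assignment <- function(assignment, path) {
  utils::write.table(assignment, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
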