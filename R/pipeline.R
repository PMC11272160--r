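#' Validate a pipeline configuration
#'
#' A configuration is a named list (typically parsed from JSON) with:
#' \describe{
#'   \item{seed}{integer, mandatory when any stochastic stage runs}
#'   \item{counts / simulate}{either `counts` (`path`, `format`, optional
#'     `meta`) pointing at an existing bulk matrix, or `simulate` (fields of
#'     [sim_config()]) to generate one}
#'   \item{thresholds}{optional `fdr_max`, `min_abs_fold`}
#'   \item{stage_map}{optional named map, wave -> timepoints}
#'   \item{stringent}{"none" (default) or "sustained"}
#'   \item{projection}{optional: `enabled`, plus either `atlas_dir` (MTX +
#'     sidecars) or `atlas_synthetic` (fields of [atlas_config()]), and
#'     `bulk` ("pipeline" to project the pipeline's own samples, or
#'     `cluster_bulks` with `n_samples`/`depth` to synthesize from the
#'     synthetic atlas clusters), `n_components`, `n_cells`, `depth`,
#'     `k_neighbors`}
#' }
#'
#' @param config Named list or path to a JSON file.
#' @return The normalized config list, or an error naming the failing field.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$seed)) stop("config error: seed is mandatory")
  config$seed <- as.integer(config$seed)
  has_counts <- !is.null(config$counts)
  has_sim <- !is.null(config$simulate)
  if (!has_counts && !has_sim)
    stop("config error: provide either counts paths or a simulate block")
  if (has_counts) {
    if (is.null(config$counts$path)) stop("config error: counts$path missing")
    if (!file.exists(config$counts$path))
      stop("config error: counts path not found: ", config$counts$path)
  }
  if (is.null(config$stringent)) config$stringent <- "none"
  if (!config$stringent %in% c("none", "sustained"))
    stop("config error: unknown stringent mode '", config$stringent, "'")
  pr <- config$projection
  if (!is.null(pr) && isTRUE(pr$enabled)) {
    if (is.null(pr$atlas_dir) && is.null(pr$atlas_synthetic))
      stop("config error: projection enabled but no atlas_dir or atlas_synthetic given")
    if (!is.null(pr$atlas_dir) && !dir.exists(pr$atlas_dir))
      stop("config error: atlas_dir not found: ", pr$atlas_dir)
  }
  config
}

cfg_thresholds <- function(config) {
  th <- config$thresholds
  de_thresholds(fdr_max = if (is.null(th$fdr_max)) 0.05 else th$fdr_max,
                min_abs_fold = if (is.null(th$min_abs_fold)) 2 else th$min_abs_fold)
}

cfg_stage_map <- function(config) {
  if (is.null(config$stage_map)) stage_map() else stage_map(config$stage_map)
}

cfg_sim_config <- function(block, seed) {
  args <- block[intersect(names(block), names(formals(sim_config)))]
  if (!is.null(args$n_genes_per_stage)) args$n_genes_per_stage <- unlist(args$n_genes_per_stage)
  if (!is.null(args$onset_map)) args$onset_map <- unlist(args$onset_map)
  if (is.null(args$seed)) args$seed <- seed
  do.call(sim_config, args)
}

cfg_atlas_config <- function(block, seed) {
  args <- block[intersect(names(block), names(formals(atlas_config)))]
  if (!is.null(args$cells_per_cluster)) args$cells_per_cluster <- unlist(args$cells_per_cluster)
  if (is.null(args$seed)) args$seed <- seed
  do.call(atlas_config, args)
}

plog <- function(log_path, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(line)
  if (!is.null(log_path)) cat(line, "\n", file = log_path, append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes filter -> normalize -> consecutive contrasts -> wave assignment
#' (optionally stringent-filtered) -> optional atlas projection, writing all
#' stage outputs and a run manifest (config echo, seed, per-stage row counts,
#' md5 hash of every output file) under `outdir`. Re-running with an
#' identical config reproduces identical outputs.
#'
#' @param config Config list or JSON path; see [validate_pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return The manifest list, invisibly; all outputs on disk under `outdir`.
#' @export
run_pipeline <- function(config, outdir) {
  config <- validate_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  if (file.exists(log_path)) unlink(log_path)
  manifest <- list(seed = config$seed, config = config, stages = list())
  outputs <- character(0)

  # --- input counts
  if (!is.null(config$simulate)) {
    plog(log_path, "simulate: generating time course")
    sim <- generate_time_course(cfg_sim_config(config$simulate, config$seed))
    cm <- sim$counts
    truth_path <- file.path(outdir, "stage_truth.csv")
    utils::write.csv(sim$truth, truth_path, row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, truth_path)
  } else {
    plog(log_path, "load: ", config$counts$path)
    cm <- read_count_matrix(config$counts$path,
                            format = if (is.null(config$counts$format)) "tsv"
                                     else config$counts$format,
                            meta = config$counts$meta)
  }
  manifest$stages$input <- list(genes = nrow(cm$counts), samples = ncol(cm$counts))

  # --- filter + normalize
  filtered <- suppressMessages(filter_low_expression(cm))
  plog(log_path, "filter: ", nrow(filtered$counts), " of ", nrow(cm$counts), " genes kept")
  sf <- size_factors_median_ratio(filtered)
  norm <- normalize_counts(filtered, sf)
  counts_path <- file.path(outdir, "filtered_counts.tsv")
  meta_path <- file.path(outdir, "samples.csv")
  write_count_matrix(filtered, counts_path, meta = meta_path)
  sf_path <- file.path(outdir, "size_factors.csv")
  utils::write.csv(data.frame(sample_id = names(sf), size_factor = sf),
                   sf_path, row.names = FALSE, quote = FALSE)
  outputs <- c(outputs, counts_path, meta_path, sf_path)
  manifest$stages$filter <- list(genes_kept = nrow(filtered$counts),
                                 filter_log = as.list(attr(filtered, "filter_log")))

  # --- consecutive contrasts + waves
  th <- cfg_thresholds(config)
  smap <- cfg_stage_map(config)
  contrasts <- consecutive_contrasts(norm, th)
  plog(log_path, "contrasts: ", length(contrasts), " consecutive-timepoint tables")
  for (nm in names(contrasts)) {
    p <- file.path(outdir, paste0("de_", gsub("[^0-9.]+", "_", nm), ".tsv"))
    write_de_table(contrasts[[nm]], p)
    outputs <- c(outputs, p)
  }
  assignment <- assign_stages(contrasts, smap, th)
  assignment <- stringent_filter(assignment, norm, mode = config$stringent)
  stage_path <- file.path(outdir, "stage_assignment.tsv")
  write_stage_assignment(assignment, stage_path)
  outputs <- c(outputs, stage_path)
  stage_counts <- table(assignment$stage)
  manifest$stages$cascade <- list(contrasts = names(contrasts),
                                  stage_counts = as.list(stage_counts),
                                  stringent = config$stringent)
  plog(log_path, "stages: ", paste(names(stage_counts), stage_counts,
                                   sep = "=", collapse = ", "))

  # --- projection (optional)
  pr <- config$projection
  if (!is.null(pr) && isTRUE(pr$enabled)) {
    if (!is.null(pr$atlas_dir)) {
      atlas <- read_reference_atlas(pr$atlas_dir)
    } else {
      plog(log_path, "projection: generating synthetic atlas")
      gen <- generate_reference_atlas(cfg_atlas_config(pr$atlas_synthetic, config$seed))
      atlas <- gen$atlas
      adir <- file.path(outdir, "atlas")
      write_reference_atlas(atlas, adir)
      outputs <- c(outputs, file.path(adir, c("counts.mtx", "genes.csv", "cells.csv")))
    }
    bulk_mode <- if (is.null(pr$bulk)) "pipeline" else pr$bulk
    if (identical(bulk_mode, "cluster_bulks")) {
      n_s <- if (is.null(pr$n_samples)) 4 else pr$n_samples
      dep <- if (is.null(pr$bulk_depth)) 1e6 else pr$bulk_depth
      mats <- lapply(seq_along(unique(atlas$labels)), function(i) {
        cl <- unique(atlas$labels)[i]
        generate_bulk_from_cluster(atlas, cl, n_s, dep, seed = config$seed + i)
      })
      counts <- do.call(cbind, lapply(mats, function(m) m$counts))
      meta <- do.call(rbind, lapply(mats, function(m) m$sample_meta))
      bulk <- count_matrix(counts, meta)
    } else {
      bulk <- filtered
    }
    proj <- map_samples_to_atlas(
      atlas, bulk,
      n_cells = if (is.null(pr$n_cells)) 100 else pr$n_cells,
      depth = pr$depth,
      n_components = if (is.null(pr$n_components)) 30 else pr$n_components,
      k_neighbors = if (is.null(pr$k_neighbors)) 15 else pr$k_neighbors,
      seed = config$seed)
    proj_path <- file.path(outdir, "projection.tsv")
    utils::write.table(proj, proj_path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, proj_path)
    manifest$stages$projection <- list(samples = nrow(proj),
                                       params = attr(proj, "params"))
    plog(log_path, "projection: ", nrow(proj), " samples assigned")
  }

  manifest$outputs <- as.list(tools::md5sum(sort(outputs)))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  plog(log_path, "done: manifest written to ", manifest_path)
  invisible(manifest)
}

cli_usage <- function() {
  paste(
    "usage: amniowave <subcommand> --config <json> [--outdir <dir>] [--seed <int>] [--log-level <level>]",
    "subcommands: simulate | normalize | de | cascade | project | run-all",
    sep = "\n")
}

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("usage error: unexpected argument '", a, "'")
    key <- sub("^--", "", a)
    if (!key %in% c("config", "outdir", "seed", "log-level"))
      stop("usage error: unknown flag --", key)
    if (i == length(args)) stop("usage error: --", key, " needs a value")
    flags[[key]] <- args[i + 1]
    i <- i + 2
  }
  flags
}

#' Command-line entry point
#'
#' Subcommand dispatcher behind the `amniowave` Rscript wrapper (see
#' `inst/scripts/amniowave.R`). Each subcommand wraps the corresponding
#' package operation; configuration is a JSON file (`--config`), optionally
#' overridden by `--seed` and `--outdir`. Returns 0 on success, 1 on a
#' runtime error and 2 on a usage/config error (one-line message on stderr).
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit code, invisibly.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  fail <- function(code, msg) {
    message("error: ", msg)
    return(invisible(code))
  }
  if (length(args) == 0) { message(cli_usage()); return(invisible(2L)) }
  sub <- args[1]
  if (!sub %in% c("simulate", "normalize", "de", "cascade", "project", "run-all"))
    return(fail(2L, paste0("unknown subcommand '", sub, "'\n", cli_usage())))
  flags <- tryCatch(parse_cli_flags(args[-1]), error = function(e) e)
  if (inherits(flags, "error")) return(fail(2L, conditionMessage(flags)))
  if (is.null(flags$config)) return(fail(2L, "--config is required"))
  config <- tryCatch(jsonlite::read_json(flags$config, simplifyVector = TRUE),
                     error = function(e) e)
  if (inherits(config, "error"))
    return(fail(2L, paste0("cannot read config: ", conditionMessage(config))))
  if (!is.null(flags$seed)) config$seed <- as.integer(flags$seed)
  outdir <- if (!is.null(flags$outdir)) flags$outdir
            else if (!is.null(config$outdir)) config$outdir else "."
  run <- function(expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      msg <- conditionMessage(res)
      code <- if (grepl("config error|usage error|overlap", msg)) 2L else 1L
      return(fail(code, gsub("\n", " ", msg)))
    }
    invisible(0L)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  switch(sub,
    "simulate" = run({
      if (is.null(config$seed)) stop("config error: seed is mandatory")
      sim <- generate_time_course(cfg_sim_config(config$simulate, config$seed))
      write_count_matrix(sim$counts, file.path(outdir, "counts.tsv"),
                         meta = file.path(outdir, "samples.csv"))
      utils::write.csv(sim$truth, file.path(outdir, "stage_truth.csv"),
                       row.names = FALSE, quote = FALSE)
      jsonlite::write_json(config, file.path(outdir, "config_echo.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }),
    "normalize" = run({
      cm <- read_count_matrix(config$counts$path, meta = config$counts$meta)
      filt <- filter_low_expression(cm)
      sf <- size_factors_median_ratio(filt)
      norm <- normalize_counts(filt, sf)
      utils::write.csv(data.frame(sample_id = names(sf), size_factor = sf),
                       file.path(outdir, "size_factors.csv"), row.names = FALSE,
                       quote = FALSE)
      utils::write.table(data.frame(gene_id = norm$gene_ids, norm$values,
                                    check.names = FALSE),
                         file.path(outdir, "normalized.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }),
    "de" = run({
      cm <- read_count_matrix(config$counts$path, meta = config$counts$meta)
      norm <- normalize_counts(filter_low_expression(cm))
      tab <- de_test(norm, unlist(config$group_a), unlist(config$group_b))
      write_de_table(tab, file.path(outdir, "de_table.tsv"))
    }),
    "cascade" = run({
      cm <- read_count_matrix(config$counts$path, meta = config$counts$meta)
      norm <- normalize_counts(filter_low_expression(cm))
      th <- cfg_thresholds(config)
      contrasts <- consecutive_contrasts(norm, th)
      asg <- assign_stages(contrasts, cfg_stage_map(config), th)
      if (!is.null(config$stringent))
        asg <- stringent_filter(asg, norm, config$stringent)
      write_stage_assignment(asg, file.path(outdir, "stage_assignment.tsv"))
    }),
    "project" = run({
      if (is.null(config$seed)) stop("config error: seed is mandatory")
      pr <- config$projection
      if (is.null(pr$atlas_dir)) stop("config error: projection$atlas_dir required")
      atlas <- read_reference_atlas(pr$atlas_dir)
      bulk <- read_count_matrix(config$counts$path, meta = config$counts$meta)
      proj <- map_samples_to_atlas(
        atlas, bulk,
        n_cells = if (is.null(pr$n_cells)) 100 else pr$n_cells,
        depth = pr$depth,
        n_components = if (is.null(pr$n_components)) 30 else pr$n_components,
        k_neighbors = if (is.null(pr$k_neighbors)) 15 else pr$k_neighbors,
        seed = config$seed)
      utils::write.table(proj, file.path(outdir, "projection.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }),
    "run-all" = run(run_pipeline(config, outdir))
  )
}
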