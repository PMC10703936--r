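#' Read a gene count matrix from TSV
#'
#' First column gene ids, header row of sample ids. Validates uniqueness,
#' integrality and non-negativity.
#'
#' @param path TSV file path.
#' @return integer matrix, genes x samples.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("count table needs a gene column and >= 1 sample")
  genes <- as.character(df[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup)) stopf("duplicate gene id(s): %s",
                         paste(unique(dup), collapse = ", "))
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(mat))) stopf("duplicate sample ids in header")
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    stopf("non-numeric count at line %d", bad[1, 1] + 1L)
  }
  if (any(is.na(mat))) stopf("missing count values")
  if (any(mat < 0)) stopf("negative counts are not allowed")
  if (any(mat != round(mat))) stopf("counts must be integers")
  storage.mode(mat) <- "integer"
  rownames(mat) <- genes
  mat
}

#' Write a count matrix as TSV
#' @param counts integer matrix, genes x samples.
#' @param path output file path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table from TSV
#' @param path TSV with a `sample` column plus covariates.
#' @return data.frame.
#' @export
read_metadata_tsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample" %in% names(df)) stopf("metadata needs a 'sample' column")
  if (anyDuplicated(df$sample)) stopf("duplicate sample ids in metadata")
  df
}

#' Write sample metadata as TSV
#' @param metadata data.frame with a `sample` column.
#' @param path output file path.
#' @export
write_metadata_tsv <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection from GMT
#'
#' Standard dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>member...`. Duplicate members within a line
#' are dropped with a warning; empty sets are dropped with a warning;
#' duplicate set names are an error.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(structure(list(), names = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm)) stopf("duplicate gene-set name(s): %s",
                               paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(parts, function(p) {
    members <- p[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warnf("duplicate member(s) within set '%s' deduplicated", p[1])
      members <- unique(members)
    }
    members
  })
  names(sets) <- nm
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warnf("%d empty set(s) dropped", sum(empty))
    sets <- sets[!empty]
  }
  sets
}

#' Write a gene-set collection as GMT
#' @param collection named list of character vectors.
#' @param path output file path.
#' @param descriptions optional per-set description strings.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  desc <- descriptions %||% rep("na", length(collection))
  lines <- vapply(seq_along(collection), function(i)
    paste(c(names(collection)[i], desc[i], collection[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Configuration for the end-to-end pipeline
#'
#' @param outdir output directory (created if missing).
#' @param sim a [sim_config()] used to generate the cohort when no input
#'   paths are given.
#' @param counts,metadata,gmt optional input file paths; when all three
#'   are given the simulation is skipped.
#' @param design a [design_spec()].
#' @param padj_threshold DE cut-off (default 0.05).
#' @param module_padj_threshold module enrichment cut-off (default 0.1).
#' @param filter_p variance-filter p (default 0.1).
#' @param selection_threshold MKL kernel-weight cut-off (default 0.01).
#' @param min_module_size smallest reported module.
#' @param n_perm permutations for module NES.
#' @param mkl_reps,mkl_train_frac,mkl_inner_k MKL protocol settings.
#' @param seed root seed for every stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, sim = sim_config(), counts = NULL,
                            metadata = NULL, gmt = NULL,
                            design = design_spec(),
                            padj_threshold = 0.05,
                            module_padj_threshold = 0.1,
                            filter_p = 0.1, selection_threshold = 0.01,
                            min_module_size = 10L, n_perm = 500L,
                            mkl_reps = 20L, mkl_train_frac = 0.8,
                            mkl_inner_k = 4L, seed = 1L) {
  for (th in c(padj_threshold, module_padj_threshold, filter_p,
               selection_threshold))
    if (th <= 0 || th > 1) stopf("thresholds must lie in (0, 1]")
  structure(list(outdir = outdir, sim = sim, counts = counts,
                 metadata = metadata, gmt = gmt, design = design,
                 padj_threshold = padj_threshold,
                 module_padj_threshold = module_padj_threshold,
                 filter_p = filter_p,
                 selection_threshold = selection_threshold,
                 min_module_size = min_module_size, n_perm = n_perm,
                 mkl_reps = mkl_reps, mkl_train_frac = mkl_train_frac,
                 mkl_inner_k = mkl_inner_k, seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) the cohort, run per-region differential expression,
#' cross-region concordance and DE-set intersection, pooled differential
#' expression over the regions with discoveries, co-expression module
#' detection with per-class NES, overrepresentation of the pooled DE
#' genes, and the replicated MKL experiment over all samples. Every stage
#' writes its artifacts under `config$outdir`, and a JSON manifest records
#' parameters, seeds and md5 hashes of all outputs; with identical config
#' and seed the run is reproducible hash-for-hash.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (invisibly also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stages <- list()
  files <- character(0)
  add_file <- function(p) files <<- c(files, p)

  external <- !is.null(config$counts) && !is.null(config$metadata) &&
    !is.null(config$gmt)
  if (external) {
    counts <- read_counts_tsv(config$counts)
    metadata <- read_metadata_tsv(config$metadata)
    pathways <- read_gmt(config$gmt)
    truth <- NULL
  } else {
    pathways <- generate_pathways(config$sim)
    metadata <- generate_metadata(config$sim)
    sim <- generate_counts(config$sim, metadata, pathways)
    counts <- sim$counts
    truth <- sim$ground_truth
    add_file(write_counts_tsv(counts, file.path(out, "counts.tsv")))
    add_file(write_metadata_tsv(metadata, file.path(out, "metadata.tsv")))
    add_file(write_gmt(pathways, file.path(out, "pathways.gmt")))
    jsonlite::write_json(truth, file.path(out, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    add_file(file.path(out, "ground_truth.json"))
  }
  stages$input <- list(mode = if (external) "files" else "simulated",
                       n_genes = nrow(counts), n_samples = ncol(counts),
                       n_pathways = length(pathways))

  # per-region DGE
  regions <- sort(unique(metadata$region))
  region_results <- list()
  for (r in regions) {
    res <- tryCatch(run_region_dge(counts, metadata, config$design,
                                   region = r),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warnf("region %s skipped: %s", r, conditionMessage(res))
      next
    }
    region_results[[r]] <- res
    f <- file.path(out, sprintf("dge_%s.tsv", r))
    utils::write.table(res$table, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add_file(f)
  }
  de_sets <- intersect_de_sets(region_results, config$padj_threshold)
  jsonlite::write_json(list(venn = as.list(de_sets$venn),
                            common_genes = de_sets$common_genes),
                       file.path(out, "venn.json"), auto_unbox = TRUE)
  add_file(file.path(out, "venn.json"))
  if (length(region_results) >= 2L) {
    sp <- cross_region_spearman(region_results)
    f <- file.path(out, "spearman.tsv")
    utils::write.table(data.frame(region = rownames(sp), sp,
                                  check.names = FALSE),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    add_file(f)
  }
  de_regions <- names(Filter(function(s) length(s) > 0, de_sets$sets))
  stages$dge <- list(regions_tested = names(region_results),
                     de_regions = de_regions,
                     common_genes = de_sets$common_genes)

  # pooled DGE over regions with discoveries (all regions when none)
  pool <- if (length(de_regions) >= 2L) de_regions else regions
  pooled <- run_region_dge(counts, metadata, config$design,
                           region = "pooled", pooled_regions = pool)
  f <- file.path(out, "dge_pooled.tsv")
  utils::write.table(pooled$table, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  add_file(f)
  pooled_de <- pooled$table$gene[!is.na(pooled$table$padj) &
                                   pooled$table$padj < config$padj_threshold]
  stages$pooled <- list(regions = pool, n_de = length(pooled_de),
                        frac_down = if (length(pooled_de))
                          mean(pooled$table$log2fc[match(pooled_de,
                                                         pooled$table$gene)] < 0)
                        else NA)

  # co-expression on the pooled samples
  sel <- metadata$region %in% pool
  expr <- normalized_log_expression(counts[, sel, drop = FALSE])
  kept <- filter_genes_by_variance(expr, config$filter_p)
  mods <- NULL
  nes_tab <- NULL
  if (length(kept) >= config$min_module_size) {
    sub <- expr[kept, , drop = FALSE]
    beta <- select_soft_threshold(sub)
    mods <- detect_modules(sub, beta,
                           min_module_size = config$min_module_size)
    if (length(mods$modules)) {
      write_gmt(stats::setNames(mods$modules,
                                sprintf("M%d", seq_along(mods$modules))),
                file.path(out, "modules.gmt"))
      add_file(file.path(out, "modules.gmt"))
      nes_tab <- module_nes(expr, metadata$condition[sel], mods,
                            n_perm = config$n_perm, seed = config$seed)
      f <- file.path(out, "module_nes.tsv")
      utils::write.table(nes_tab, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      add_file(f)
    }
  }
  stages$coexpr <- list(n_filtered_genes = length(kept),
                        n_modules = if (is.null(mods)) 0L
                        else length(mods$modules))

  # overrepresentation of the pooled DE genes
  if (length(pooled_de) > 0L && length(pathways) > 0L) {
    ora <- run_ora(pooled_de, pathways, background = pooled$table$gene,
                   seed = config$seed)
    f <- file.path(out, "ora.tsv")
    utils::write.table(ora$table, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add_file(f)
    f <- file.path(out, "ora_edges.tsv")
    utils::write.table(ora$edges, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add_file(f)
    stages$ora <- list(n_query = length(pooled_de),
                       n_uncovered = ora$n_uncovered,
                       top_pathway = if (nrow(ora$table)) ora$table$Pathway[1]
                       else NA)
  }

  # MKL over all samples
  if (length(pathways) > 0L) {
    norm_all <- sweep(counts, 2, estimate_size_factors(counts), "/")
    report <- replicate_experiment(norm_all, metadata$condition, pathways,
                                   n_replications = config$mkl_reps,
                                   seed = config$seed,
                                   train_frac = config$mkl_train_frac,
                                   inner_k = config$mkl_inner_k,
                                   selection_threshold =
                                     config$selection_threshold)
    f <- file.path(out, "mkl_selection.tsv")
    utils::write.table(data.frame(pathway = names(report$selection_counts),
                                  selection_count = report$selection_counts,
                                  mean_weight = colMeans(report$eta)),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    add_file(f)
    jsonlite::write_json(list(mean_auc = report$mean_auc,
                              sd_auc = report$sd_auc,
                              informative = report$informative,
                              n_failed = report$n_failed),
                         file.path(out, "mkl_report.json"),
                         auto_unbox = TRUE, digits = NA)
    add_file(file.path(out, "mkl_report.json"))
    stages$mkl <- list(mean_auc = report$mean_auc, sd_auc = report$sd_auc,
                       informative = report$informative)
  }

  manifest <- list(package_version = as.character(utils::packageVersion("pathexpr")),
                   seed = config$seed,
                   parameters = list(padj_threshold = config$padj_threshold,
                                     module_padj_threshold =
                                       config$module_padj_threshold,
                                     filter_p = config$filter_p,
                                     selection_threshold =
                                       config$selection_threshold,
                                     mkl_reps = config$mkl_reps,
                                     mkl_train_frac = config$mkl_train_frac,
                                     mkl_inner_k = config$mkl_inner_k),
                   stages = stages,
                   elapsed_sec = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")),
                   files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
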