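#' Simulation configuration for a synthetic case/control brain cohort
#'
#' Builds the configuration object consumed by [generate_pathways()],
#' [generate_metadata()] and [generate_counts()]. The defaults emulate a
#' multi-study postmortem cohort: seven brain regions with the per-region
#' case/control sizes of a pooled three-study design, negative-binomial
#' counts with library-size variation, per-gene nuisance covariate effects
#' (study/batch, sex, age, postmortem interval, region), a small block of
#' condition-associated genes shared across a subset of regions (an
#' activity-dependent "hub plus immediate-early-gene block"), latent-factor
#' co-expression modules whose activity shifts with condition, and a
#' pathway collection of which only a few sets are informative for the
#' condition label.
#'
#' @param n_genes number of genes to simulate.
#' @param n_samples_per_region named list, one entry per region, each a
#'   length-2 integer vector `c(n_control, n_case)`.
#' @param n_datasets number of source studies (batch levels).
#' @param de_genes data.frame with columns `gene` (integer gene index),
#'   `log2fc` (condition effect, case vs control) and `regions` (list column
#'   of region names the effect applies to). May have zero rows.
#' @param module_specs list of module specifications, each a list with
#'   `genes` (integer gene indices), `latent_sd` (sd of the shared latent
#'   factor) and `condition_shift` (case-minus-control mean shift of the
#'   latent factor, on the log2-expression scale).
#' @param pathway_specs list with `n_pathways`, `genes_per_pathway`,
#'   `informative_pathway_ids` (integer indices into the pathway list) and
#'   `informative_effect` (absolute log2 fold change given to member genes
#'   of informative pathways, applied in every region; sign is drawn per
#'   gene).
#' @param nb_dispersion global NB dispersion alpha in Var = mu + alpha*mu^2.
#' @param libsize_log_sd sd of the per-sample log library-size factor.
#' @param covariate_effect_sds named numeric vector of per-gene effect sds
#'   (log2 scale) for `dataset`, `sex`, `age`, `pmi`, `region`.
#' @param baseline_log_mean,baseline_log_sd log-normal parameters (natural
#'   log) of per-gene baseline mean counts.
#' @param seed root seed; every generator operation derives its own child
#'   stream from it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_samples_per_region = list(
                         AnCg  = c(24L, 23L),
                         aINS  = c(22L, 26L),
                         Cg25  = c(15L, 13L),
                         DLPFC = c(71L, 79L),
                         nACC  = c(43L, 51L),
                         OFC   = c(22L, 25L),
                         vSUB  = c(19L, 24L)),
                       n_datasets = 3,
                       de_genes = default_de_genes(),
                       module_specs = default_module_specs(n_genes),
                       pathway_specs = list(n_pathways = 30L,
                                            genes_per_pathway = 15L,
                                            informative_pathway_ids = 1:3,
                                            informative_effect = 1),
                       nb_dispersion = 0.1,
                       libsize_log_sd = 0.3,
                       covariate_effect_sds = c(dataset = 0.3, sex = 0.1,
                                                age = 0.1, pmi = 0.05,
                                                region = 0.2),
                       baseline_log_mean = log(100),
                       baseline_log_sd = 1.2,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_per_region = n_samples_per_region,
              n_regions = length(n_samples_per_region),
              n_datasets = as.integer(n_datasets),
              de_genes = de_genes,
              module_specs = module_specs,
              pathway_specs = pathway_specs,
              nb_dispersion = nb_dispersion,
              libsize_log_sd = libsize_log_sd,
              covariate_effect_sds = covariate_effect_sds,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default planted condition-associated genes
#'
#' One hub gene downregulated (log2FC -1) in three of the seven default
#' regions, plus a block of six immediate-early-gene-like genes
#' downregulated in the largest region only. Effect sizes span the
#' 0.5--2 absolute log2FC range typical of bulk brain case/control studies;
#' the generator makes no claim about the (unknown) true effect-size
#' distribution.
#'
#' @return data.frame with columns `gene`, `log2fc`, `regions`.
#' @export
default_de_genes <- function() {
  data.frame(
    gene = 1:7,
    log2fc = c(-1, -2, -1.7, -1.4, -1.1, -0.8, -0.5),
    regions = I(c(list(c("DLPFC", "nACC", "vSUB")),
                  rep(list("DLPFC"), 6))))
}

#' Default latent-factor co-expression modules
#'
#' Two disjoint modules (sizes mirror a two-module solution of 128 and 60
#' genes when `n_genes` allows) whose shared latent factor is shifted down
#' in cases, so module activity is higher in controls.
#'
#' @param n_genes gene universe size (modules are truncated to fit).
#' @return list of module specification lists.
#' @export
default_module_specs <- function(n_genes = 2000) {
  s1 <- min(128L, max(0L, floor((n_genes - 10L) / 3)))
  s2 <- min(60L, max(0L, floor((n_genes - 10L) / 3)))
  if (s1 < 10L || s2 < 10L) return(list())
  list(
    list(genes = seq(11L, 10L + s1), latent_sd = 1, condition_shift = -0.8),
    list(genes = seq(11L + s1, 10L + s1 + s2), latent_sd = 1,
         condition_shift = -0.8))
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1L) stopf("n_genes must be positive")
  if (cfg$n_regions < 1L) stopf("at least one region is required")
  if (is.null(names(cfg$n_samples_per_region)) ||
      anyDuplicated(names(cfg$n_samples_per_region)))
    stopf("regions must have unique names")
  for (r in names(cfg$n_samples_per_region)) {
    ns <- cfg$n_samples_per_region[[r]]
    if (length(ns) != 2L || any(ns < 0L) || sum(ns) < 1L)
      stopf("region '%s' needs non-negative (n_control, n_case) with >= 1 sample", r)
  }
  if (cfg$n_datasets < 1L) stopf("n_datasets must be positive")
  if (cfg$nb_dispersion < 0) stopf("nb_dispersion must be >= 0")
  if (cfg$libsize_log_sd < 0) stopf("libsize_log_sd must be >= 0")
  if (nrow(cfg$de_genes) > 0L) {
    if (!all(is.finite(cfg$de_genes$log2fc))) stopf("planted log2fc must be finite")
    if (any(cfg$de_genes$gene < 1L | cfg$de_genes$gene > cfg$n_genes))
      stopf("de_genes gene index out of range")
    regs <- unique(unlist(cfg$de_genes$regions))
    bad <- setdiff(regs, names(cfg$n_samples_per_region))
    if (length(bad))
      stopf("de_genes refers to unknown region(s): %s", paste(bad, collapse = ", "))
  }
  for (m in cfg$module_specs) {
    if (any(m$genes < 1L | m$genes > cfg$n_genes))
      stopf("module gene index out of range")
    if (m$latent_sd < 0) stopf("module latent_sd must be >= 0")
  }
  ps <- cfg$pathway_specs
  if (ps$n_pathways < 0L) stopf("n_pathways must be >= 0")
  if (ps$n_pathways > 0L && ps$genes_per_pathway > cfg$n_genes)
    stopf("genes_per_pathway exceeds n_genes")
  if (length(ps$informative_pathway_ids) &&
      (any(ps$informative_pathway_ids < 1L) ||
       any(ps$informative_pathway_ids > ps$n_pathways)))
    stopf("informative_pathway_ids out of range 1..n_pathways")
  invisible(cfg)
}

sim_gene_ids <- function(n) sprintf("gene%05d", seq_len(n))
sim_pathway_ids <- function(n) sprintf("pathway_%02d", seq_len(n))

#' Generate a synthetic pathway collection
#'
#' Draws `n_pathways` gene sets of `genes_per_pathway` members each from the
#' gene universe (sets may overlap). Member genes of the configured
#' informative pathways are the genes that [generate_counts()] endows with a
#' condition effect, so only those sets carry label information.
#'
#' @param config a [sim_config()] object.
#' @return named list of character vectors of gene ids
#'   (a `GeneSetCollection` in GMT terms).
#' @export
generate_pathways <- function(config) {
  validate_sim_config(config)
  ps <- config$pathway_specs
  genes <- sim_gene_ids(config$n_genes)
  if (ps$n_pathways == 0L) return(structure(list(), names = character(0)))
  set.seed(child_seed(config$seed, "pathways"))
  sets <- lapply(seq_len(ps$n_pathways), function(i) {
    sort(sample(genes, ps$genes_per_pathway))
  })
  names(sets) <- sim_pathway_ids(ps$n_pathways)
  sets
}

#' Generate synthetic sample metadata
#'
#' One row per sample with condition (`CTRL`/`CASE`), source dataset, sex,
#' age, postmortem interval (PMI, hours) and brain region. Per-region
#' case/control counts are exactly as configured (stratification is
#' deterministic); ages and PMIs are drawn from truncated normals around
#' typical postmortem-cohort demographics (ages ~48 +/- 15 years, PMI
#' ~24-26 +/- 16 h, with a higher female fraction among cases).
#'
#' @param config a [sim_config()] object.
#' @return data.frame with columns `sample`, `condition`, `dataset`, `sex`,
#'   `age`, `pmi`, `region`.
#' @export
generate_metadata <- function(config) {
  validate_sim_config(config)
  set.seed(child_seed(config$seed, "metadata"))
  rows <- lapply(names(config$n_samples_per_region), function(r) {
    ns <- config$n_samples_per_region[[r]]
    n <- sum(ns)
    cond <- c(rep("CTRL", ns[1]), rep("CASE", ns[2]))
    data.frame(sample = sprintf("%s_s%03d", r, seq_len(n)),
               condition = cond,
               dataset = sample(sprintf("ds%d", seq_len(config$n_datasets)),
                                n, replace = TRUE),
               sex = ifelse(stats::runif(n) <
                              ifelse(cond == "CASE", 0.427, 0.287), "F", "M"),
               age = round(rnorm_trunc0(n, 47.66, 15.18), 1),
               pmi = round(rnorm_trunc0(n, ifelse(cond == "CASE", 26.32, 24.08),
                                        16.22), 1),
               region = r,
               stringsAsFactors = FALSE)
  })
  meta <- do.call(rbind, rows)
  rownames(meta) <- NULL
  meta
}

#' Generate a synthetic count matrix with ground truth
#'
#' Counts are negative binomial, `counts[g, s] ~ NB(mu_gs, alpha)` with
#' `Var = mu + alpha * mu^2` and
#' `mu_gs = s_s * q_g * 2^(eta_gs)`, where `s_s` is a log-normal library
#' factor, `q_g` a log-normal baseline mean, and `eta_gs` (log2 scale) sums
#' per-gene nuisance covariate effects (dataset, sex, centered age and PMI,
#' region), the planted condition effects (region-restricted `de_genes` and
#' all-region effects for member genes of informative pathways), and
#' latent-factor module contributions (each module gene loads on a shared
#' per-sample factor whose mean differs by condition).
#'
#' @param config a [sim_config()] object.
#' @param metadata output of [generate_metadata()] (or compatible).
#' @param pathways output of [generate_pathways()]; informative condition
#'   effects are attached to the member genes of
#'   `config$pathway_specs$informative_pathway_ids`.
#' @return list with `counts` (integer matrix genes x samples) and
#'   `ground_truth` (list: `true_de` data.frame of gene/region/log2fc,
#'   `true_modules` list of gene-id sets, `informative_pathways`,
#'   `sample_labels`).
#' @export
generate_counts <- function(config, metadata, pathways = NULL) {
  validate_sim_config(config)
  genes <- sim_gene_ids(config$n_genes)
  n <- nrow(metadata)
  if (n < 1L) stopf("metadata has no samples")
  set.seed(child_seed(config$seed, "counts"))

  sf <- exp(stats::rnorm(n, 0, config$libsize_log_sd))
  q <- exp(stats::rnorm(config$n_genes, config$baseline_log_mean,
                        config$baseline_log_sd))
  # planted DE genes are expressed genes by construction: a near-silent
  # gene cannot carry a meaningful fold change, so their baselines are
  # pinned to the typical expression level
  if (nrow(config$de_genes) > 0L)
    q[config$de_genes$gene] <- exp(config$baseline_log_mean)

  sds <- config$covariate_effect_sds
  eta <- matrix(0, config$n_genes, n)

  # nuisance covariates, one effect per gene (per level for factors)
  ds_lev <- sort(unique(metadata$dataset))
  if (length(ds_lev) > 1L) {
    b <- matrix(stats::rnorm(config$n_genes * length(ds_lev), 0, sds[["dataset"]]),
                config$n_genes, length(ds_lev))
    eta <- eta + b[, match(metadata$dataset, ds_lev), drop = FALSE]
  }
  rg_lev <- sort(unique(metadata$region))
  if (length(rg_lev) > 1L) {
    b <- matrix(stats::rnorm(config$n_genes * length(rg_lev), 0, sds[["region"]]),
                config$n_genes, length(rg_lev))
    eta <- eta + b[, match(metadata$region, rg_lev), drop = FALSE]
  }
  eta <- eta + stats::rnorm(config$n_genes, 0, sds[["sex"]]) %o%
    as.numeric(metadata$sex == "F")
  eta <- eta + stats::rnorm(config$n_genes, 0, sds[["age"]]) %o%
    as.numeric(scale(metadata$age))
  eta <- eta + stats::rnorm(config$n_genes, 0, sds[["pmi"]]) %o%
    as.numeric(scale(metadata$pmi))

  is_case <- metadata$condition == "CASE"

  # region-restricted planted condition effects
  true_de <- data.frame(gene = character(0), region = character(0),
                        log2fc = numeric(0), stringsAsFactors = FALSE)
  if (nrow(config$de_genes) > 0L) {
    for (i in seq_len(nrow(config$de_genes))) {
      g <- config$de_genes$gene[i]
      lfc <- config$de_genes$log2fc[i]
      regs <- config$de_genes$regions[[i]]
      hit <- is_case & metadata$region %in% regs
      eta[g, hit] <- eta[g, hit] + lfc
      true_de <- rbind(true_de, data.frame(gene = genes[g], region = regs,
                                           log2fc = lfc))
    }
  }

  # all-region effects for member genes of informative pathways
  info_ids <- config$pathway_specs$informative_pathway_ids
  info_genes <- character(0)
  if (!is.null(pathways) && length(info_ids)) {
    info_genes <- sort(unique(unlist(pathways[info_ids])))
    gi <- match(info_genes, genes)
    sgn <- sample(c(-1, 1), length(gi), replace = TRUE)
    lfc <- sgn * config$pathway_specs$informative_effect
    eta[gi, is_case] <- eta[gi, is_case] + lfc
    if (any(lfc != 0))
      true_de <- rbind(true_de,
                       do.call(rbind, lapply(seq_along(gi), function(k) {
                         data.frame(gene = info_genes[k],
                                    region = names(config$n_samples_per_region),
                                    log2fc = lfc[k])
                       })))
  }

  # latent-factor modules
  true_modules <- list()
  for (m in config$module_specs) {
    u <- stats::rnorm(n, ifelse(is_case, m$condition_shift / 2,
                                -m$condition_shift / 2), m$latent_sd)
    load <- stats::runif(length(m$genes), 0.8, 1.2)
    eta[m$genes, ] <- eta[m$genes, ] + load %o% u
    true_modules <- c(true_modules, list(genes[m$genes]))
  }

  log_mu <- log(q) + eta * log(2) + rep(log(sf), each = config$n_genes)
  if (any(!is.finite(log_mu)) || any(log_mu > log(1e12)))
    stopf("non-finite or overflowing NB mean; check planted effect sizes")
  mu <- exp(log_mu)

  a <- config$nb_dispersion
  counts <- if (a <= 1e-12) {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = 1 / a)
  }
  counts <- matrix(as.integer(counts), config$n_genes, n,
                   dimnames = list(genes, metadata$sample))

  gt <- list(true_de = unique(true_de[true_de$log2fc != 0, , drop = FALSE]),
             true_modules = true_modules,
             informative_pathways = if (length(info_ids))
               names(pathways)[info_ids] else character(0),
             sample_labels = stats::setNames(metadata$condition, metadata$sample))
  list(counts = counts, ground_truth = gt)
}

#' Generate a signal-free cohort
#'
#' Convenience wrapper: all condition effects are zeroed (planted DE genes,
#' informative-pathway effects and module condition shifts), so the
#' condition labels carry no information. Nuisance covariate effects,
#' library-size variation and module latent factors are retained. Used for
#' type-I-error and chance-AUC calibration.
#'
#' @param config a [sim_config()] object.
#' @return list with `counts`, `metadata`, `pathways`, `ground_truth`.
#' @export
generate_null_cohort <- function(config) {
  cfg <- config
  cfg$de_genes <- cfg$de_genes[0, , drop = FALSE]
  cfg$pathway_specs$informative_effect <- 0
  cfg$module_specs <- lapply(cfg$module_specs, function(m) {
    m$condition_shift <- 0
    m
  })
  class(cfg) <- "sim_config"
  pw <- generate_pathways(cfg)
  meta <- generate_metadata(cfg)
  gc_ <- generate_counts(cfg, meta, pw)
  gt <- gc_$ground_truth
  gt$true_de <- gt$true_de[0, , drop = FALSE]
  gt$informative_pathways <- character(0)
  list(counts = gc_$counts, metadata = meta, pathways = pw, ground_truth = gt)
}
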