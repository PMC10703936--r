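# Shared fixtures: small synthetic study configurations used across tests.
# All cohorts are generated in code at test time; nothing is stored on disk.

empty_de <- function() {
  data.frame(gene = integer(0), log2fc = numeric(0),
             regions = I(list()))[0, ]
}

no_pathways <- function() {
  list(n_pathways = 0L, genes_per_pathway = 0L,
       informative_pathway_ids = integer(0), informative_effect = 0)
}

# Signal-free cohort with all nuisance covariates active: two regions so
# the pooled design carries a region term.
null_cohort_config <- function(seed, n_genes = 1000L, n_per_arm = 15L) {
  sim_config(n_genes = n_genes,
             n_samples_per_region = list(R1 = c(n_per_arm, n_per_arm),
                                         R2 = c(n_per_arm, n_per_arm)),
             de_genes = empty_de(),
             module_specs = list(),
             pathway_specs = no_pathways(),
             seed = seed)
}

# Seven regions at the default cohort proportions with a single hub gene
# downregulated in three of them.
hub_config <- function(seed, n_genes = 800L) {
  sim_config(n_genes = n_genes,
             de_genes = data.frame(
               gene = 1L, log2fc = -1,
               regions = I(list(c("DLPFC", "nACC", "vSUB")))),
             module_specs = list(),
             pathway_specs = no_pathways(),
             seed = seed)
}

# One-region cohort with two planted 30-gene latent-factor modules whose
# activity is shifted down in cases.
module_config <- function(seed, n_genes = 500L) {
  sim_config(n_genes = n_genes,
             n_samples_per_region = list(A = c(40L, 40L)),
             de_genes = empty_de(),
             module_specs = list(
               list(genes = 1:30, latent_sd = 1, condition_shift = -0.8),
               list(genes = 31:60, latent_sd = 1, condition_shift = -0.8)),
             pathway_specs = no_pathways(),
             seed = seed)
}

# 200-sample cohort with 30 pathways of which 3 are informative.
mkl_config <- function(seed, n_genes = 600L) {
  sim_config(n_genes = n_genes,
             n_samples_per_region = list(A = c(100L, 100L)),
             de_genes = empty_de(),
             module_specs = list(),
             pathway_specs = list(n_pathways = 30L, genes_per_pathway = 15L,
                                  informative_pathway_ids = 1:3,
                                  informative_effect = 1),
             seed = seed)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Independent brute-force BH step-up: sort, cummin from the largest rank,
# unsort. Kept deliberately separate from the implementation under test.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- sorted * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Independent brute-force GSEA running sum over explicit positions
# (shares the positive-wins tie convention of the implementation).
es_oracle <- function(scores, gene_set, p = 1) {
  n <- length(scores)
  hits <- names(scores) %in% gene_set
  nh <- sum(hits)
  if (nh == n) return(1)
  nr <- sum(abs(scores[hits])^p)
  run <- 0
  best_pos <- best_neg <- 0
  for (i in seq_len(n)) {
    run <- run + if (hits[i]) abs(unname(scores[i]))^p / nr else -1 / (n - nh)
    if (run > best_pos) best_pos <- run
    if (run < best_neg) best_neg <- run
  }
  if (best_pos + best_neg >= -1e-12) best_pos else best_neg
}

# Independent hypergeometric upper tail by direct pmf summation.
hyper_tail_oracle <- function(a, K, N, n) {
  hi <- min(K, n)
  if (a > hi) return(0)
  sum(stats::dhyper(a:hi, K, N - K, n))
}
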