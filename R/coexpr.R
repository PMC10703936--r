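#' Variance-based gene filter with a fitted chi-square null
#'
#' Models the per-gene sample variances on the (log-)normalized expression
#' matrix as draws from a scaled chi-square null,
#' `var_g ~ scale * chisq(df) / df`: variances are scaled by their typical
#' magnitude and `df` is fitted empirically from their relative spread
#' (`df = 2 * (location / spread)^2`). Each gene gets an upper-tail p for
#' excess variance and genes with `p < p_threshold` are kept. Location and
#' spread are estimated robustly (median and MAD) so that genuinely
#' high-variance genes do not inflate the null they are tested against;
#' the fit is deterministic. Genes with non-positive mean expression are
#' excluded up front.
#'
#' @param expr numeric matrix, genes x samples (log2 normalized counts).
#' @param p_threshold keep genes with excess-variance p below this
#'   (default 0.1, the conventional filtering p).
#' @return character vector of retained gene ids, with the per-gene
#'   p-values attached as attribute `p`.
#' @export
filter_genes_by_variance <- function(expr, p_threshold = 0.1) {
  if (ncol(expr) < 2L) stopf("need at least 2 samples")
  m <- rowMeans(expr)
  v <- row_vars(expr)
  ok <- m > 0 & is.finite(v)
  score <- v[ok]
  mu <- stats::median(score)
  sig <- stats::mad(score)
  if (sig == 0) sig <- max(stats::sd(score), .Machine$double.eps)
  df <- max(1, 2 * mu^2 / sig^2)
  # median of chi2_df is ~ df*(1-2/(9df))^3; anchor the scale to it
  med_chi <- df * (1 - 2 / (9 * df))^3
  p <- stats::pchisq(score * med_chi / mu, df = df, lower.tail = FALSE)
  keep <- rownames(expr)[ok][p < p_threshold]
  if (length(keep) < 10L)
    warnf("fewer than 10 genes pass the variance filter; proceeding")
  attr(keep, "p") <- stats::setNames(p, rownames(expr)[ok])
  keep
}

# Scale-free topology fit index: R^2 of log10 frequency vs log10 mean
# connectivity over equal-width bins, zeroed when the slope is positive.
scale_free_r2 <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(0)
  br <- seq(min(k), max(k), length.out = n_bins + 1L)
  cut_i <- cut(k, br, include.lowest = TRUE)
  freq <- tabulate(cut_i, n_bins)
  mean_k <- tapply(k, cut_i, mean)
  use <- freq > 0 & !is.na(mean_k)
  if (sum(use) < 3L) return(0)
  x <- log10(mean_k[use]); y <- log10(freq[use] / sum(freq))
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  if (stats::coef(fit)[2] > 0) 0 else r2
}

#' Select the soft-threshold power for the co-expression network
#'
#' Returns the smallest candidate power `beta` for which the connectivity
#' distribution of the `|cor|^beta` network reaches a scale-free fit
#' `R^2 >= r2_cut` while keeping a mean connectivity of at least
#' `min_mean_k` (without the connectivity proviso the fit index creeps up
#' spuriously as high powers empty the network). Small desk-scale networks
#' often never reach the threshold at all; in that case the
#' sample-size-based power convention for unsigned networks is used
#' instead (6 for >= 40 samples, 7 for 30-39, 8 for 20-29, 9 below 20),
#' with a message. Constant genes are excluded before the correlation
#' with a warning.
#'
#' @param expr numeric matrix, genes x samples (filtered genes).
#' @param candidate_betas integer vector of powers to try.
#' @param r2_cut scale-free fit threshold (default 0.8).
#' @param cor_method correlation method (default Pearson).
#' @param min_mean_k smallest acceptable mean connectivity (default 1).
#' @return selected power, with the per-beta fit indices attached as
#'   attribute `fit_indices`.
#' @export
select_soft_threshold <- function(expr, candidate_betas = 1:20,
                                  r2_cut = 0.8, cor_method = "pearson",
                                  min_mean_k = 1) {
  if (nrow(expr) < 3L) stopf("need at least 3 genes")
  v <- row_vars(expr)
  if (any(v == 0)) {
    warnf("%d constant gene(s) excluded before correlation", sum(v == 0))
    expr <- expr[v > 0, , drop = FALSE]
  }
  a <- abs(stats::cor(t(expr), method = cor_method))
  diag(a) <- 0
  ks <- lapply(candidate_betas, function(b) colSums(a^b))
  r2s <- vapply(ks, scale_free_r2, numeric(1))
  mean_k <- vapply(ks, mean, numeric(1))
  hit <- which(r2s >= r2_cut & mean_k >= min_mean_k)
  if (length(hit)) {
    beta <- candidate_betas[hit[1]]
  } else if (length(candidate_betas) == 1L) {
    beta <- candidate_betas
  } else {
    n <- ncol(expr)
    fallback <- if (n >= 40) 6L else if (n >= 30) 7L else if (n >= 20) 8L else 9L
    beta <- candidate_betas[which.min(abs(candidate_betas - fallback))]
    message(sprintf(
      "no power reaches the scale-free fit threshold; using the sample-size default %d",
      beta))
  }
  attr(beta, "fit_indices") <- stats::setNames(r2s, candidate_betas)
  beta
}

# Unsigned topological overlap matrix from an adjacency matrix.
tom_similarity <- function(a) {
  diag(a) <- 0
  l <- a %*% a
  k <- colSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules
#'
#' Builds the unsigned weighted network `|cor|^beta`, converts it to
#' topological-overlap dissimilarity, clusters genes by average-linkage
#' hierarchical clustering, and cuts the tree at a fixed dissimilarity
#' height; clusters smaller than `min_module_size` go to the unassigned
#' set. Modules are returned largest first.
#'
#' @param expr numeric matrix, genes x samples.
#' @param beta soft-threshold power (see [select_soft_threshold()]).
#' @param min_module_size smallest cluster kept as a module (default 30;
#'   10 is a reasonable desk-scale override).
#' @param cut_height static tree-cut height on TOM dissimilarity
#'   (default 0.99, the fixed-height tree-cut convention; uncorrelated
#'   genes sit essentially at dissimilarity 1 and stay unmerged).
#' @param cor_method correlation method (default Pearson).
#' @return object of class `module_set`: list with `modules` (list of
#'   gene-id vectors), `unassigned`, `beta`, `cut_height`.
#' @export
detect_modules <- function(expr, beta, min_module_size = 30L,
                           cut_height = 0.99, cor_method = "pearson") {
  if (nrow(expr) < min_module_size) stopf("fewer genes than min_module_size")
  v <- row_vars(expr)
  if (any(v == 0)) {
    warnf("%d constant gene(s) moved to unassigned", sum(v == 0))
  }
  keep <- v > 0
  genes <- rownames(expr)
  a <- abs(stats::cor(t(expr[keep, , drop = FALSE]), method = cor_method))^beta
  diss <- 1 - tom_similarity(a)
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  tab <- table(cl)
  mod_ids <- names(tab)[tab >= min_module_size]
  modules <- lapply(mod_ids, function(i) sort(genes[keep][cl == as.integer(i)]))
  modules <- modules[order(-vapply(modules, length, integer(1)))]
  assigned <- unlist(modules)
  res <- list(modules = modules,
              unassigned = sort(setdiff(genes, assigned)),
              beta = beta, cut_height = cut_height)
  class(res) <- "module_set"
  res
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d module(s) of sizes %s; %d unassigned (beta = %s)\n",
              length(x$modules),
              paste(vapply(x$modules, length, integer(1)), collapse = ", "),
              length(x$unassigned), format(x$beta)))
  invisible(x)
}

#' Per-class ranked gene scores
#'
#' Z-scores each gene across all samples (zero-variance genes get z = 0),
#' then scores each gene per condition class as the mean z over that
#' class's samples, returning one descending-sorted score vector per
#' class. For two equal-sized classes the two score vectors are exact
#' negatives of each other genewise.
#'
#' @param expr numeric matrix, genes x samples.
#' @param labels per-sample class labels (length = samples).
#' @return named list, one descending-sorted named numeric vector per class.
#' @export
rank_genes_per_class <- function(expr, labels) {
  labels <- as.character(labels)
  if (any(table(labels) < 2L)) stopf("every class needs >= 2 samples")
  m <- rowMeans(expr)
  s <- sqrt(row_vars(expr))
  z <- (expr - m) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  out <- lapply(sort(unique(labels)), function(cl) {
    sc <- rowMeans(z[, labels == cl, drop = FALSE])
    sort(sc, decreasing = TRUE)
  })
  stats::setNames(out, sort(unique(labels)))
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The classic GSEA running-sum statistic on a ranked score vector: hit
#' positions advance the sum by `|score|^weight_p` (normalized over hits),
#' miss positions retreat by `1 / (N - N_hits)`; the enrichment score is
#' the running-sum value of largest absolute magnitude (when the largest
#' positive and negative excursions tie in magnitude, the positive one is
#' returned by convention). When the set covers the whole universe there
#' are no misses and the score is +1 by convention.
#'
#' @param scores named numeric vector sorted in decreasing order.
#' @param gene_set character vector of gene ids.
#' @param weight_p hit-weight exponent (default 1).
#' @return enrichment score in `[-1, 1]`.
#' @export
gsea_enrichment_score <- function(scores, gene_set, weight_p = 1) {
  hits <- names(scores) %in% gene_set
  nh <- sum(hits)
  if (nh == 0L) stopf("gene set does not intersect the ranked universe")
  n <- length(scores)
  if (nh == n) return(1)
  w <- abs(scores)^weight_p
  inc <- ifelse(hits, w / sum(w[hits]), 0)
  dec <- ifelse(hits, 0, 1 / (n - nh))
  running <- cumsum(inc - dec)
  pos <- max(running)
  neg <- min(running)
  if (pos + neg >= -1e-12) pos else neg
}

#' Per-class normalized enrichment scores for modules
#'
#' Scores every module against every class ranking from
#' [rank_genes_per_class()]. The null distribution comes from
#' size-matched random gene sets (`n_perm` draws per module size, a
#' gene-label permutation null); `NES = ES / mean(|null ES|)` over null
#' scores of the same sign, the p-value is the same-sign null tail
#' `(1 + #{|null| >= |ES|}) / (1 + #same-sign)`, and BH adjustment is
#' applied across modules within each class.
#'
#' @param expr numeric matrix, genes x samples.
#' @param labels per-sample class labels.
#' @param modules a `module_set` (or plain list of gene-id vectors).
#' @param n_perm number of null gene sets per module (default 1000; fewer
#'   than 100 triggers a warning).
#' @param seed RNG seed for the permutation null.
#' @param weight_p hit-weight exponent passed to the enrichment score.
#' @return data.frame with columns module, class, size, ES, NES, pvalue,
#'   padj.
#' @export
module_nes <- function(expr, labels, modules, n_perm = 1000L, seed = 1L,
                       weight_p = 1) {
  mods <- if (inherits(modules, "module_set")) modules$modules else modules
  if (length(mods) == 0L) stopf("no modules to score")
  if (n_perm < 100L) warnf("n_perm < 100 gives unstable p-values")
  rankings <- rank_genes_per_class(expr, labels)
  universe <- rownames(expr)
  set.seed(child_seed(seed, "perm"))
  rows <- list()
  for (cl in names(rankings)) {
    sc <- rankings[[cl]]
    es <- nes <- p <- numeric(length(mods))
    for (mi in seq_along(mods)) {
      gs <- intersect(mods[[mi]], universe)
      es[mi] <- gsea_enrichment_score(sc, gs, weight_p)
      null_es <- vapply(seq_len(n_perm), function(i)
        gsea_enrichment_score(sc, sample(universe, length(gs)), weight_p),
        numeric(1))
      same <- null_es[sign(null_es) == sign(es[mi])]
      if (length(same) == 0L) same <- abs(null_es)
      nes[mi] <- es[mi] / mean(abs(same))
      p[mi] <- (1 + sum(abs(same) >= abs(es[mi]))) / (1 + length(same))
    }
    rows[[cl]] <- data.frame(module = sprintf("M%d", seq_along(mods)),
                             class = cl,
                             size = vapply(mods, length, integer(1)),
                             ES = es, NES = nes, pvalue = p,
                             padj = bh_adjust(p),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Log2 normalized expression from counts
#'
#' `log2(counts / size_factor + 1)` using median-of-ratios size factors —
#' the expression matrix fed to the co-expression and kernel stages.
#'
#' @param counts integer matrix, genes x samples.
#' @param size_factors optional precomputed factors.
#' @return numeric matrix of the same shape.
#' @export
normalized_log_expression <- function(counts, size_factors = NULL) {
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  sf <- size_factors %||% estimate_size_factors(counts)
  log2(sweep(counts, 2, sf, "/") + 1)
}
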