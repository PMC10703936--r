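#' Design specification for differential expression
#'
#' @param covariates character vector of metadata columns to adjust for
#'   (order is kept in the design matrix). Numeric columns enter centered;
#'   character/factor columns are treatment-coded with the
#'   lexicographically first level as reference.
#' @param condition_column metadata column holding the condition label.
#' @param reference_level condition level treated as baseline, so the
#'   reported log2 fold change is case vs control and downregulation in
#'   cases gives a negative value.
#' @return list of class `design_spec`.
#' @export
design_spec <- function(covariates = c("dataset", "sex", "age", "pmi"),
                        condition_column = "condition",
                        reference_level = "CTRL") {
  if (condition_column %in% covariates)
    stopf("condition_column must not appear among covariates")
  structure(list(covariates = covariates,
                 condition_column = condition_column,
                 reference_level = reference_level),
            class = "design_spec")
}

# Build the model matrix for a design_spec on a metadata subset.
# Constant covariates (e.g. a single dataset within one region) are dropped
# with a message; the condition term is always the last column.
build_design_matrix <- function(metadata, design) {
  for (cl in c(design$covariates, design$condition_column))
    if (!cl %in% names(metadata)) stopf("metadata lacks column '%s'", cl)
  cond <- metadata[[design$condition_column]]
  if (!design$reference_level %in% cond)
    stopf("reference level '%s' absent from %s", design$reference_level,
          design$condition_column)
  if (length(unique(cond)) < 2L)
    stopf("only one condition level present; cannot test")
  keep <- character(0)
  for (cl in design$covariates) {
    v <- metadata[[cl]]
    if (length(unique(v)) < 2L) {
      message(sprintf("covariate '%s' is constant in this subset; dropped", cl))
    } else keep <- c(keep, cl)
  }
  df <- metadata[, keep, drop = FALSE]
  for (cl in keep) {
    if (is.numeric(df[[cl]])) df[[cl]] <- df[[cl]] - mean(df[[cl]])
    else df[[cl]] <- factor(df[[cl]], levels = sort(unique(df[[cl]])))
  }
  lev <- c(design$reference_level,
           sort(setdiff(unique(cond), design$reference_level)))
  df$.condition <- factor(cond, levels = lev)
  X <- stats::model.matrix(~ ., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  cond_col <- grep("^\\.condition", colnames(X), value = TRUE)[1]
  list(X = X, condition_col = cond_col)
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization constants in the DESeq convention: each
#' sample's factor is the median, over genes with strictly positive counts
#' in every sample, of the ratio of that sample's count to the gene's
#' geometric mean, then all factors are rescaled to geometric mean one.
#'
#' @param counts integer matrix, genes x samples.
#' @param on_zero what to do when no gene is positive in all samples:
#'   `"error"` (default) or `"pseudocount"` (estimate on counts + 0.5).
#' @return named positive numeric vector, one per sample.
#' @export
estimate_size_factors <- function(counts, on_zero = c("error", "pseudocount")) {
  on_zero <- match.arg(on_zero)
  if (any(colSums(counts) == 0)) stopf("sample(s) with all-zero counts")
  logc <- log(counts)
  loggeo <- rowMeans(logc)
  ref <- is.finite(loggeo)
  if (!any(ref)) {
    if (on_zero == "error")
      stopf(paste("no gene has positive counts in every sample;",
                  "rerun with on_zero = 'pseudocount'"))
    logc <- log(counts + 0.5)
    loggeo <- rowMeans(logc)
    ref <- rep(TRUE, nrow(counts))
  }
  sf <- apply(logc[ref, , drop = FALSE], 2,
              function(x) exp(stats::median(x - loggeo[ref])))
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Gene-wise method-of-moments NB dispersions
#'
#' For each gene, the residual variance of normalized counts around the
#' design fit (ordinary least squares, the moment analogue of group means)
#' is compared with the mean:
#' `alpha_g = (s2_g - xi * mean_g) / mean_g^2`, where `xi = mean(1/s_s)`
#' accounts for the Poisson part after normalization. Estimates are floored
#' at `alpha_min`; optional shrinkage pulls log dispersions halfway toward
#' a log-linear mean-dispersion trend.
#'
#' @param counts integer matrix, genes x samples.
#' @param size_factors per-sample factors from [estimate_size_factors()].
#' @param design_matrix numeric model matrix (samples x coefficients); must
#'   be full rank with at least 2 residual degrees of freedom.
#' @param alpha_min dispersion floor.
#' @param shrink logical; apply trend shrinkage.
#' @return named numeric vector of dispersions, one per gene.
#' @export
estimate_dispersions <- function(counts, size_factors, design_matrix,
                                 alpha_min = 1e-8, shrink = FALSE) {
  n <- ncol(counts)
  p <- ncol(design_matrix)
  if (n - p < 2L) stopf("need >= 2 residual degrees of freedom")
  qrX <- qr(design_matrix)
  if (qrX$rank < p) {
    bad <- colnames(design_matrix)[qrX$pivot[(qrX$rank + 1L):p]]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  y <- sweep(counts, 2, size_factors, "/")
  fitted <- t(qr.fitted(qrX, t(y)))
  rss <- rowSums((y - fitted)^2)
  s2 <- rss / (n - p)
  m <- rowMeans(y)
  xi <- mean(1 / size_factors)
  alpha <- pmax(alpha_min, (s2 - xi * m) / m^2)
  alpha[m <= 0] <- alpha_min
  if (shrink) {
    ok <- m > 0 & alpha > alpha_min
    if (sum(ok) >= 10L) {
      fit <- stats::lm(log(alpha[ok]) ~ log(m[ok]))
      trend <- exp(cbind(1, log(pmax(m, 1e-8))) %*% stats::coef(fit))[, 1]
      alpha <- pmax(alpha_min, exp(0.5 * log(alpha) + 0.5 * log(trend)))
    }
  }
  stats::setNames(alpha, rownames(counts))
}

#' Fit a negative-binomial GLM for one gene
#'
#' Log-link NB regression with fixed dispersion and `log(size_factor)`
#' offsets, maximized by iteratively reweighted least squares (Fisher
#' scoring, weights `mu / (1 + alpha * mu)`). Coefficients are on the
#' natural-log scale; the asymptotic covariance is `(X' W X)^-1`.
#'
#' @param y integer counts for one gene (length = samples).
#' @param size_factors per-sample normalization factors.
#' @param design_matrix model matrix.
#' @param alpha NB dispersion for this gene.
#' @param tol convergence tolerance on `max |delta beta|`.
#' @param max_iter iteration cap.
#' @return list with `beta`, `cov`, `converged`, `iterations`, `mu`.
#' @export
fit_nb_glm <- function(y, size_factors, design_matrix, alpha,
                       tol = 1e-6, max_iter = 100L) {
  X <- design_matrix
  off <- log(size_factors)
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  beta <- rep(0, ncol(X))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit$coefficients))) break
    delta <- fit$coefficients - beta
    beta <- fit$coefficients
    eta <- off + drop(X %*% beta)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  w <- mu / (1 + alpha * mu)
  xtwx <- crossprod(X, X * w)
  covb <- tryCatch(solve(xtwx), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  dimnames(covb) <- list(colnames(X), colnames(X))
  list(beta = stats::setNames(beta, colnames(X)), cov = covb,
       converged = converged, iterations = it, mu = mu)
}

#' Wald test for one coefficient
#'
#' `z = beta / SE`, two-sided `p = 2 * pnorm(-|z|)`. A zero or non-finite
#' standard error yields `NA` with a flag.
#'
#' @param beta named coefficient vector.
#' @param cov coefficient covariance matrix.
#' @param coefficient name of the tested coefficient.
#' @return list with `z`, `p`, `se`, `ok`.
#' @export
wald_test <- function(beta, cov, coefficient) {
  if (!coefficient %in% names(beta)) stopf("coefficient '%s' not in fit", coefficient)
  se <- sqrt(cov[coefficient, coefficient])
  if (!is.finite(se) || se <= 0)
    return(list(z = NA_real_, p = NA_real_, se = se, ok = FALSE))
  z <- beta[[coefficient]] / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)), se = se, ok = TRUE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment over the non-missing entries; `NA`s are excluded
#' from the multiplicity count and propagated.
#'
#' @param p numeric vector of p-values (NA allowed).
#' @return numeric vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p-values must lie in [0, 1]")
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Covariate-adjusted NB differential expression for one region (or pooled)
#'
#' Orchestrates the full test for condition: drop all-zero genes, estimate
#' median-of-ratios size factors, prefilter genes by normalized mean
#' expression, estimate gene-wise dispersions, fit the NB GLM per gene with
#' the covariate design, Wald-test the condition coefficient, and BH-adjust
#' over the genes actually tested (non-converged fits are excluded from the
#' multiplicity count and reported). No log-fold-change cut-off is applied.
#'
#' @param counts integer matrix, genes x samples.
#' @param metadata data.frame with one row per sample (same order as
#'   columns of `counts`), containing the design columns and a `region`
#'   column.
#' @param design a [design_spec()]. For `region = "pooled"` the region
#'   column is appended to the covariates; for a single region it is not.
#' @param region region label to subset to, or `"pooled"` to use all rows
#'   of `metadata` (or the subset in `pooled_regions`).
#' @param pooled_regions optional character vector restricting the pooled
#'   analysis to specific regions.
#' @param prefilter_mean genes with normalized mean below this are excluded
#'   before testing (default 1).
#' @param alpha_min dispersion floor.
#' @param shrink_dispersions logical, passed to [estimate_dispersions()];
#'   on by default — pulling gene-wise dispersions halfway toward the
#'   mean-dispersion trend tames the far p-value tail that raw
#'   method-of-moments estimates produce at moderate sample sizes.
#' @return object of class `dge_result`: data.frame `table` (gene,
#'   baseMean, log2fc, se, wald_z, pvalue, padj), plus `size_factors`,
#'   `dispersions`, `n_filtered`, `n_nonconverged`, `region`.
#' @export
run_region_dge <- function(counts, metadata, design = design_spec(),
                           region = "pooled", pooled_regions = NULL,
                           prefilter_mean = 1, alpha_min = 1e-8,
                           shrink_dispersions = TRUE) {
  if (ncol(counts) != nrow(metadata))
    stopf("counts columns and metadata rows do not match")
  if (region != "pooled") {
    sel <- metadata$region == region
    if (!any(sel)) stopf("region '%s' has no samples", region)
    metadata <- metadata[sel, , drop = FALSE]
    counts <- counts[, sel, drop = FALSE]
    design_use <- design
  } else {
    if (!is.null(pooled_regions)) {
      sel <- metadata$region %in% pooled_regions
      metadata <- metadata[sel, , drop = FALSE]
      counts <- counts[, sel, drop = FALSE]
    }
    design_use <- design
    if (length(unique(metadata$region)) > 1L &&
        !"region" %in% design$covariates)
      design_use$covariates <- c(design$covariates, "region")
  }
  cond <- metadata[[design$condition_column]]
  if (length(unique(cond)) < 2L)
    stopf("region '%s' has a single condition level; cannot test", region)

  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  sf <- estimate_size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(norm)
  keep <- base_mean >= prefilter_mean
  n_filtered <- sum(!keep)
  counts <- counts[keep, , drop = FALSE]
  base_mean <- base_mean[keep]

  dm <- build_design_matrix(metadata, design_use)
  alpha <- estimate_dispersions(counts, sf, dm$X, alpha_min = alpha_min,
                                shrink = shrink_dispersions)

  ng <- nrow(counts)
  log2fc <- se <- z <- p <- rep(NA_real_, ng)
  conv <- logical(ng)
  for (g in seq_len(ng)) {
    fit <- fit_nb_glm(counts[g, ], sf, dm$X, alpha[g])
    conv[g] <- fit$converged
    if (!fit$converged) next
    wt <- wald_test(fit$beta, fit$cov, dm$condition_col)
    if (!wt$ok) { conv[g] <- FALSE; next }
    log2fc[g] <- fit$beta[[dm$condition_col]] / log(2)
    se[g] <- wt$se / log(2)
    z[g] <- wt$z
    p[g] <- wt$p
  }
  padj <- rep(NA_real_, ng)
  padj[conv] <- bh_adjust(p[conv])
  res <- list(table = data.frame(gene = rownames(counts),
                                 baseMean = base_mean,
                                 log2fc = log2fc, se = se, wald_z = z,
                                 pvalue = p, padj = padj,
                                 row.names = NULL,
                                 stringsAsFactors = FALSE),
              size_factors = sf, dispersions = alpha,
              n_filtered = n_filtered, n_nonconverged = sum(!conv),
              region = region)
  class(res) <- "dge_result"
  res
}

#' @export
print.dge_result <- function(x, ...) {
  nde <- sum(x$table$padj < 0.05, na.rm = TRUE)
  cat(sprintf("dge_result [%s]: %d genes tested, %d at padj < 0.05 (%d non-converged)\n",
              x$region, nrow(x$table), nde, x$n_nonconverged))
  invisible(x)
}

#' Cross-region Spearman concordance of log2 fold changes
#'
#' For every pair of regions, the Spearman rank correlation of log2FC over
#' the genes with finite estimates in both results. Pairs sharing fewer
#' than 3 genes get `NA` with a warning.
#'
#' @param results named list of `dge_result` objects, one per region.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
cross_region_spearman <- function(results) {
  if (length(results) < 2L) stopf("need at least two regions")
  regs <- names(results)
  m <- matrix(NA_real_, length(regs), length(regs), dimnames = list(regs, regs))
  diag(m) <- 1
  for (i in seq_along(regs)) for (j in seq_along(regs)) {
    if (j <= i) next
    a <- results[[i]]$table; b <- results[[j]]$table
    common <- intersect(a$gene[is.finite(a$log2fc)], b$gene[is.finite(b$log2fc)])
    if (length(common) < 3L) {
      warnf("regions %s/%s share fewer than 3 genes; correlation set to NA",
            regs[i], regs[j])
      next
    }
    m[i, j] <- m[j, i] <- stats::cor(a$log2fc[match(common, a$gene)],
                                     b$log2fc[match(common, b$gene)],
                                     method = "spearman")
  }
  m
}

#' Intersect per-region differentially expressed gene sets
#'
#' Builds per-region DE sets at `padj < threshold`, counts genes in every
#' region combination (Venn cell counts: genes DE in exactly that set of
#' regions), and reports the genes common to all regions with their
#' per-region log2FC signs.
#'
#' @param results named list of `dge_result` objects.
#' @param threshold adjusted-p cut-off (default 0.05).
#' @return list with `sets` (per-region DE gene vectors), `venn` (named
#'   count vector, names like "A&B"), `common_genes`, `common_signs`
#'   (matrix gene x region of log2FC signs).
#' @export
intersect_de_sets <- function(results, threshold = 0.05) {
  regs <- names(results)
  sets <- lapply(results, function(r) {
    t <- r$table
    t$gene[!is.na(t$padj) & t$padj < threshold]
  })
  all_genes <- unique(unlist(sets))
  memb <- vapply(sets, function(s) all_genes %in% s,
                 logical(length(all_genes)))
  if (length(all_genes) == 1L) memb <- matrix(memb, nrow = 1,
                                              dimnames = list(NULL, regs))
  venn <- c()
  if (length(all_genes) > 0L) {
    key <- apply(memb, 1, function(r) paste(regs[r], collapse = "&"))
    venn <- table(key)
    venn <- stats::setNames(as.integer(venn), names(venn))
  }
  common <- if (length(all_genes)) all_genes[rowSums(memb) == length(regs)]
            else character(0)
  signs <- NULL
  if (length(common)) {
    signs <- vapply(results, function(r)
      sign(r$table$log2fc[match(common, r$table$gene)]),
      numeric(length(common)))
    signs <- matrix(signs, nrow = length(common),
                    dimnames = list(common, regs))
  }
  list(sets = sets, venn = venn, common_genes = common, common_signs = signs)
}
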