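#' Stratified train/test split with train-fitted normalization
#'
#' Log2-transforms the normalized count matrix (`log2(x + 1)`), splits the
#' samples into train and test keeping the class ratio the same in both
#' partitions, and z-normalizes each gene using the mean and standard
#' deviation of the training set only (the same statistics are applied to
#' the test set, so no test information leaks into the features). Genes
#' with zero training variance get unit variance substituted.
#'
#' @param expr numeric matrix of normalized counts, genes x samples.
#' @param labels per-sample class labels with exactly two levels; the
#'   lexicographically larger level (e.g. `CASE` vs `CTRL` maps CASE via
#'   explicit argument) -- see `positive`.
#' @param train_frac fraction of each class assigned to training
#'   (default 0.8).
#' @param seed RNG seed for the split.
#' @param positive label treated as the positive class (+1); default
#'   `"CASE"` when present, else the first label alphabetically.
#' @param log_transform apply `log2(x + 1)` first (default TRUE).
#' @return list with `train` and `test`, each `list(x, y)` where `x` is
#'   samples x genes and `y` in `{-1, +1}`, plus `normalizer`
#'   (`mean`, `sd` per gene) and `n_zero_var`.
#' @export
preprocess_split <- function(expr, labels, train_frac = 0.8, seed = 1L,
                             positive = NULL, log_transform = TRUE) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stopf("need exactly two classes")
  if (any(table(labels) < 2L)) stopf("both classes need >= 2 samples")
  positive <- positive %||% if ("CASE" %in% classes) "CASE" else classes[1]
  y_all <- ifelse(labels == positive, 1, -1)

  x <- t(expr)
  if (log_transform) x <- log2(x + 1)

  set.seed(child_seed(seed, "split"))
  train_idx <- integer(0)
  for (cl in classes) {
    idx <- which(labels == cl)
    n_tr <- round(train_frac * length(idx))
    train_idx <- c(train_idx, sample(idx, n_tr))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(nrow(x)), train_idx)

  mu <- colMeans(x[train_idx, , drop = FALSE])
  sdv <- apply(x[train_idx, , drop = FALSE], 2, stats::sd)
  n_zero <- sum(sdv == 0)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")

  list(train = list(x = xs[train_idx, , drop = FALSE], y = y_all[train_idx]),
       test = list(x = xs[test_idx, , drop = FALSE], y = y_all[test_idx]),
       normalizer = list(mean = mu, sd = sdv),
       n_zero_var = n_zero, positive = positive)
}

#' Gaussian kernel pair restricted to one pathway
#'
#' Restricts the feature matrices to the pathway's genes present in the
#' data and computes `K(x, y) = exp(-||x - y||^2 / (2 sigma^2))` with the
#' bandwidth heuristic `sigma^2 =` mean squared pairwise distance between
#' training samples; the cross (test x train) kernel uses the training
#' bandwidth. Pathways with fewer than `min_genes` expressed genes are
#' rejected with `NULL`.
#'
#' @param train_x samples x genes training matrix.
#' @param test_x samples x genes matrix evaluated against the training
#'   samples (may be `NULL`).
#' @param gene_set character vector of gene ids.
#' @param min_genes minimum genes required (default 3).
#' @param sigma2 optional fixed bandwidth, overriding the heuristic.
#' @return list with `train` (n_train x n_train), `cross`
#'   (n_test x n_train or NULL), `sigma2`, `genes`; or `NULL` when too few
#'   genes are present.
#' @export
pathway_kernel <- function(train_x, test_x = NULL, gene_set,
                           min_genes = 3L, sigma2 = NULL) {
  genes <- intersect(gene_set, colnames(train_x))
  if (length(genes) < min_genes) return(NULL)
  a <- train_x[, genes, drop = FALSE]
  d2 <- as.matrix(stats::dist(a))^2
  if (is.null(sigma2)) {
    off <- d2[upper.tri(d2)]
    sigma2 <- mean(off)
    if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- 1
  }
  ktr <- exp(-d2 / (2 * sigma2))
  kcr <- NULL
  if (!is.null(test_x)) {
    b <- test_x[, genes, drop = FALSE]
    cross_d2 <- outer(rowSums(b^2), rowSums(a^2), "+") - 2 * b %*% t(a)
    cross_d2[cross_d2 < 0] <- 0
    kcr <- exp(-cross_d2 / (2 * sigma2))
  }
  list(train = ktr, cross = kcr, sigma2 = sigma2, genes = genes)
}

# Build train/cross kernels for every usable pathway in a collection.
build_kernel_bundle <- function(train_x, test_x, collection, min_genes = 3L) {
  ks <- lapply(collection, function(s)
    pathway_kernel(train_x, test_x, s, min_genes = min_genes))
  usable <- !vapply(ks, is.null, logical(1))
  list(kernels = ks[usable],
       pathways = names(collection)[usable],
       skipped = names(collection)[!usable])
}

#' Soft-margin SVM dual with a precomputed kernel
#'
#' Thin wrapper around `kernlab::ksvm` (C-classification with a kernel
#' matrix). Labels are coded as a factor with levels `c(-1, 1)` so that
#' positive decision values correspond to the +1 class. When the kernel is
#' not numerically PSD a `1e-8` diagonal jitter is added (flagged).
#'
#' @param K symmetric PSD kernel matrix (n x n).
#' @param y labels in `{-1, +1}`.
#' @param C soft-margin cost.
#' @param tol SMO termination tolerance (KKT violation).
#' @return list with `coef` (signed dual coefficients `alpha_i * y_i`,
#'   full length n), `b` (intercept offset; decision is
#'   `K_new %*% coef - b`), `objective` (dual objective value),
#'   `jittered`.
#' @export
solve_svm_dual <- function(K, y, C, tol = 1e-6) {
  if (!all(y %in% c(-1, 1))) stopf("labels must be -1/+1")
  jitter <- FALSE
  ev_ok <- tryCatch({ chol(K + diag(1e-10, nrow(K))); TRUE },
                    error = function(e) FALSE)
  if (!ev_ok) {
    K <- K + diag(1e-8, nrow(K))
    jitter <- TRUE
  }
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K),
                     factor(y, levels = c(-1, 1)),
                     type = "C-svc", C = C, kernel = "matrix",
                     tol = tol, scaled = FALSE)
  cf <- rep(0, nrow(K))
  cf[unlist(kernlab::alphaindex(m))] <- unlist(kernlab::coef(m))
  b0 <- kernlab::b(m)
  alpha_pos <- cf * y
  obj <- sum(alpha_pos) - 0.5 * drop(crossprod(cf, K %*% cf))
  list(coef = cf, b = b0, objective = obj, jittered = jitter)
}

#' Sparse multiple-kernel-learning weights over pathway kernels
#'
#' Alternating optimization of the simplex-constrained (l1) kernel
#' combination: (a) solve the SVM dual on the current weighted kernel
#' `K_eta = sum_m eta_m K_m`; (b) multiplicative weight update
#' `eta_m <- eta_m * sqrt(a' K_m a)` followed by renormalization onto the
#' simplex. The l1 constraint drives most weights to zero; entries below
#' `1e-6` are clamped to exactly zero. Iterates until
#' `max |delta eta| < tol` or `max_iter`; on non-convergence the iterate
#' with the best (lowest) SVM objective is returned, flagged.
#'
#' @param kernels list of train kernel matrices (one per pathway).
#' @param y labels in `{-1, +1}`.
#' @param C soft-margin cost.
#' @param tol convergence tolerance on the weight change (default 1e-4).
#' @param max_iter alternation cap (default 50).
#' @param selection_threshold weight above which a pathway counts as
#'   selected (default 0.01).
#' @param svm_tol SMO tolerance for the inner dual solves.
#' @return object of class `mkl_model`: `eta` (named simplex weights),
#'   `coef`, `b`, `C`, `selected` (pathway names with
#'   `eta > selection_threshold`), `converged`, `iterations`,
#'   `objective_trace`, `eta_trace` (matrix, one row per iteration).
#' @export
optimize_kernel_weights <- function(kernels, y, C, tol = 1e-4,
                                    max_iter = 50L,
                                    selection_threshold = 0.01,
                                    svm_tol = 1e-6) {
  m_n <- length(kernels)
  if (m_n == 0L) stopf("need at least one usable kernel")
  nm <- names(kernels) %||% sprintf("kernel_%d", seq_len(m_n))
  n <- nrow(kernels[[1]])
  # kernels stacked as columns so combination and the quadratic forms
  # a' K_m a are single BLAS products
  k_flat <- vapply(kernels, as.numeric, numeric(n * n))
  eta <- rep(1 / m_n, m_n)
  best <- NULL
  obj_trace <- numeric(0)
  eta_trace <- matrix(numeric(0), ncol = m_n, dimnames = list(NULL, nm))
  converged <- FALSE
  sol <- NULL
  for (it in seq_len(max_iter)) {
    k_eta <- matrix(k_flat %*% eta, n, n)
    sol <- solve_svm_dual(k_eta, y, C, tol = svm_tol)
    obj_trace <- c(obj_trace, sol$objective)
    eta_trace <- rbind(eta_trace, eta)
    if (is.null(best) || sol$objective <= best$objective)
      best <- list(eta = eta, sol = sol, objective = sol$objective)
    aa <- as.numeric(tcrossprod(sol$coef))
    q <- pmax(0, as.numeric(crossprod(k_flat, aa)))
    new_eta <- eta * sqrt(q)
    if (sum(new_eta) <= 0) { converged <- TRUE; break }
    new_eta <- new_eta / sum(new_eta)
    new_eta[new_eta < 1e-6] <- 0
    new_eta <- new_eta / sum(new_eta)
    delta <- max(abs(new_eta - eta))
    eta <- new_eta
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    eta <- best$eta
    sol <- best$sol
  } else {
    # final fit at the converged weights
    k_eta <- matrix(k_flat %*% eta, n, n)
    sol <- solve_svm_dual(k_eta, y, C, tol = svm_tol)
  }
  names(eta) <- nm
  res <- list(eta = eta, coef = sol$coef, b = sol$b, C = C,
              selected = nm[eta > selection_threshold],
              selection_threshold = selection_threshold,
              converged = converged, iterations = nrow(eta_trace),
              objective_trace = obj_trace, eta_trace = eta_trace)
  class(res) <- "mkl_model"
  res
}

#' @export
print.mkl_model <- function(x, ...) {
  cat(sprintf("mkl_model: C = %g, %d/%d kernels above %.3g (%sconverged in %d iterations)\n",
              x$C, length(x$selected), length(x$eta), x$selection_threshold,
              if (x$converged) "" else "NOT ", x$iterations))
  invisible(x)
}

# Decision values of an mkl_model on cross kernels (test x train).
mkl_decision <- function(model, cross_kernels) {
  kx <- Reduce(`+`, Map(`*`, cross_kernels, model$eta))
  drop(kx %*% model$coef) - model$b
}

# Stratified fold assignment; retried when a fold misses a class.
stratified_folds <- function(y, k, seed) {
  for (try in 0:4) {
    set.seed(child_seed(seed + try, "cv"))
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(y[fold == f])) == 2L, logical(1)))
    if (ok) return(fold)
    warnf("fold with a single class; refolding with a new seed")
  }
  stopf("could not build %d stratified folds with both classes", k)
}

#' Inner cross-validation for the SVM cost C
#'
#' Stratified k-fold cross-validation on the training set: for each
#' candidate C, pathway kernels are rebuilt on each fold's training part,
#' the MKL model is fitted, and the held-out fold is scored by AUC. The C
#' with the highest mean fold AUC wins; ties go to the smallest C.
#'
#' @param x training samples x genes matrix (already normalized).
#' @param y labels in `{-1, +1}`.
#' @param collection named list of pathway gene sets.
#' @param C_grid candidate costs (default `10^(-2:2)`).
#' @param k folds (default 4).
#' @param seed RNG seed for the fold assignment.
#' @param min_genes pathway gene floor for kernels.
#' @param mkl_control list of `tol`/`max_iter` overrides for the inner
#'   fits (defaults are looser than the final fit: tol 1e-3, 20
#'   iterations -- the C ranking is insensitive to the tail of the weight
#'   optimization).
#' @return selected C, with mean fold AUCs attached as attribute
#'   `cv_auc`.
#' @export
inner_cv_select_C <- function(x, y, collection, C_grid = 10^(-2:2),
                              k = 4L, seed = 1L, min_genes = 3L,
                              mkl_control = list()) {
  if (length(C_grid) == 0L) stopf("C_grid must be nonempty")
  C_grid <- sort(C_grid)
  if (length(C_grid) == 1L) return(C_grid)
  tol <- mkl_control$tol %||% 1e-3
  max_iter <- mkl_control$max_iter %||% 20L
  svm_tol <- mkl_control$svm_tol %||% 1e-4
  fold <- stratified_folds(y, k, seed)
  auc_mat <- matrix(NA_real_, k, length(C_grid))
  for (f in seq_len(k)) {
    tr <- fold != f
    bundle <- build_kernel_bundle(x[tr, , drop = FALSE],
                                  x[!tr, , drop = FALSE],
                                  collection, min_genes)
    if (length(bundle$kernels) == 0L) stopf("no usable kernels in CV fold")
    ktr <- lapply(bundle$kernels, `[[`, "train")
    kcr <- lapply(bundle$kernels, `[[`, "cross")
    for (ci in seq_along(C_grid)) {
      model <- optimize_kernel_weights(ktr, y[tr], C_grid[ci], tol = tol,
                                       max_iter = max_iter,
                                       svm_tol = svm_tol)
      auc_mat[f, ci] <- auc(mkl_decision(model, kcr), y[!tr])
    }
  }
  mean_auc <- colMeans(auc_mat)
  best <- C_grid[which.max(mean_auc)]  # which.max takes the first (smallest) tie
  attr(best, "cv_auc") <- stats::setNames(mean_auc, C_grid)
  best
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with ties counted one half.
#'
#' @param scores numeric decision values.
#' @param labels labels in `{-1, +1}` (or logical/two-level).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  pos <- labels == 1 | labels == TRUE
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stopf("AUC undefined with a single class")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Replicated MKL experiment with selection frequencies
#'
#' The full protocol: for each replication, a stratified 80/20 split with
#' train-only normalization, inner k-fold cross-validation for C on the
#' training part, an MKL fit on the whole training set, test-set AUC, and
#' the kernel weight vector. Replication r uses child seed `seed + r`, so
#' any single replication can be re-run exactly. Aggregates mean and sd of
#' the test AUC and, per pathway, the number of replications in which its
#' weight exceeded `selection_threshold`; pathways selected in at least
#' half the replications are reported as informative.
#'
#' @param expr numeric matrix of normalized counts, genes x samples.
#' @param labels per-sample class labels (two levels).
#' @param collection named list of pathway gene sets.
#' @param n_replications outer replications (default 100).
#' @param seed root seed.
#' @param train_frac training fraction (default 0.8).
#' @param C_grid candidate costs for the inner CV.
#' @param inner_k inner CV folds (default 4).
#' @param selection_threshold kernel-weight selection cut-off
#'   (default 0.01).
#' @param min_genes pathway gene floor.
#' @param mkl_control list of `tol`/`max_iter` overrides for the final
#'   per-replication fit; an optional `cv` sub-list is forwarded to
#'   [inner_cv_select_C()].
#' @return object of class `mkl_report`: `replications` (data.frame rep,
#'   seed, C, auc), `eta` (matrix rep x pathway), `selection_counts`,
#'   `selection_frequency`, `informative` (selected in >= half the
#'   replications), `mean_auc`, `sd_auc`, `n_failed`, `skipped_pathways`.
#' @export
replicate_experiment <- function(expr, labels, collection,
                                 n_replications = 100L, seed = 1L,
                                 train_frac = 0.8, C_grid = 10^(-2:2),
                                 inner_k = 4L, selection_threshold = 0.01,
                                 min_genes = 3L, mkl_control = list()) {
  tol <- mkl_control$tol %||% 1e-4
  max_iter <- mkl_control$max_iter %||% 50L
  reps <- list()
  etas <- list()
  skipped <- character(0)
  n_failed <- 0L
  for (r in seq_len(n_replications)) {
    rseed <- seed + r
    res <- tryCatch({
      sp <- preprocess_split(expr, labels, train_frac = train_frac,
                             seed = rseed)
      bundle <- build_kernel_bundle(sp$train$x, sp$test$x, collection,
                                    min_genes)
      if (length(bundle$kernels) == 0L) stopf("no usable pathway kernels")
      skipped <- union(skipped, bundle$skipped)
      C <- inner_cv_select_C(sp$train$x, sp$train$y, collection,
                             C_grid = C_grid, k = inner_k, seed = rseed,
                             min_genes = min_genes,
                             mkl_control = mkl_control$cv %||% list())
      model <- optimize_kernel_weights(lapply(bundle$kernels, `[[`, "train"),
                                       sp$train$y, as.numeric(C), tol = tol,
                                       max_iter = max_iter,
                                       selection_threshold = selection_threshold)
      names(model$eta) <- bundle$pathways
      f_test <- mkl_decision(model, lapply(bundle$kernels, `[[`, "cross"))
      list(C = as.numeric(C), auc = auc(f_test, sp$test$y), eta = model$eta)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warnf("replication %d failed: %s", r, conditionMessage(res))
      n_failed <- n_failed + 1L
      next
    }
    reps[[length(reps) + 1L]] <- data.frame(rep = r, seed = rseed,
                                            C = res$C, auc = res$auc)
    etas[[length(etas) + 1L]] <- res$eta
  }
  if (length(reps) == 0L) stopf("all replications failed")
  rep_df <- do.call(rbind, reps)
  pw <- sort(unique(unlist(lapply(etas, names))))
  eta_mat <- t(vapply(etas, function(e) {
    out <- stats::setNames(rep(0, length(pw)), pw)
    out[names(e)] <- e
    out
  }, numeric(length(pw))))
  sel_counts <- colSums(eta_mat > selection_threshold)
  n_ok <- nrow(rep_df)
  report <- list(replications = rep_df, eta = eta_mat,
                 selection_counts = sel_counts,
                 selection_frequency = sel_counts / n_ok,
                 informative = names(sel_counts)[sel_counts >= n_ok / 2],
                 mean_auc = mean(rep_df$auc),
                 sd_auc = stats::sd(rep_df$auc),
                 n_replications = n_replications, n_failed = n_failed,
                 selection_threshold = selection_threshold,
                 skipped_pathways = skipped)
  class(report) <- "mkl_report"
  report
}

#' @export
print.mkl_report <- function(x, ...) {
  cat(sprintf("mkl_report: %d replication(s), mean AUC %.3f (sd %.3f); %d pathway(s) informative (>= half of replications)\n",
              nrow(x$replications), x$mean_auc,
              if (is.na(x$sd_auc)) 0 else x$sd_auc, length(x$informative)))
  if (length(x$informative))
    cat("  informative:", paste(x$informative, collapse = ", "), "\n")
  invisible(x)
}
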