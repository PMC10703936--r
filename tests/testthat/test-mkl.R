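toy_expr <- function(n_genes = 40, n = 60, seed = 1) {
  set.seed(seed)
  matrix(rpois(n_genes * n, 60), n_genes, n,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n))))
}

test_that("the stratified split is exact and the normalizer train-fitted", {
  expr <- toy_expr(30, 100)
  labels <- rep(c("CTRL", "CASE"), 50)
  sp <- preprocess_split(expr, labels, train_frac = 0.8, seed = 5)
  expect_equal(sum(sp$train$y == 1), 40)
  expect_equal(sum(sp$train$y == -1), 40)
  expect_equal(sum(sp$test$y == 1), 10)
  expect_equal(sum(sp$test$y == -1), 10)

  expect_equal(unname(colMeans(sp$train$x)), rep(0, 30), tolerance = 1e-12)
  expect_equal(unname(apply(sp$train$x, 2, sd)), rep(1, 30),
               tolerance = 1e-12)

  sp2 <- preprocess_split(expr, labels, train_frac = 0.8, seed = 6)
  expect_false(identical(rownames(sp$train$x), rownames(sp2$train$x)))
  expect_equal(table(sp2$train$y), table(sp$train$y))
})

test_that("test-set statistics never leak into the training features", {
  expr <- toy_expr(20, 40, seed = 2)
  labels <- rep(c("CTRL", "CASE"), 20)
  sp <- preprocess_split(expr, labels, seed = 3)
  # make one gene constant in train but wildly variable in test
  expr2 <- expr
  test_samples <- rownames(sp$test$x)
  train_samples <- rownames(sp$train$x)
  expr2["g01", train_samples] <- 64L
  sp_a <- preprocess_split(expr2, labels, seed = 3)
  expect_equal(sp_a$n_zero_var, 1)
  expr3 <- expr2
  expr3["g01", test_samples] <- as.integer(expr2["g01", test_samples] * 5L)
  sp_b <- preprocess_split(expr3, labels, seed = 3)
  expect_identical(sp_a$train$x, sp_b$train$x)
  k_a <- pathway_kernel(sp_a$train$x, NULL, c("g01", "g02", "g03"))
  k_b <- pathway_kernel(sp_b$train$x, NULL, c("g01", "g02", "g03"))
  expect_identical(k_a$train, k_b$train)
})

test_that("pathway kernels are Gaussian with the mean-distance bandwidth", {
  x <- matrix(c(0, 0, 1, 0, 0, 2), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("g1", "g2")))
  k <- pathway_kernel(x, NULL, c("g1", "g2"), min_genes = 2, sigma2 = 1)
  expect_equal(unname(diag(k$train)), rep(1, 3))
  expect_equal(k$train["a", "b"], exp(-1 / 2))
  expect_equal(k$train["a", "c"], exp(-4 / 2))
  expect_equal(k$train["b", "c"], exp(-5 / 2))

  # bandwidth heuristic: mean squared pairwise distance
  k2 <- pathway_kernel(x, NULL, c("g1", "g2"), min_genes = 2)
  expect_equal(k2$sigma2, mean(c(1, 4, 5)))

  # huge bandwidth saturates toward 1
  k3 <- pathway_kernel(x, NULL, c("g1", "g2"), min_genes = 2, sigma2 = 1e9)
  expect_true(all(k3$train > 0.999))

  expect_null(pathway_kernel(x, NULL, c("g1", "zz"), min_genes = 2))

  # cross kernel evaluates test rows against train columns
  k4 <- pathway_kernel(x, x[1:2, , drop = FALSE], c("g1", "g2"),
                       min_genes = 2, sigma2 = 1)
  expect_equal(k4$cross, k4$train[1:2, ], ignore_attr = TRUE)
})

test_that("the SVM dual recovers the two-point maximum margin solution", {
  x <- rbind(c(1, 0), c(-1, 0))
  y <- c(1, -1)
  K <- x %*% t(x)
  sol <- solve_svm_dual(K, y, C = 10)
  # maximum margin: w = (1, 0), alpha = 0.5 for both points, bias 0
  expect_equal(sol$coef, c(0.5, -0.5), tolerance = 1e-3)
  expect_equal(sol$b, 0, tolerance = 1e-3)
  f <- drop(K %*% sol$coef) - sol$b
  expect_equal(f, c(1, -1), tolerance = 1e-3)

  # C -> 0: coefficients bounded by C, decision collapses
  set.seed(31)
  n <- 20
  xb <- matrix(rnorm(2 * n), n, 2)
  yb <- rep(c(-1, 1), n / 2)
  Kb <- xb %*% t(xb)
  sol0 <- solve_svm_dual(Kb, yb, C = 1e-4)
  expect_true(all(abs(sol0$coef) <= 1e-4 + 1e-12))
})

test_that("duplicating training samples leaves the decision unchanged", {
  set.seed(32)
  n <- 30
  x <- matrix(rnorm(2 * n), n, 2)
  y <- ifelse(x[, 1] + 0.3 * rnorm(n) > 0, 1, -1)
  xt <- matrix(rnorm(20), 10, 2)
  K <- x %*% t(x); Kt <- xt %*% t(x)
  sol <- solve_svm_dual(K, y, C = 1)
  f1 <- drop(Kt %*% sol$coef) - sol$b

  x2 <- rbind(x, x); y2 <- c(y, y)
  K2 <- x2 %*% t(x2); Kt2 <- xt %*% t(x2)
  sol2 <- solve_svm_dual(K2, y2, C = 0.5)  # halve C to keep the same margin
  f2 <- drop(Kt2 %*% sol2$coef) - sol2$b
  expect_equal(f1, f2, tolerance = 0.05)
  expect_gt(cor(f1, f2), 0.9999)
})

test_that("AUC follows the Mann-Whitney pair count with half ties", {
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(-1, -1, 1, 1)), 1)
  expect_equal(auc(rep(0.5, 6), rep(c(-1, 1), 3)), 0.5)
  expect_equal(auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, -1, -1)), 0.75)
  expect_error(auc(1:3, c(1, 1, 1)), "single class")
})

test_that("kernel weights live on the simplex and find the informative kernel", {
  set.seed(33)
  n <- 60
  y <- rep(c(-1, 1), each = n / 2)
  informative <- matrix(rnorm(n * 3, mean = y), n, 3,
                        dimnames = list(NULL, c("f1", "f2", "f3")))
  ks <- c(list(pathway_kernel(informative, NULL, c("f1", "f2", "f3"))$train),
          lapply(1:9, function(i)
            pathway_kernel(matrix(rnorm(n * 3), n, 3,
                                  dimnames = list(NULL, c("f1", "f2", "f3"))),
                           NULL, c("f1", "f2", "f3"))$train))
  names(ks) <- c("signal", sprintf("noise%d", 1:9))
  model <- optimize_kernel_weights(ks, y, C = 1)
  expect_true(all(model$eta >= 0))
  expect_equal(sum(model$eta), 1, tolerance = 1e-12)
  # every iterate stays on the simplex
  expect_true(all(model$eta_trace >= 0))
  expect_equal(unname(rowSums(model$eta_trace)),
               rep(1, nrow(model$eta_trace)), tolerance = 1e-12)
  expect_gte(model$eta[["signal"]], 0.5)
  expect_gte(sum(model$eta[-1] < 0.01), 8)
  expect_setequal(model$selected,
                  names(model$eta)[model$eta > model$selection_threshold])
  # SVM objective is non-increasing along the alternation
  expect_true(all(diff(model$objective_trace) <= 1e-6))

  single <- optimize_kernel_weights(ks[1], y, C = 1)
  expect_equal(unname(single$eta), 1)

  twin <- optimize_kernel_weights(list(a = ks[[1]], b = ks[[1]]), y, C = 1)
  expect_equal(unname(twin$eta), c(0.5, 0.5), tolerance = 1e-8)
})

test_that("inner cross-validation is stratified, 4-fold and deterministic", {
  y <- rep(c(-1, 1), each = 20)
  fold <- pathexpr:::stratified_folds(y, 4, seed = 7)
  expect_equal(as.vector(table(fold)), rep(10L, 4))
  for (f in 1:4) expect_setequal(unique(y[fold == f]), c(-1, 1))

  expect_equal(inner_cv_select_C(NULL, NULL, NULL, C_grid = 0.5), 0.5)

  cfg <- mkl_config(seed = 9, n_genes = 200)
  cfg$n_samples_per_region <- list(A = c(30L, 30L))
  cfg$pathway_specs$n_pathways <- 8L
  pw <- generate_pathways(cfg)
  meta <- generate_metadata(cfg)
  sim <- generate_counts(cfg, meta, pw)
  norm <- sweep(sim$counts, 2, estimate_size_factors(sim$counts), "/")
  sp <- preprocess_split(norm, meta$condition, seed = 4)
  c1 <- inner_cv_select_C(sp$train$x, sp$train$y, pw,
                          C_grid = c(0.01, 1, 100), seed = 11)
  c2 <- inner_cv_select_C(sp$train$x, sp$train$y, pw,
                          C_grid = c(0.01, 1, 100), seed = 11)
  expect_equal(as.numeric(c1), as.numeric(c2))
  expect_length(attr(c1, "cv_auc"), 3)
})

test_that("a single-replication report reduces to one split", {
  cfg <- mkl_config(seed = 10, n_genes = 150)
  cfg$n_samples_per_region <- list(A = c(25L, 25L))
  cfg$pathway_specs$n_pathways <- 6L
  cfg$pathway_specs$informative_pathway_ids <- 1L
  pw <- generate_pathways(cfg)
  meta <- generate_metadata(cfg)
  sim <- generate_counts(cfg, meta, pw)
  norm <- sweep(sim$counts, 2, estimate_size_factors(sim$counts), "/")
  rep1 <- replicate_experiment(norm, meta$condition, pw,
                               n_replications = 1, seed = 2,
                               C_grid = c(0.1, 1))
  expect_equal(nrow(rep1$replications), 1)
  expect_equal(rep1$sd_auc, NA_real_)
  expect_true(all(rep1$selection_counts %in% c(0L, 1L)))
  expect_true(rep1$mean_auc >= 0 && rep1$mean_auc <= 1)
  expect_equal(rep1$replications$seed, 3)  # root seed + replication index
})
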