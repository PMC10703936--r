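make_counts <- function(mat, genes = NULL, samples = NULL) {
  genes <- genes %||% sprintf("g%02d", seq_len(nrow(mat)))
  samples <- samples %||% sprintf("s%02d", seq_len(ncol(mat)))
  matrix(as.integer(mat), nrow(mat), ncol(mat),
         dimnames = list(genes, samples))
}

test_that("size factors follow the median-of-ratios convention", {
  m <- make_counts(matrix(c(10, 20, 5, 10, 20, 5), 3, 2))
  expect_equal(unname(estimate_size_factors(m)), c(1, 1))

  m2 <- make_counts(cbind(c(10, 20, 5), c(20, 40, 10)))
  expect_equal(unname(estimate_size_factors(m2)),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # scaling one column scales its factor (up to the geometric-mean-1
  # rescale shared by all samples)
  set.seed(1)
  m3 <- make_counts(matrix(rpois(60, 50), 10, 6))
  sf <- estimate_size_factors(m3)
  m4 <- m3; m4[, 3] <- m4[, 3] * 4L
  sf2 <- estimate_size_factors(m4)
  rel <- sf2 / sf
  expect_equal(unname(rel[3] / rel[1]), 4, tolerance = 1e-9)

  zeros <- make_counts(rbind(c(5L, 0L), c(0L, 5L)))
  expect_error(estimate_size_factors(zeros), "pseudocount")
  expect_length(estimate_size_factors(zeros, on_zero = "pseudocount"), 2)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))

  set.seed(7)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }

  p <- c(0.01, NA, 0.5)
  out <- bh_adjust(p)
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], bh_oracle(p[c(1, 3)]))
})

test_that("the NB GLM reduces to Poisson closed forms at zero dispersion", {
  set.seed(2)
  y <- rpois(20, 40)
  sf <- exp(rnorm(20, 0, 0.2)); sf <- sf / exp(mean(log(sf)))
  X <- matrix(1, 20, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_nb_glm(y, sf, X, alpha = 0)
  expect_true(fit$converged)
  # Poisson intercept-only with offsets: exp(beta) = sum(y) / sum(sf)
  expect_equal(unname(fit$beta[1]), log(sum(y) / sum(sf)), tolerance = 1e-6)

  grp <- rep(0:1, each = 10)
  X2 <- cbind(`(Intercept)` = 1, grp = grp)
  sf1 <- rep(1, 20)
  fit2 <- fit_nb_glm(y, sf1, X2, alpha = 0)
  expect_equal(unname(fit2$beta[1]), log(mean(y[grp == 0])), tolerance = 1e-6)
  expect_equal(unname(fit2$beta[1] + fit2$beta[2]), log(mean(y[grp == 1])),
               tolerance = 1e-6)
})

test_that("the NB GLM agrees with an independent fixed-theta glm fit", {
  skip_if_not_installed("MASS")
  set.seed(3)
  n <- 60
  sf <- exp(rnorm(n, 0, 0.3)); sf <- sf / exp(mean(log(sf)))
  x1 <- rnorm(n)
  grp <- rep(0:1, each = n / 2)
  mu <- sf * exp(3 + 0.7 * grp + 0.3 * x1)
  alpha <- 0.15
  y <- rnbinom(n, mu = mu, size = 1 / alpha)
  X <- cbind(`(Intercept)` = 1, grp = grp, x1 = x1)
  fit <- fit_nb_glm(y, sf, X, alpha = alpha)
  ref <- stats::glm(y ~ grp + x1 + offset(log(sf)),
                    family = MASS::negative.binomial(theta = 1 / alpha,
                                                     link = "log"))
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-5)
  se_ref <- summary(ref, dispersion = 1)$coefficients[, "Std. Error"]
  expect_equal(sqrt(diag(fit$cov)), unname(se_ref),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("planted log2 fold changes are recovered without bias", {
  set.seed(4)
  n <- 400  # 200 per group
  grp <- rep(0:1, each = n / 2)
  X <- cbind(`(Intercept)` = 1, grp = grp)
  sf <- rep(1, n)
  ests <- vapply(1:100, function(i) {
    mu <- exp(4 + log(2) * grp)
    y <- rnbinom(n, mu = mu, size = 1 / 0.1)
    fit <- fit_nb_glm(y, sf, X, alpha = 0.1)
    fit$beta[["grp"]] / log(2)
  }, numeric(1))
  expect_gt(mean(ests), 0.9)
  expect_lt(mean(ests), 1.1)
})

test_that("Wald test converts coefficients to calibrated p-values", {
  cov <- matrix(c(0.04, 0, 0, 0.04), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(wald_test(c(a = 0, b = 1), cov, "a")$p, 1)
  z_crit <- 1.959964
  wt <- wald_test(c(a = z_crit * 0.2, b = 0), cov, "a")
  expect_equal(wt$p, 0.05, tolerance = 1e-6)
  bad <- wald_test(c(a = 1), matrix(0, 1, 1, dimnames = list("a", "a")), "a")
  expect_false(bad$ok)

  # type-I calibration on simulated null genes
  set.seed(5)
  n <- 50
  X <- cbind(`(Intercept)` = 1, grp = rep(0:1, each = n / 2))
  ps <- vapply(1:2000, function(i) {
    y <- rnbinom(n, mu = 50, size = 1 / 0.1)
    fit <- fit_nb_glm(y, rep(1, n), X, alpha = 0.1)
    wald_test(fit$beta, fit$cov, "grp")$p
  }, numeric(1))
  rate <- mean(ps < 0.05)
  ci_half <- 1.96 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(rate, 0.05 + ci_half + 0.01)
})

test_that("Wald statistics are stable under rescaling a sample column", {
  # the size factor absorbs the depth change; the statistics are only
  # asymptotically invariant (scaled counts are no longer exactly NB),
  # so near-invariance is asserted rather than bit equality
  cfg <- null_cohort_config(seed = 21, n_genes = 60, n_per_arm = 12)
  meta <- generate_metadata(cfg)
  sim <- generate_counts(cfg, meta, NULL)
  r1 <- run_region_dge(sim$counts, meta, design_spec(), region = "pooled")
  scaled <- sim$counts
  scaled[, 5] <- scaled[, 5] * 3L
  r2 <- run_region_dge(scaled, meta, design_spec(), region = "pooled")
  common <- intersect(r1$table$gene, r2$table$gene)
  expect_gt(length(common), 50)
  z1 <- r1$table$wald_z[match(common, r1$table$gene)]
  z2 <- r2$table$wald_z[match(common, r2$table$gene)]
  expect_lt(max(abs(z1 - z2)), 0.15)
  expect_lt(median(abs(z1 - z2)), 0.02)
  expect_gt(cor(z1, z2), 0.999)
  # the size-factor absorption itself is exact
  expect_equal(unname(r2$size_factors[5] / r1$size_factors[5] /
                        (r2$size_factors[1] / r1$size_factors[1])),
               3, tolerance = 1e-9)
})

test_that("a batch effect is absorbed when the dataset covariate is modeled", {
  # plant a strong dataset effect correlated with condition, no true
  # condition effect; omitting the covariate must inflate discoveries
  set.seed(6)
  n <- 60
  meta <- data.frame(sample = sprintf("s%02d", 1:n),
                     condition = rep(c("CTRL", "CASE"), each = n / 2),
                     dataset = c(rep("ds1", 20), rep("ds2", 10),
                                 rep("ds1", 10), rep("ds2", 20)),
                     region = "A", stringsAsFactors = FALSE)
  ngene <- 300
  batch <- ifelse(meta$dataset == "ds2", 1, 0)
  bg <- rnorm(ngene, 0, 1)
  mu <- exp(4 + bg %o% batch)
  counts <- matrix(rnbinom(ngene * n, mu = mu, size = 50), ngene, n,
                   dimnames = list(sprintf("g%03d", 1:ngene), meta$sample))
  with_cov <- run_region_dge(counts, meta, design_spec(covariates = "dataset"),
                             region = "A")
  without_cov <- run_region_dge(counts, meta,
                                design_spec(covariates = character(0)),
                                region = "A")
  n_with <- sum(with_cov$table$padj < 0.05, na.rm = TRUE)
  n_without <- sum(without_cov$table$padj < 0.05, na.rm = TRUE)
  expect_lte(n_with, 0.05 * ngene)
  expect_gt(n_without, n_with)
})

test_that("rank-deficient designs fail with a named-column error", {
  cfg <- null_cohort_config(seed = 22, n_genes = 30, n_per_arm = 8)
  meta <- generate_metadata(cfg)
  meta$copy <- meta$age
  sim <- generate_counts(cfg, meta, NULL)
  expect_error(run_region_dge(sim$counts, meta,
                              design_spec(covariates = c("age", "copy")),
                              region = "pooled"),
               "rank deficient")
})

fake_dge <- function(genes, padj, log2fc = rep(-1, length(genes)),
                     region = "X") {
  structure(list(table = data.frame(gene = genes, baseMean = 10,
                                    log2fc = log2fc, se = 0.1,
                                    wald_z = log2fc / 0.1,
                                    pvalue = padj, padj = padj,
                                    stringsAsFactors = FALSE),
                 region = region),
            class = "dge_result")
}

test_that("cross-region Spearman concordance behaves as a rank statistic", {
  g <- sprintf("g%02d", 1:20)
  set.seed(8)
  lfc <- rnorm(20)
  a <- fake_dge(g, runif(20), log2fc = lfc)
  b <- fake_dge(g, runif(20), log2fc = exp(lfc))  # monotone transform
  m <- cross_region_spearman(list(A = a, B = b))
  expect_equal(diag(m), c(A = 1, B = 1))
  expect_equal(m["A", "B"], 1)
  expect_equal(m, t(m))

  # independent null fits decorrelate
  c2 <- fake_dge(g, runif(20), log2fc = rnorm(20))
  m2 <- cross_region_spearman(list(A = a, C = c2))
  expect_lt(abs(m2["A", "C"]), 0.6)

  few <- fake_dge(g[1:2], runif(2), log2fc = lfc[1:2])
  expect_warning(m3 <- cross_region_spearman(list(A = a, F = few)),
                 "fewer than 3")
  expect_true(is.na(m3["A", "F"]))
})

test_that("DE-set intersection reports Venn cells, common genes and signs", {
  g <- sprintf("g%02d", 1:10)
  a <- fake_dge(g, c(0.01, rep(0.9, 9)))
  b <- fake_dge(g, c(0.9, 0.01, rep(0.9, 8)))
  out <- intersect_de_sets(list(A = a, B = b))
  expect_length(out$common_genes, 0)
  expect_equal(unname(out$venn[["A"]]), 1)
  expect_equal(unname(out$venn[["B"]]), 1)

  shared <- fake_dge(g, c(0.001, rep(0.9, 9)), log2fc = c(-2, rnorm(9)))
  out2 <- intersect_de_sets(list(A = shared, B = shared, C = shared))
  expect_equal(out2$common_genes, "g01")
  expect_true(all(out2$common_signs["g01", ] == -1))

  out3 <- intersect_de_sets(list(A = a, B = b), threshold = 1.0)
  expect_setequal(out3$common_genes, g)
})
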