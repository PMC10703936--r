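#' One-sided Fisher exact test for gene-set overrepresentation
#'
#' Builds the 2x2 table for a query gene list against one pathway within a
#' background universe (`a` = overlap, `b` = query-only, `c` = pathway-only
#' with the pathway first restricted to the background, `d` = the rest) and
#' returns the one-sided enrichment p-value as the hypergeometric upper
#' tail `P(X >= a)`.
#'
#' @param query character vector of gene ids (must lie in `background`).
#' @param pathway character vector of gene ids; members outside the
#'   background are ignored.
#' @param background character vector, the gene universe.
#' @return list with `p`, `table` (2x2 integer matrix), `overlap_genes`,
#'   `set_size` (pathway size within the background).
#' @export
fisher_ora <- function(query, pathway, background) {
  if (length(background) == 0L) stopf("empty background universe")
  background <- unique(background)
  query <- unique(query)
  if (!all(query %in% background))
    stopf("query contains genes outside the background universe")
  pw <- intersect(unique(pathway), background)
  a <- length(intersect(query, pw))
  n_q <- length(query)
  big_k <- length(pw)
  big_n <- length(background)
  b <- n_q - a
  cc <- big_k - a
  d <- big_n - n_q - big_k + a
  p <- stats::phyper(a - 1, big_k, big_n - big_k, n_q, lower.tail = FALSE)
  tab <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE,
                dimnames = list(c("query", "not_query"),
                                c("in_set", "not_in_set")))
  list(p = p, table = tab, overlap_genes = sort(intersect(query, pw)),
       set_size = big_k)
}

#' Odds ratio of a 2x2 overlap table
#'
#' `(a*d)/(b*c)`; when any cell is zero all cells get the Haldane 0.5
#' correction (flagged in the `haldane` attribute).
#'
#' @param table 2x2 matrix as produced by [fisher_ora()].
#' @return non-negative odds ratio.
#' @export
odds_ratio <- function(table) {
  t0 <- as.numeric(table)
  hald <- any(t0 == 0)
  if (hald) t0 <- t0 + 0.5
  or <- (t0[1] * t0[4]) / (t0[2] * t0[3])
  attr(or, "haldane") <- hald
  or
}

#' Combined enrichment score
#'
#' `c = -ln(p) * z`, the product of the Fisher significance and a
#' deviation z-score describing how much better the pathway ranked than
#' expected for a random query of the same size. Negative products are
#' floored at zero so a worse-than-expected pathway scores 0. A zero
#' p-value is clamped to the smallest positive double with a warning.
#'
#' @param p Fisher p-value.
#' @param z deviation score (see [run_ora()] for the resampling estimate;
#'   a `log(odds ratio)` fallback is also accepted).
#' @return non-negative combined score.
#' @export
combined_score <- function(p, z) {
  if (any(p == 0)) {
    warnf("p = 0 clamped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  pmax(0, -log(p) * z)
}

# Vectorized overlap counts and Fisher p for all pathways at once.
ora_all_pathways <- function(query, collection, background) {
  memb <- lapply(collection, function(s) intersect(unique(s), background))
  big_k <- vapply(memb, length, integer(1))
  a <- vapply(memb, function(s) length(intersect(query, s)), integer(1))
  big_n <- length(background)
  n_q <- length(query)
  p <- stats::phyper(a - 1, big_k, big_n - big_k, n_q, lower.tail = FALSE)
  list(a = a, K = big_k, p = p)
}

#' Overrepresentation analysis of a query list against a collection
#'
#' Per-pathway Fisher p (one-sided), BH adjustment over the whole
#' collection, odds ratio, and combined score. The deviation z behind the
#' combined score is estimated by resampling: `n_resample` random queries
#' of the same size are drawn from the background, each pathway's p-value
#' rank is recorded, and `z = (mean null rank - observed rank) / sd(null
#' rank)` (positive when the pathway ranks better than chance). Setting
#' `score_mode = "logOR"` replaces the resampled z by `log(odds ratio)`.
#' The result table is sorted by combined score and truncated to `top_k`;
#' a gene-gene co-occurrence edge list over those top pathways is emitted
#' (edge weight = number of top pathways containing both genes), together
#' with the count of query genes absent from every pathway.
#'
#' @param query character vector of gene ids.
#' @param collection named list of pathways (gene-id vectors).
#' @param background gene universe (default: union of collection and
#'   query).
#' @param top_k rows kept in the ranked table (default 10).
#' @param n_resample random queries for the z estimate (default 200).
#' @param seed RNG seed for the resampling.
#' @param score_mode `"resample"` (default) or `"logOR"`.
#' @return list of class `ora_result`: `table` (Pathway, Overlap, k, K, P,
#'   Padj, OddsRatio, Z, CombinedScore, Genes), `edges` (gene_a, gene_b,
#'   weight), `n_uncovered`, `background_size`.
#' @export
run_ora <- function(query, collection, background = NULL, top_k = 10L,
                    n_resample = 200L, seed = 1L,
                    score_mode = c("resample", "logOR")) {
  score_mode <- match.arg(score_mode)
  if (length(collection) == 0L) stopf("empty pathway collection")
  background <- unique(background %||% union(unlist(collection), query))
  query <- unique(intersect(query, background))
  if (length(query) == 0L) stopf("query does not intersect the background")

  obs <- ora_all_pathways(query, collection, background)
  padj <- bh_adjust(obs$p)
  ors <- z <- numeric(length(collection))
  genes_str <- character(length(collection))
  for (i in seq_along(collection)) {
    fo <- fisher_ora(query, collection[[i]], background)
    ors[i] <- as.numeric(odds_ratio(fo$table))
    genes_str[i] <- paste(fo$overlap_genes, collapse = ",")
  }
  if (score_mode == "resample") {
    set.seed(child_seed(seed, "resample"))
    obs_rank <- rank(obs$p, ties.method = "average")
    null_ranks <- matrix(0, n_resample, length(collection))
    for (r in seq_len(n_resample)) {
      rq <- sample(background, length(query))
      null_ranks[r, ] <- rank(ora_all_pathways(rq, collection, background)$p,
                              ties.method = "average")
    }
    mu <- colMeans(null_ranks)
    sdv <- apply(null_ranks, 2, stats::sd)
    sdv[sdv == 0] <- 1
    z <- (mu - obs_rank) / sdv
  } else {
    z <- log(pmax(ors, .Machine$double.xmin))
  }
  cs <- combined_score(obs$p, z)

  tab <- data.frame(Pathway = names(collection),
                    Overlap = sprintf("%d/%d", obs$a, obs$K),
                    k = obs$a, K = obs$K,
                    P = obs$p, Padj = padj, OddsRatio = ors, Z = z,
                    CombinedScore = cs, Genes = genes_str,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$CombinedScore, tab$P), , drop = FALSE]
  rownames(tab) <- NULL
  top <- utils::head(tab, top_k)

  # co-occurrence of query genes across the top pathways
  edges <- data.frame(gene_a = character(0), gene_b = character(0),
                      weight = integer(0), stringsAsFactors = FALSE)
  top_sets <- lapply(collection[top$Pathway], function(s)
    intersect(intersect(s, background), query))
  cov_genes <- sort(unique(unlist(top_sets)))
  if (length(cov_genes) >= 2L) {
    inc <- vapply(top_sets, function(s) cov_genes %in% s,
                  logical(length(cov_genes)))
    w <- inc %*% t(inc)
    idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
    if (nrow(idx)) {
      edges <- data.frame(gene_a = cov_genes[idx[, 1]],
                          gene_b = cov_genes[idx[, 2]],
                          weight = as.integer(w[idx]),
                          stringsAsFactors = FALSE)
      edges <- edges[order(-edges$weight, edges$gene_a, edges$gene_b), ]
      rownames(edges) <- NULL
    }
  }
  covered <- unique(unlist(lapply(collection, intersect, y = query)))
  res <- list(table = top, full_table = tab, edges = edges,
              n_uncovered = length(setdiff(query, covered)),
              background_size = length(background))
  class(res) <- "ora_result"
  res
}

#' @export
print.ora_result <- function(x, ...) {
  cat(sprintf("ora_result: %d pathway(s) scored, background %d; %d query gene(s) in no pathway\n",
              nrow(x$full_table), x$background_size, x$n_uncovered))
  print(utils::head(x$table[, c("Pathway", "Overlap", "Padj", "OddsRatio",
                                "CombinedScore")], 10))
  invisible(x)
}
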