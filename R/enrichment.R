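#' Rank genes by their strongest moderated t-statistic
#'
#' Each gene is summarized by the probe t-statistic of largest magnitude
#' among its probes (`summary = "max"`; `"mean"` averages instead). Genes
#' are then ranked by the signed statistic in the chosen direction: for
#' `direction = "north"` rank 1 is the gene most up-regulated in the North
#' (largest t under the North-minus-South contrast); for `"south"`, the
#' most up-regulated in the South. Ties break by gene id so the ranking is
#' deterministic.
#'
#' @param stats per-probe statistics with a `t` column.
#' @param probe_gene data frame mapping `probe_id` to `gene_id` (rows with
#'   missing gene are ignored).
#' @param direction `"north"` or `"south"`.
#' @param summary per-gene probe summary, `"max"` (largest |t|) or
#'   `"mean"`.
#' @return data frame (`gene_id`, `t`, `rank`) sorted by rank; ranks are a
#'   permutation of `1..N`.
#' @export
rank_genes <- function(stats, probe_gene, direction = c("north", "south"),
                       summary = c("max", "mean")) {
  direction <- match.arg(direction)
  summary <- match.arg(summary)
  m <- merge(stats[, c("probe_id", "t")], probe_gene, by = "probe_id")
  m <- m[!is.na(m$gene_id), ]
  if (!nrow(m)) stopf("no probes map to any gene")
  tt <- tapply(m$t, m$gene_id, function(x) {
    if (summary == "max") x[which.max(abs(x))] else mean(x)
  })
  g <- data.frame(gene_id = names(tt), t = as.numeric(tt),
                  stringsAsFactors = FALSE)
  key <- if (direction == "north") -g$t else g$t
  g <- g[order(key, g$gene_id), ]
  g$rank <- seq_len(nrow(g))
  rownames(g) <- NULL
  g
}

# One-sided lower-tail p-value for the rank sum W of m ranks drawn without
# replacement from 1..N. Exact via the Wilcoxon rank-sum null
# (W - m(m+1)/2 is Mann-Whitney U); normal approximation with continuity
# correction otherwise.
rank_sum_p <- function(W, m, N, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (m * (N - m) <= 2000) "exact" else "normal"
  }
  if (method == "exact") {
    p <- pwilcox(W - m * (m + 1) / 2, m, N - m)
  } else {
    mu <- m * (N + 1) / 2
    sigma <- sqrt(m * (N - m) * (N + 1) / 12)
    p <- pnorm(W + 0.5, mu, sigma)
  }
  min(p, 1)
}

#' Score one gene category on a ranked list
#'
#' The category score is the Wilcoxon rank sum `W` of its member genes'
#' ranks; the one-sided p-value is the probability, under uniformly random
#' assignment of `m` of the `N` ranks, of a rank sum at most `W` — i.e.
#' small p means the category's genes sit unusually high in the ranking.
#'
#' @param ranked ranked gene list from [rank_genes()].
#' @param members character vector of the category's gene ids (must be a
#'   strict, non-empty subset of the ranked genes after intersection).
#' @param method `"exact"` (rank-sum null distribution), `"normal"`
#'   (approximation with continuity correction) or `"auto"`.
#' @return list with `W`, `m`, `N`, `p`, `method`.
#' @export
category_score <- function(ranked, members,
                           method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  N <- nrow(ranked)
  ranks <- ranked$rank[ranked$gene_id %in% members]
  m <- length(ranks)
  if (m == 0) stopf("category has no genes in the ranked list")
  if (m == N) stopf("category covers every ranked gene (no complement)")
  W <- sum(ranks)
  used <- if (method == "auto") {
    if (m * (N - m) <= 2000) "exact" else "normal"
  } else method
  list(W = W, m = m, N = N, p = rank_sum_p(W, m, N, used), method = used)
}

#' Score every category and estimate a permutation FDR
#'
#' Scores each category with [category_score()], then estimates a false
#' discovery rate by gene-category permutation: in each permutation the
#' gene-to-rank assignment is shuffled uniformly and all category p-values
#' recomputed; the FDR at an observed p is the mean number of null
#' categories at or below it per permutation, divided by the observed
#' number at or below it, capped at 1.
#'
#' @param ranked ranked gene list from [rank_genes()].
#' @param categories named list of gene-id vectors (e.g. from
#'   [read_gmt()]); categories with no overlap with the ranked list are
#'   dropped.
#' @param n_permutations number of permutations (>= 100 recommended for
#'   stable estimates).
#' @param seed integer seed for the permutations.
#' @param method p-value method passed to [category_score()].
#' @return data frame (`category`, `m`, `W`, `p`, `fdr`) sorted by `p`.
#' @export
enrich_categories <- function(ranked, categories, n_permutations = 1000L,
                              seed = 1L, method = "auto") {
  N <- nrow(ranked)
  idx <- lapply(categories, function(g) which(ranked$gene_id %in% g))
  keep <- vapply(idx, function(i) length(i) > 0 && length(i) < N, TRUE)
  idx <- idx[keep]
  if (!length(idx)) stopf("no usable categories (all empty or all-covering)")
  obs <- lapply(names(idx), function(nm)
    category_score(ranked, categories[[nm]], method))
  p_obs <- vapply(obs, `[[`, numeric(1), "p")
  m_obs <- vapply(obs, `[[`, numeric(1), "m")
  W_obs <- vapply(obs, `[[`, numeric(1), "W")

  fdr <- rep(NA_real_, length(idx))
  if (n_permutations > 0) {
    null_counts <- numeric(length(idx))
    with_seed(seed, {
      for (b in seq_len(n_permutations)) {
        r <- sample.int(N)
        p_null <- vapply(seq_along(idx), function(ci) {
          rank_sum_p(sum(r[idx[[ci]]]), m_obs[ci], N, method)
        }, numeric(1))
        # for each observed p, count null categories at or below it
        null_counts <- null_counts +
          vapply(p_obs, function(p0) sum(p_null <= p0), numeric(1))
      }
    })
    expected_null <- null_counts / n_permutations
    observed <- vapply(p_obs, function(p0) sum(p_obs <= p0), numeric(1))
    fdr <- pmin(1, expected_null / observed)
  }
  out <- data.frame(category = names(idx), m = m_obs, W = W_obs, p = p_obs,
                    fdr = fdr, stringsAsFactors = FALSE)
  out <- out[order(out$p, out$category), ]
  rownames(out) <- NULL
  out
}

#' Build a chromosomal-window gene category
#'
#' The set of genes whose body overlaps a genomic interval by at least one
#' base (the same overlap rule used to label probes), usable alongside any
#' functional category.
#'
#' @param annotation a `clinetile_annotation`.
#' @param chrom chromosome name.
#' @param start,end interval bounds (1-based inclusive).
#' @return character vector of member gene ids.
#' @export
positional_category <- function(annotation, chrom, start, end) {
  if (!chrom %in% names(annotation$chrom_lengths)) {
    stopf("unknown chromosome: %s", chrom)
  }
  g <- annotation$genes[annotation$genes$chrom == chrom, ]
  g$gene_id[g$start <= end & g$end >= start]
}
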