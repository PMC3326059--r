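#' Thresholds for the three differential-expression scenarios
#'
#' A probe is called differentially expressed when any of three window
#' scenarios fires: *short* — its own p-value is below `short_p`; *medium* —
#' the geometric mean of its p-value and those of the probes immediately
#' up- and downstream (a 3-probe window by default) is below `medium_p`;
#' *long* — the Gaussian-weighted geometric mean of the 21-probe window (10
#' probes each side, weights `exp(-i^2 / (2 * gaussian_variance))` on
#' probe-index distance i) is below `long_p`.
#'
#' @param short_p,medium_p,long_p scenario thresholds.
#' @param medium_flank probes on each side for the medium window (1 gives
#'   the 3-probe window; 2 gives the alternative 5-probe reading).
#' @param long_halfwidth probes on each side for the long window.
#' @param gaussian_variance variance of the Gaussian weight function, in
#'   squared probe-index units.
#' @return a `scenario_thresholds` list.
#' @export
scenario_thresholds <- function(short_p = 1e-5, medium_p = 0.01,
                                medium_flank = 1L, long_p = 0.1,
                                long_halfwidth = 10L, gaussian_variance = 5) {
  stopifnot(short_p > 0, short_p < 1, medium_p > 0, medium_p < 1,
            long_p > 0, long_p < 1, medium_flank >= 0, long_halfwidth >= 0,
            gaussian_variance > 0)
  structure(list(short_p = short_p, medium_p = medium_p,
                 medium_flank = as.integer(medium_flank), long_p = long_p,
                 long_halfwidth = as.integer(long_halfwidth),
                 gaussian_variance = gaussian_variance),
            class = "scenario_thresholds")
}

#' Weighted geometric mean of p-values
#'
#' `exp(sum(w * log(p)) / sum(w))`; always lies between `min(p)` and
#' `max(p)`. A zero p-value is an error — degenerate probes must be
#' resolved upstream before aggregation.
#'
#' @param p p-values in (0, 1].
#' @param weights non-negative weights, not all zero.
#' @return the aggregated p-value.
#' @export
weighted_geometric_mean <- function(p, weights = rep(1, length(p))) {
  if (any(p <= 0)) stopf("p-values must be positive (zero found)")
  if (any(p > 1)) stopf("p-values must not exceed 1")
  if (any(weights < 0) || sum(weights) == 0) {
    stopf("weights must be non-negative and not all zero")
  }
  exp(sum(weights * log(p)) / sum(weights))
}

# Rolling weighted mean of x with a symmetric kernel; edges computed
# directly with truncated, renormalized weights.
rolling_weighted_mean <- function(x, half, weights) {
  n <- length(x)
  if (half == 0L || n == 1L) return(x)
  if (n >= 2L * half + 1L) {
    k <- weights / sum(weights)
    out <- as.numeric(stats::filter(x, k, sides = 2))
    edge <- unique(c(seq_len(min(half, n)),
                     seq.int(max(1L, n - half + 1L), n)))
  } else {
    out <- numeric(n)
    edge <- seq_len(n)
  }
  for (i in edge) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    w <- weights[(lo - i + half + 1L):(hi - i + half + 1L)]
    out[i] <- sum(w * x[lo:hi]) / sum(w)
  }
  out
}

#' Call differentially expressed probes under the three window scenarios
#'
#' Probes must be supplied in genomic position order; windows never cross a
#' chromosome boundary and are truncated (with weights renormalized) at
#' chromosome ends.
#'
#' @param p per-probe p-values, position-ordered within chromosome.
#' @param chrom optional chromosome of each probe (a single block is
#'   assumed when omitted); chromosome blocks must be contiguous.
#' @param pos optional positions used to verify sort order.
#' @param thresholds a [scenario_thresholds()].
#' @return data frame of logical columns `short`, `medium`, `long`, `any`.
#' @export
call_probes <- function(p, chrom = NULL, pos = NULL,
                        thresholds = scenario_thresholds()) {
  if (any(p <= 0)) stopf("p-values must be positive; resolve degenerate probes first")
  if (any(p > 1)) stopf("p-values must not exceed 1")
  if (is.null(chrom)) chrom <- rep("all", length(p))
  if (anyDuplicated(rle(chrom)$values)) {
    stopf("chromosome blocks must be contiguous")
  }
  if (!is.null(pos)) {
    bad <- tapply(pos, factor(chrom, unique(chrom)),
                  function(x) is.unsorted(x))
    if (any(bad)) stopf("probes are not position-sorted within chromosome")
  }
  th <- thresholds
  lw <- exp(-(seq(-th$long_halfwidth, th$long_halfwidth))^2 /
              (2 * th$gaussian_variance))
  lp <- log(p)
  short <- p < th$short_p
  medium <- long <- logical(length(p))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    medium[i] <- exp(rolling_weighted_mean(
      lp[i], th$medium_flank, rep(1, 2 * th$medium_flank + 1))) < th$medium_p
    long[i] <- exp(rolling_weighted_mean(
      lp[i], th$long_halfwidth, lw)) < th$long_p
  }
  data.frame(short = short, medium = medium, long = long,
             any = short | medium | long)
}

#' Summarize probe calls into gene and intergenic-region lists
#'
#' Genes are those overlapped by at least one called probe (exonic or
#' intronic by default; set `include_intronic = FALSE` to require exonic
#' probes). Each gene's direction is the sign of the mean effect of its
#' called probes under the North-minus-South contrast. Called intergenic
#' probes are assigned to the maximal intergenic region containing them.
#'
#' @param calls data frame from [call_probes()], aligned with `stats`.
#' @param stats per-probe statistics with `chrom`, `start`, `end`, `label`,
#'   `effect`, `p` (from [probe_stats()] with probe coordinates).
#' @param annotation a `clinetile_annotation`.
#' @param intergenic intergenic region table
#'   ([define_intergenic_regions()]); computed from `annotation` if `NULL`.
#' @param include_intronic count genes reached only by intronic probes.
#' @return list with `genes` (gene_id, direction, n_probes, best_p),
#'   `intergenic` (region table), `counts` (n_probes, n_genes,
#'   n_intergenic) and the per-probe `calls`.
#' @export
summarize_calls <- function(calls, stats, annotation, intergenic = NULL,
                            include_intronic = TRUE) {
  stopifnot(nrow(calls) == nrow(stats))
  if (is.null(intergenic)) intergenic <- define_intergenic_regions(annotation)
  called <- which(calls$any)
  if (length(called) && any(is.na(stats$label[called]))) {
    stopf("called probe without a label")
  }
  gene_labels <- if (include_intronic) c("exonic", "intronic") else "exonic"
  gsel <- called[stats$label[called] %in% gene_labels]
  genes_out <- data.frame(gene_id = character(), direction = character(),
                          n_probes = integer(), best_p = numeric(),
                          stringsAsFactors = FALSE)
  if (length(gsel)) {
    pr <- IRanges::IRanges(stats$start[gsel], stats$end[gsel])
    rows <- list()
    for (ch in unique(stats$chrom[gsel])) {
      pi <- which(stats$chrom[gsel] == ch)
      gi <- which(annotation$genes$chrom == ch)
      if (!length(gi)) next
      hits <- IRanges::findOverlaps(
        pr[pi], IRanges::IRanges(annotation$genes$start[gi],
                                 annotation$genes$end[gi]))
      if (!length(hits)) next
      probe_row <- gsel[pi][S4Vectors::queryHits(hits)]
      gene_id <- annotation$genes$gene_id[gi][S4Vectors::subjectHits(hits)]
      rows[[ch]] <- data.frame(gene_id = gene_id,
                               effect = stats$effect[probe_row],
                               p = stats$p[probe_row],
                               stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      gp <- do.call(rbind, rows)
      agg <- split(gp, gp$gene_id)
      genes_out <- do.call(rbind, lapply(agg, function(g) {
        data.frame(gene_id = g$gene_id[1],
                   direction = if (mean(g$effect) > 0) "North" else "South",
                   n_probes = nrow(g), best_p = min(g$p),
                   stringsAsFactors = FALSE)
      }))
      rownames(genes_out) <- NULL
    }
  }
  isel <- called[stats$label[called] == "intergenic"]
  ig_out <- intergenic[0, ]
  if (length(isel) && nrow(intergenic)) {
    hit_ids <- character(0)
    for (ch in unique(stats$chrom[isel])) {
      pi <- which(stats$chrom[isel] == ch)
      ri <- which(intergenic$chrom == ch)
      if (!length(ri)) next
      ov <- IRanges::overlapsAny(
        IRanges::IRanges(intergenic$start[ri], intergenic$end[ri]),
        IRanges::IRanges(stats$start[isel][pi], stats$end[isel][pi]))
      hit_ids <- c(hit_ids, intergenic$region_id[ri][ov])
    }
    ig_out <- intergenic[intergenic$region_id %in% hit_ids, ]
  }
  list(genes = genes_out, intergenic = ig_out,
       counts = c(n_probes = length(called), n_genes = nrow(genes_out),
                  n_intergenic = nrow(ig_out)),
       calls = calls)
}

#' Hypergeometric upper-tail probability of a gene-list overlap
#'
#' Probability of observing at least `k` shared genes when lists of sizes
#' `n_a` and `n_b` are drawn independently without replacement from a
#' universe of `universe` genes.
#'
#' @param k observed intersection size.
#' @param n_a,n_b list sizes.
#' @param universe universe size.
#' @return upper-tail probability `P(K >= k)`.
#' @export
hypergeometric_overlap_p <- function(k, n_a, n_b, universe) {
  if (universe < max(n_a, n_b)) {
    stopf("universe (%d) smaller than a list (%d)", universe, max(n_a, n_b))
  }
  phyper(k - 1, n_a, universe - n_a, n_b, lower.tail = FALSE)
}

#' Test whether two called gene lists overlap more than expected by chance
#'
#' @param list_a,list_b character vectors of gene ids.
#' @param universe number of genes the lists were drawn from (e.g. genes
#'   with at least one retained probe).
#' @return list with `k` (intersection size), `n_a`, `n_b`, `universe` and
#'   the upper-tail hypergeometric `p`.
#' @export
overlap_test <- function(list_a, list_b, universe) {
  list_a <- unique(list_a); list_b <- unique(list_b)
  k <- length(intersect(list_a, list_b))
  p <- hypergeometric_overlap_p(k, length(list_a), length(list_b), universe)
  list(k = k, n_a = length(list_a), n_b = length(list_b),
       universe = universe, p = p)
}
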