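#' Specify a synthetic genome for the tiling-array simulator
#'
#' The generator emulates the situation the pipeline is built for: a compact
#' genome tiled by short probes, with genes (each a run of exons separated by
#' short introns) placed without overlap and separated by intergenic gaps.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome (bp).
#' @param n_genes total number of genes across all chromosomes.
#' @param exons_per_gene exons per gene; introns between them are short
#'   (`intron_length_range`), as is typical of compact insect genomes.
#' @param gene_length_range inclusive range (bp) from which gene spans are
#'   drawn uniformly.
#' @param intron_length_range inclusive range (bp) for intron lengths.
#' @param min_intergenic_gap minimum gap (bp) between consecutive genes and
#'   between a gene and the chromosome end. Keeping neighbouring genes at
#'   least this far apart ensures a called probe run bleeding a few probes
#'   past a gene boundary cannot reach the next gene, so planted-truth
#'   bookkeeping stays unambiguous.
#' @return a `genome_spec` list.
#' @export
genome_spec <- function(n_chromosomes = 2L, chrom_length = 200000L,
                        n_genes = 80L, exons_per_gene = 3L,
                        gene_length_range = c(800L, 2400L),
                        intron_length_range = c(60L, 100L),
                        min_intergenic_gap = 800L) {
  stopifnot(n_chromosomes >= 1, chrom_length >= 1, n_genes >= 0,
            exons_per_gene >= 1, length(gene_length_range) == 2,
            gene_length_range[1] <= gene_length_range[2],
            gene_length_range[1] >= 1, min_intergenic_gap >= 0)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 gene_length_range = as.integer(gene_length_range),
                 intron_length_range = as.integer(intron_length_range),
                 min_intergenic_gap = as.integer(min_intergenic_gap)),
            class = "genome_spec")
}

#' Specify the planted clinal effect structure
#'
#' All standard deviations are on the log2-intensity scale. The planted
#' North-minus-South shift is applied to every exonic probe of a selected
#' gene, identically at both larval stages.
#'
#' @param de_gene_fraction fraction of genes planted as differentially
#'   expressed between cline ends.
#' @param log2_fold_change absolute North-minus-South log2 fold change of a
#'   planted gene; each planted gene is independently assigned an
#'   up-in-North or up-in-South direction.
#' @param probe_affinity_sd sd of the per-probe multiplicative affinity
#'   (log2 scale), shared across arrays.
#' @param background_trend_amplitude amplitude, in raw intensity units, of
#'   the smooth per-array additive background (sinusoid along the
#'   chromosome plus a per-array offset): the stray, annotation-independent
#'   signal that windowed-percentile background subtraction removes. It is
#'   added on the raw scale, on top of the exponentiated log2 signal.
#' @param replicate_noise_sd sd of independent per-measurement noise.
#' @param baseline_exonic,baseline_nonexonic mean log2 intensity of exonic
#'   and non-exonic probes.
#' @return an `effect_spec` list.
#' @export
effect_spec <- function(de_gene_fraction = 0.1, log2_fold_change = 2,
                        probe_affinity_sd = 0.5,
                        background_trend_amplitude = 100,
                        replicate_noise_sd = 0.25,
                        baseline_exonic = 10, baseline_nonexonic = 7) {
  stopifnot(de_gene_fraction >= 0, de_gene_fraction <= 1,
            probe_affinity_sd >= 0, background_trend_amplitude >= 0,
            replicate_noise_sd >= 0)
  structure(list(de_gene_fraction = de_gene_fraction,
                 log2_fold_change = log2_fold_change,
                 probe_affinity_sd = probe_affinity_sd,
                 background_trend_amplitude = background_trend_amplitude,
                 replicate_noise_sd = replicate_noise_sd,
                 baseline_exonic = baseline_exonic,
                 baseline_nonexonic = baseline_nonexonic),
            class = "effect_spec")
}

#' Build the array design table
#'
#' Two cline ends crossed with two larval stages, `n_replicates` biological
#' replicates each.
#'
#' @param n_replicates biological replicates per (cline end, stage) group.
#' @param stages character vector of stage labels.
#' @return data frame with columns `array_id`, `cline_end`, `stage`,
#'   `replicate`.
#' @export
design_table <- function(n_replicates = 5L, stages = c("L2", "L3")) {
  stopifnot(n_replicates >= 2)
  d <- expand.grid(replicate = seq_len(n_replicates),
                   cline_end = c("North", "South"), stage = stages,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$array_id <- sprintf("%s_%s_r%d", d$cline_end, d$stage, d$replicate)
  d[, c("array_id", "cline_end", "stage", "replicate")]
}

# Partition `total` into `k` non-negative integer parts, uniformly at random
# in distribution over orderings (multinomial split).
random_partition <- function(total, k) {
  if (k == 1L) return(total)
  if (total == 0L) return(integer(k))
  as.integer(stats::rmultinom(1L, total, rep(1 / k, k)))
}

#' Generate a random genome and gene/exon annotation
#'
#' Genes are placed without overlap on each chromosome by distributing the
#' free (non-genic) space randomly among the gaps, respecting the minimum
#' intergenic gap; exons are laid out left to right with short introns
#' between them. Coordinates are 1-based inclusive (GFF3 convention).
#'
#' @param spec a [genome_spec()].
#' @param seed integer seed; identical `(spec, seed)` give identical output.
#' @return a `clinetile_annotation` list: `genome` (DNAStringSet), `genes`
#'   and `exons` data frames, `chrom_lengths`.
#' @export
generate_annotation <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(seed, {
    chroms <- sprintf("chr%d", seq_len(spec$n_chromosomes))
    genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
      paste(sample(c("A", "C", "G", "T"), spec$chrom_length, replace = TRUE),
            collapse = "")
    }, ""))
    names(genome) <- chroms

    # round-robin split of genes over chromosomes
    chrom_of <- rep_len(chroms, spec$n_genes)
    genes <- list(); exons <- list()
    for (ch in chroms) {
      k <- sum(chrom_of == ch)
      if (k == 0L) next
      lens <- sample(seq(spec$gene_length_range[1], spec$gene_length_range[2]),
                     k, replace = TRUE)
      reserved <- sum(lens) + (k + 1L) * spec$min_intergenic_gap
      if (reserved > spec$chrom_length) {
        stopf("infeasible packing on %s: %d bp of genes + gaps > %d bp",
              ch, reserved, spec$chrom_length)
      }
      extra <- random_partition(spec$chrom_length - reserved, k + 1L)
      gaps <- spec$min_intergenic_gap + extra
      step_gaps <- if (k > 1L) gaps[2:k] else integer(0)
      starts <- cumsum(c(gaps[1] + 1L, head(lens, -1L) + step_gaps))
      ends <- starts + lens - 1L
      ids <- sprintf("gene_%s_%03d", sub("^chr", "", ch), seq_len(k))
      strands <- sample(c("+", "-"), k, replace = TRUE)
      genes[[ch]] <- data.frame(gene_id = ids, chrom = ch, start = starts,
                                end = ends, strand = strands,
                                stringsAsFactors = FALSE)
      exons[[ch]] <- do.call(rbind, lapply(seq_len(k), function(i) {
        gene_exons(ids[i], ch, starts[i], ends[i], strands[i],
                   spec$exons_per_gene, spec$intron_length_range)
      }))
    }
    genes <- if (length(genes)) do.call(rbind, genes) else
      data.frame(gene_id = character(), chrom = character(),
                 start = integer(), end = integer(), strand = character(),
                 stringsAsFactors = FALSE)
    exons <- if (length(exons)) do.call(rbind, exons) else
      data.frame(exon_id = character(), gene_id = character(),
                 chrom = character(), start = integer(), end = integer(),
                 strand = character(), stringsAsFactors = FALSE)
    rownames(genes) <- rownames(exons) <- NULL
    structure(list(genome = genome, genes = genes, exons = exons,
                   chrom_lengths = setNames(rep(spec$chrom_length,
                                                length(chroms)), chroms)),
              class = "clinetile_annotation")
  })
}

# Exon layout within one gene: n_exons exons separated by introns drawn from
# intron_length_range; falls back to a single exon if the gene is too short.
gene_exons <- function(gene_id, chrom, start, end, strand, n_exons,
                       intron_range) {
  glen <- end - start + 1L
  min_exon <- 50L
  introns <- if (n_exons > 1L) {
    sample(seq(intron_range[1], intron_range[2]), n_exons - 1L,
           replace = TRUE)
  } else integer(0)
  if (glen < n_exons * min_exon + sum(introns)) {
    n_exons <- 1L
    introns <- integer(0)
  }
  exon_total <- glen - sum(introns)
  lens <- min_exon + random_partition(exon_total - n_exons * min_exon, n_exons)
  starts <- start + cumsum(c(0L, head(lens, -1L) + introns))
  data.frame(exon_id = sprintf("%s_ex%d", gene_id, seq_len(n_exons)),
             gene_id = gene_id, chrom = chrom, start = starts,
             end = starts + lens - 1L, strand = strand,
             stringsAsFactors = FALSE)
}

#' Tile a genome with fixed-step probes
#'
#' Probes of constant length are laid down at a fixed step along each
#' chromosome, starting at position 1; the number of probes per chromosome
#' is `floor((L - probe_length) / step) + 1`.
#'
#' @param annotation a `clinetile_annotation`.
#' @param probe_length probe length (bp).
#' @param step distance between consecutive probe starts (bp).
#' @return data frame of probes (`probe_id`, `chrom`, `start`, `end`,
#'   `strand`, `sequence`), ordered by (chromosome, start).
#' @export
generate_probes <- function(annotation, probe_length = 25L, step = 40L) {
  stopifnot(step >= 1)
  out <- lapply(names(annotation$genome), function(ch) {
    L <- annotation$chrom_lengths[[ch]]
    if (probe_length > L) stopf("probe_length %d exceeds %s length %d",
                                probe_length, ch, L)
    starts <- seq.int(1L, L - probe_length + 1L, by = step)
    seqs <- substring(as.character(annotation$genome[[ch]]),
                      starts, starts + probe_length - 1L)
    data.frame(probe_id = sprintf("%s_p%06d", ch, seq_along(starts)),
               chrom = ch, start = starts, end = starts + probe_length - 1L,
               strand = "+", sequence = seqs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate raw tiling-array intensities with planted clinal effects
#'
#' Log2 signal of probe i on array j is the sum of a baseline (exonic
#' probes carry their gene's expression level, other probes a lower
#' background level), a per-probe affinity, the planted North/South shift
#' for exonic probes of differentially expressed genes, and independent
#' replicate noise. The returned raw intensity is the exponentiated signal
#' plus a smooth per-array additive background (a sinusoid along each
#' chromosome plus a per-array offset, scaled by the trend amplitude) —
#' the artefact the windowed-percentile background stage estimates and
#' subtracts.
#'
#' @param probes probe table from [generate_probes()].
#' @param design design table from [design_table()].
#' @param effects an [effect_spec()].
#' @param annotation the `clinetile_annotation` the probes tile.
#' @param seed integer seed.
#' @return list with `intensities` (probes x arrays matrix, raw scale),
#'   `truth` (planted genes: `gene_id`, `direction`, `log2_fold_change`),
#'   and `probe_gene` (per-probe gene assignment and exonic flag used by the
#'   simulator).
#' @export
simulate_intensities <- function(probes, design, effects, annotation,
                                 seed = 1L) {
  stopifnot(inherits(effects, "effect_spec"), nrow(design) > 0,
            nrow(probes) > 0)
  with_seed(seed, {
    genes <- annotation$genes
    n_genes <- nrow(genes)
    # probe -> gene / exon assignment by interval overlap
    pr <- IRanges::IRanges(probes$start, probes$end)
    exonic <- logical(nrow(probes))
    gene_idx <- rep(NA_integer_, nrow(probes))
    for (ch in names(annotation$genome)) {
      pi <- which(probes$chrom == ch)
      if (!length(pi)) next
      gi <- which(genes$chrom == ch)
      if (length(gi)) {
        hits <- IRanges::findOverlaps(pr[pi],
                                      IRanges::IRanges(genes$start[gi],
                                                       genes$end[gi]),
                                      select = "first")
        gene_idx[pi] <- gi[hits]
      }
      ei <- which(annotation$exons$chrom == ch)
      if (length(ei)) {
        ov <- IRanges::overlapsAny(pr[pi],
                                   IRanges::IRanges(annotation$exons$start[ei],
                                                    annotation$exons$end[ei]))
        exonic[pi] <- ov
      }
    }

    n_de <- round(effects$de_gene_fraction * n_genes)
    de_idx <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer(0)
    de_dir <- sample(c(1, -1), length(de_idx), replace = TRUE)
    gene_level <- rnorm(n_genes, effects$baseline_exonic, 1)

    base <- ifelse(exonic & !is.na(gene_idx), gene_level[gene_idx],
                   effects$baseline_nonexonic)
    affinity <- rnorm(nrow(probes), 0, effects$probe_affinity_sd)

    shift_half <- numeric(nrow(probes))  # +/- half FC for North; South negated
    if (length(de_idx)) {
      de_map <- setNames(de_dir, de_idx)
      in_de <- exonic & !is.na(gene_idx) & gene_idx %in% de_idx
      shift_half[in_de] <- de_map[as.character(gene_idx[in_de])] *
        effects$log2_fold_change / 2
    }

    n_arrays <- nrow(design)
    amp <- effects$background_trend_amplitude
    phases <- matrix(runif(n_arrays * length(annotation$chrom_lengths),
                           0, 2 * pi),
                     nrow = n_arrays)
    offsets <- runif(n_arrays, 0, amp / 2)
    chrom_i <- match(probes$chrom, names(annotation$chrom_lengths))
    relpos <- probes$start / annotation$chrom_lengths[chrom_i]

    raw <- matrix(0, nrow(probes), n_arrays,
                  dimnames = list(probes$probe_id, design$array_id))
    for (j in seq_len(n_arrays)) {
      trend <- amp * (1 + sin(2 * pi * 3 * relpos + phases[j, chrom_i])) / 2 +
        offsets[j]
      group_sign <- if (design$cline_end[j] == "North") 1 else -1
      mu <- base + affinity + group_sign * shift_half
      raw[, j] <- 2^(mu + rnorm(nrow(probes), 0,
                                effects$replicate_noise_sd)) + trend
    }

    truth <- data.frame(gene_id = genes$gene_id[de_idx],
                        direction = ifelse(de_dir > 0, "North", "South"),
                        log2_fold_change = de_dir * effects$log2_fold_change,
                        stringsAsFactors = FALSE)
    probe_gene <- data.frame(probe_id = probes$probe_id,
                             gene_id = ifelse(is.na(gene_idx), NA_character_,
                                              genes$gene_id[gene_idx]),
                             exonic = exonic, stringsAsFactors = FALSE)
    list(intensities = raw, truth = truth, probe_gene = probe_gene)
  })
}

#' Simulate a latitudinal table of expression or allele-frequency values
#'
#' Values follow a linear cline in latitude with Gaussian noise; optionally
#' one population is displaced to act as a planted outlier. Latitudes span
#' the sampled range of the east Australian coast (signed degrees, southern
#' hemisphere negative).
#'
#' @param n_populations number of populations (>= 3).
#' @param slope,intercept cline parameters (value per degree latitude).
#' @param noise_sd residual sd around the cline.
#' @param outlier_index optional index of the displaced population.
#' @param outlier_shift displacement added to that population's value.
#' @param seed integer seed.
#' @param latitude_range range of latitudes (degrees, signed).
#' @return data frame with `population_id`, `latitude`, `value`, `outlier`.
#' @export
generate_clinal_table <- function(n_populations = 15L, slope = 0.05,
                                  intercept = 3, noise_sd = 0.2,
                                  outlier_index = NULL, outlier_shift = 0,
                                  seed = 1L,
                                  latitude_range = c(-43.2, -16.9)) {
  stopifnot(n_populations >= 3)
  if (!is.null(outlier_index) &&
      (outlier_index < 1 || outlier_index > n_populations)) {
    stopf("outlier_index %d out of range 1..%d", outlier_index, n_populations)
  }
  with_seed(seed, {
    lat <- seq(latitude_range[1], latitude_range[2],
               length.out = n_populations)
    value <- intercept + slope * lat + rnorm(n_populations, 0, noise_sd)
    outlier <- logical(n_populations)
    if (!is.null(outlier_index)) {
      value[outlier_index] <- value[outlier_index] + outlier_shift
      outlier[outlier_index] <- TRUE
    }
    data.frame(population_id = sprintf("pop%02d", seq_len(n_populations)),
               latitude = lat, value = value, outlier = outlier,
               stringsAsFactors = FALSE)
  })
}
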