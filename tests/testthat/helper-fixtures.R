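# Shared fixture builders. Everything is generated in code at test time.

tiny_annotation <- function(seed = 3, n_genes = 8, chrom_length = 40000,
                            n_chromosomes = 1) {
  generate_annotation(genome_spec(n_chromosomes = n_chromosomes,
                                  chrom_length = chrom_length,
                                  n_genes = n_genes),
                      seed = seed)
}

# Hand-built annotation with known coordinates, for labelling tests:
# one gene [101, 400] with exons [101,200] and [301,400] on a 1000 bp
# chromosome of repeating sequence.
fixed_annotation <- function() {
  genome <- Biostrings::DNAStringSet(
    paste(rep("ACGT", 250), collapse = ""))
  names(genome) <- "chrT"
  structure(list(
    genome = genome,
    genes = data.frame(gene_id = "gT", chrom = "chrT", start = 101L,
                       end = 400L, strand = "+", stringsAsFactors = FALSE),
    exons = data.frame(exon_id = c("gT_ex1", "gT_ex2"), gene_id = "gT",
                       chrom = "chrT", start = c(101L, 301L),
                       end = c(200L, 400L), strand = "+",
                       stringsAsFactors = FALSE),
    chrom_lengths = c(chrT = 1000L)),
    class = "clinetile_annotation")
}

# Brute-force Hamming-scan mapper used as the independent oracle for
# map_probes(): per-base comparison at every offset on both strands.
brute_force_map <- function(sequence, genome, max_mismatches = 1) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  pl <- nchar(sequence)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sequence)))
  out <- list()
  for (ch in names(genome)) {
    g <- strsplit(as.character(genome[[ch]]), "")[[1]]
    fw <- strsplit(sequence, "")[[1]]
    rv <- strsplit(rc, "")[[1]]
    for (s in seq_len(length(g) - pl + 1)) {
      win <- g[s:(s + pl - 1)]
      mmf <- sum(win != fw)
      if (mmf <= max_mismatches) {
        out[[length(out) + 1]] <- data.frame(chrom = ch, start = s,
                                             strand = "+", mismatches = mmf,
                                             stringsAsFactors = FALSE)
      }
      mmr <- sum(win != rv)
      if (mmr <= max_mismatches) {
        out[[length(out) + 1]] <- data.frame(chrom = ch, start = s,
                                             strand = "-", mismatches = mmr,
                                             stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), mismatches = integer()))
  }
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start, df$strand), , drop = FALSE]
}

# Naive windowed nearest-rank percentile, recomputed per window with a full
# sort: the oracle for local_background().
naive_local_background <- function(values, half_window, percentile) {
  n <- length(values)
  sapply(seq_len(n), function(i) {
    w <- sort(values[max(1, i - half_window):min(n, i + half_window)])
    w[ceiling(percentile / 100 * length(w))]
  })
}
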