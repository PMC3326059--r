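#' Map probe sequences to a genome allowing up to one mismatch
#'
#' Finds every location on either strand where a probe matches the genome
#' with Hamming distance at most `max_mismatches` (substitutions only; a
#' tiling probe keeps its length, so indels are out of scope). Matching is
#' exhaustive: for the one-mismatch case each probe is split into two
#' halves, one of which must match exactly (pigeonhole), exact half matches
#' are located with `Biostrings::matchPDict()`, and every candidate is then
#' verified base by base. Reverse-strand hits are found by matching the
#' probe's reverse complement against the forward genome and are reported at
#' their leftmost forward-strand coordinate.
#'
#' Probes containing ambiguous bases (anything outside A/C/G/T) are
#' rejected with an error rather than wildcard-matched.
#'
#' @param sequences character vector (or `DNAStringSet`) of probe sequences.
#' @param genome named `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @param max_mismatches 0 or 1 substitutions allowed.
#' @return data frame of hits: `probe` (index into `sequences`), `chrom`,
#'   `start` (1-based leftmost), `strand`, `mismatches`.
#' @export
map_probes <- function(sequences, genome, max_mismatches = 1L) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome))) stopf("genome chromosomes must be named")
  seq_chr <- if (is.character(sequences)) toupper(sequences) else
    as.character(sequences)
  if (any(grepl("[^ACGT]", seq_chr))) {
    stopf("probe sequences contain ambiguous bases (non-ACGT); refusing to map")
  }
  if (!max_mismatches %in% c(0L, 1L)) {
    stopf("max_mismatches must be 0 or 1")
  }
  chrom_str <- setNames(as.character(genome), names(genome))

  hits <- list()
  for (L in unique(nchar(seq_chr))) {
    idx <- which(nchar(seq_chr) == L)
    fwd <- seq_chr[idx]
    rev <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(fwd)))
    for (str in c("+", "-")) {
      pat <- if (str == "+") fwd else rev
      cand <- candidate_starts(pat, genome, L, max_mismatches)
      if (!nrow(cand)) next
      # verify Hamming distance at each candidate start
      windows <- substring(chrom_str[cand$chrom], cand$start,
                           cand$start + L - 1L)
      mm <- hamming_vec(pat[cand$pattern], windows)
      keep <- mm <= max_mismatches
      if (!any(keep)) next
      hits[[paste0(L, str)]] <- data.frame(
        probe = idx[cand$pattern[keep]], chrom = cand$chrom[keep],
        start = cand$start[keep], strand = str, mismatches = mm[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(probe = integer(), chrom = character(),
                      start = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- unique(out)
  out <- out[order(out$probe, out$chrom, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# Candidate start positions for constant-width patterns: exact matches of
# each half (pigeonhole for <=1 mismatch), or of the full pattern when no
# mismatch is allowed. Returns a data frame (pattern index, chrom, start).
candidate_starts <- function(pat, genome, L, max_mismatches) {
  dna <- Biostrings::DNAStringSet(pat)
  if (max_mismatches == 0L) {
    pieces <- list(list(dict = Biostrings::PDict(dna), offset = 0L))
  } else {
    h <- L %/% 2L
    pieces <- list(
      list(dict = Biostrings::PDict(Biostrings::subseq(dna, 1L, h)),
           offset = 0L),
      list(dict = Biostrings::PDict(Biostrings::subseq(dna, h + 1L, L)),
           offset = h))
  }
  res <- list()
  for (ch in names(genome)) {
    clen <- length(genome[[ch]])
    for (pc in pieces) {
      m <- Biostrings::matchPDict(pc$dict, genome[[ch]])
      starts <- BiocGenerics::start(m)
      n_per <- lengths(starts)
      if (!sum(n_per)) next
      s <- unlist(starts, use.names = FALSE) - pc$offset
      p <- rep.int(seq_along(n_per), n_per)
      ok <- s >= 1L & s + L - 1L <= clen
      if (!any(ok)) next
      res[[paste(ch, pc$offset)]] <- data.frame(
        pattern = p[ok], chrom = ch, start = s[ok], stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(pattern = integer(), chrom = character(),
                      start = integer(), stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, res))
}

# Vectorized Hamming distance between equal-length string pairs.
hamming_vec <- function(a, b) {
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}

#' @rdname map_probes
#' @param sequence a single probe sequence.
#' @return `map_probe()` returns the hit data frame for one probe (without
#'   the `probe` index column).
#' @export
map_probe <- function(sequence, genome, max_mismatches = 1L) {
  stopifnot(length(sequence) == 1)
  out <- map_probes(sequence, genome, max_mismatches)
  out$probe <- NULL
  out
}

#' Retain probes that map to a single genomic location
#'
#' Applies the unique-location rule: probes with exactly one hit are
#' retained at that location; probes with none are labelled `unmapped` and
#' probes with two or more are labelled `multi`, and both are excluded from
#' all downstream statistics.
#'
#' @param probes probe table with a `probe_id` column (and optionally
#'   `sequence`).
#' @param hits hit table from [map_probes()] run on `probes$sequence`.
#' @return `probes` with columns `n_locations`, `label_mapping`
#'   (`unique`/`multi`/`unmapped`) and, for retained probes, the mapped
#'   `chrom`, `start`, `end`, `strand`, `mismatches`.
#' @export
filter_unique <- function(probes, hits) {
  n_loc <- tabulate(hits$probe, nbins = nrow(probes))
  out <- probes
  out$n_locations <- n_loc
  out$label_mapping <- ifelse(n_loc == 0L, "unmapped",
                              ifelse(n_loc == 1L, "unique", "multi"))
  uniq <- hits[hits$probe %in% which(n_loc == 1L), ]
  width <- nchar(probes$sequence[uniq$probe])
  out$chrom <- NA_character_; out$start <- NA_integer_
  out$end <- NA_integer_; out$strand <- NA_character_
  out$mismatches <- NA_integer_
  out$chrom[uniq$probe] <- uniq$chrom
  out$start[uniq$probe] <- uniq$start
  out$end[uniq$probe] <- uniq$start + width - 1L
  out$strand[uniq$probe] <- uniq$strand
  out$mismatches[uniq$probe] <- uniq$mismatches
  out
}

#' Label probe locations as exonic, intronic or intergenic
#'
#' A probe is exonic if its interval overlaps at least one base of any
#' exon; otherwise intronic if it overlaps any gene body; otherwise
#' intergenic. Gene-body overlap takes precedence over intergenic, so a
#' probe straddling a gene boundary that touches no exon is intronic.
#'
#' @param probes data frame with `chrom`, `start`, `end` (unique locations).
#' @param annotation a `clinetile_annotation`.
#' @return character vector of labels, one per row of `probes`.
#' @export
label_probes <- function(probes, annotation) {
  unknown <- setdiff(unique(probes$chrom), names(annotation$chrom_lengths))
  if (length(unknown)) stopf("unknown chromosome(s): %s",
                             paste(unknown, collapse = ", "))
  label <- rep("intergenic", nrow(probes))
  pr <- IRanges::IRanges(probes$start, probes$end)
  for (ch in unique(probes$chrom)) {
    pi <- which(probes$chrom == ch)
    gi <- annotation$genes$chrom == ch
    if (any(gi)) {
      in_gene <- IRanges::overlapsAny(
        pr[pi], IRanges::IRanges(annotation$genes$start[gi],
                                 annotation$genes$end[gi]))
      label[pi][in_gene] <- "intronic"
    }
    ei <- annotation$exons$chrom == ch
    if (any(ei)) {
      in_exon <- IRanges::overlapsAny(
        pr[pi], IRanges::IRanges(annotation$exons$start[ei],
                                 annotation$exons$end[ei]))
      label[pi][in_exon] <- "exonic"
    }
  }
  label
}

#' Enumerate maximal intergenic regions
#'
#' The per-chromosome complement of the union of gene intervals, including
#' the stretches up to the chromosome ends. Abutting or overlapping genes
#' merge before complementing.
#'
#' @param annotation a `clinetile_annotation`.
#' @return data frame (`region_id`, `chrom`, `start`, `end`), sorted and
#'   non-overlapping.
#' @export
define_intergenic_regions <- function(annotation) {
  out <- lapply(names(annotation$chrom_lengths), function(ch) {
    L <- annotation$chrom_lengths[[ch]]
    gi <- annotation$genes$chrom == ch
    if (!any(gi)) {
      return(data.frame(chrom = ch, start = 1L, end = L,
                        stringsAsFactors = FALSE))
    }
    genes <- IRanges::reduce(IRanges::IRanges(annotation$genes$start[gi],
                                              annotation$genes$end[gi]))
    comp <- IRanges::setdiff(IRanges::IRanges(1L, L), genes)
    if (!length(comp)) {
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE))
    }
    data.frame(chrom = ch, start = BiocGenerics::start(comp),
               end = BiocGenerics::end(comp), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (nrow(out)) out$region_id <- sprintf("ig_%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("region_id", "chrom", "start", "end")]
}

#' Map, filter and label a probe set in one step
#'
#' Runs [map_probes()], [filter_unique()] and [label_probes()], returning
#' the probe table with mapping status and genomic label attached. Only
#' uniquely mapping probes receive an exonic/intronic/intergenic label;
#' unmapped and multi-mapping probes carry their mapping status as label.
#'
#' @inheritParams map_probes
#' @param probes probe table with `probe_id` and `sequence`.
#' @param annotation a `clinetile_annotation`.
#' @return annotated probe table with a `label` column.
#' @export
annotate_probes <- function(probes, annotation, max_mismatches = 1L) {
  hits <- map_probes(probes$sequence, annotation$genome, max_mismatches)
  out <- filter_unique(probes[, setdiff(names(probes),
                                        c("chrom", "start", "end", "strand"))],
                       hits)
  out$label <- out$label_mapping
  uniq <- out$label_mapping == "unique"
  if (any(uniq)) out$label[uniq] <- label_probes(out[uniq, ], annotation)
  out
}
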