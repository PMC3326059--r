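#' Read or write a tab-separated table
#'
#' Thin wrappers around [utils::read.delim()] / [utils::write.table()] with
#' the conventions used throughout the package (no quoting, no row names,
#' header line, tab separator).
#'
#' @param path file path.
#' @param x data frame to write.
#' @return `read_tsv()` returns a data frame; `write_tsv()` returns `path`
#'   invisibly.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' @rdname read_tsv
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic genome and its annotation to standard formats
#'
#' The genome goes to FASTA (via Biostrings) and the gene/exon annotation to
#' GFF3 (via rtracklayer), using 1-based inclusive coordinates throughout.
#'
#' @param annotation an annotation object from [generate_annotation()].
#' @param fasta,gff3 output paths.
#' @return invisibly, a character vector of the files written.
#' @export
write_annotation <- function(annotation, fasta, gff3) {
  Biostrings::writeXStringSet(annotation$genome, fasta)
  genes <- annotation$genes
  exons <- annotation$exons
  gr_list <- list()
  if (nrow(genes)) {
    g <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start, genes$end),
                                strand = genes$strand)
    S4Vectors::mcols(g)$type <- "gene"
    S4Vectors::mcols(g)$ID <- genes$gene_id
    S4Vectors::mcols(g)$Parent <- NA_character_
    gr_list$genes <- g
  }
  if (!is.null(exons) && nrow(exons)) {
    e <- GenomicRanges::GRanges(exons$chrom,
                                IRanges::IRanges(exons$start, exons$end),
                                strand = exons$strand)
    S4Vectors::mcols(e)$type <- "exon"
    S4Vectors::mcols(e)$ID <- exons$exon_id
    S4Vectors::mcols(e)$Parent <- exons$gene_id
    gr_list$exons <- e
  }
  if (length(gr_list)) {
    gr <- do.call(c, unname(gr_list))
    GenomeInfoDb::seqlengths(gr) <-
      setNames(Biostrings::width(annotation$genome)[
        match(GenomeInfoDb::seqlevels(gr), names(annotation$genome))],
        GenomeInfoDb::seqlevels(gr))
  } else {
    gr <- GenomicRanges::GRanges()
  }
  rtracklayer::export(gr, gff3, format = "gff3")
  invisible(c(fasta, gff3))
}

#' Read a genome FASTA plus GFF3 annotation back into the package's
#' annotation structure
#'
#' @param fasta,gff3 paths written by [write_annotation()] (or any
#'   gene/exon GFF3 with `ID` on genes and `Parent` on exons).
#' @return an annotation list with elements `genome`, `genes`, `exons` and
#'   `chrom_lengths`, as produced by [generate_annotation()].
#' @export
read_annotation <- function(fasta, gff3) {
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(gff3, format = "gff3")
  df <- as.data.frame(gr)
  is_gene <- df$type == "gene"
  genes <- data.frame(gene_id = as.character(df$ID[is_gene]),
                      chrom = as.character(df$seqnames[is_gene]),
                      start = df$start[is_gene], end = df$end[is_gene],
                      strand = as.character(df$strand[is_gene]),
                      stringsAsFactors = FALSE)
  is_exon <- df$type == "exon"
  parent <- df$Parent[is_exon]
  parent <- vapply(as.list(parent), function(p) as.character(p)[1], "")
  exons <- data.frame(exon_id = as.character(df$ID[is_exon]),
                      gene_id = parent,
                      chrom = as.character(df$seqnames[is_exon]),
                      start = df$start[is_exon], end = df$end[is_exon],
                      strand = as.character(df$strand[is_exon]),
                      stringsAsFactors = FALSE)
  structure(list(genome = genome, genes = genes, exons = exons,
                 chrom_lengths = setNames(Biostrings::width(genome),
                                          names(genome))),
            class = "clinetile_annotation")
}

#' Write intergenic regions as BED
#'
#' Coordinates are converted from the package's 1-based inclusive convention
#' to BED's 0-based half-open convention at this boundary only.
#'
#' @param regions data frame from [define_intergenic_regions()].
#' @param path output path.
#' @export
write_intergenic_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom, start = regions$start - 1L,
                    end = regions$end, name = regions$region_id)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene categories in GMT format
#'
#' One category per line: name, description, then member gene ids, all
#' tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(fields, function(f) unique(f[-(1:2)])),
           vapply(fields, `[`, "", 1L))
}

#' @rdname read_gmt
#' @param categories named list of character vectors.
#' @param description optional per-category description column.
#' @export
write_gmt <- function(categories, path, description = "") {
  lines <- vapply(seq_along(categories), function(i) {
    paste(c(names(categories)[i], description,
            categories[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
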