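test_that("probe mapping agrees with a brute-force Hamming scan", {
  set.seed(21)
  ann <- generate_annotation(genome_spec(n_chromosomes = 2,
                                         chrom_length = 3000, n_genes = 0),
                             seed = 21)
  genome <- ann$genome
  gstr <- as.character(genome[[1]])
  probes <- character(0)
  # probes drawn from the genome, some mutated at one or two positions
  for (i in 1:40) {
    s <- sample(3000 - 24, 1)
    sq <- substring(gstr, s, s + 24)
    nmut <- sample(0:2, 1)
    for (m in seq_len(nmut)) {
      pos <- sample(25, 1)
      substr(sq, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                             substr(sq, pos, pos)), 1)
    }
    probes <- c(probes, sq)
  }
  # plus purely random probes (mostly unmappable)
  probes <- c(probes, vapply(1:10, function(i) {
    paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE), collapse = "")
  }, ""))
  hits <- map_probes(probes, genome, 1)
  for (i in seq_along(probes)) {
    got <- hits[hits$probe == i, c("chrom", "start", "strand", "mismatches")]
    rownames(got) <- NULL
    want <- brute_force_map(probes[i], genome, 1)
    rownames(want) <- NULL
    expect_equal(got, want, info = sprintf("probe %d", i))
  }
})

test_that("mapping is strand-symmetric and reports one-mismatch hits", {
  ann <- tiny_annotation(seed = 8, n_genes = 0, chrom_length = 5000)
  gstr <- as.character(ann$genome[[1]])
  probe <- substring(gstr, 1001, 1025)
  h <- map_probe(probe, ann$genome, 1)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 1001)
  expect_equal(h$mismatches, 0)
  expect_equal(h$strand, "+")
  # the reverse complement maps to the same place on the minus strand
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(probe)))
  hrc <- map_probe(rc, ann$genome, 1)
  expect_equal(nrow(hrc), 1)
  expect_equal(hrc$start, 1001)
  expect_equal(hrc$strand, "-")
  # one substitution is still found, labelled with mismatches = 1
  mut <- probe
  substr(mut, 7, 7) <- setdiff(c("A", "C", "G", "T"), substr(mut, 7, 7))[1]
  hm <- map_probe(mut, ann$genome, 1)
  expect_true(any(hm$start == 1001 & hm$mismatches == 1))
})

test_that("probes with ambiguous bases are rejected", {
  ann <- tiny_annotation(seed = 8, n_genes = 0, chrom_length = 1000)
  expect_error(map_probe(paste(c(rep("A", 24), "N"), collapse = ""),
                         ann$genome), "ambiguous")
})

test_that("a duplicated substring produces two locations and is filtered out", {
  seg <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
               collapse = "")
  filler <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
  set.seed(31)
  genome <- Biostrings::DNAStringSet(paste0(filler(200), seg, filler(300),
                                            seg, filler(200)))
  names(genome) <- "chrD"
  probe <- substring(seg, 1, 25)
  h <- map_probe(probe, genome, 1)
  expect_equal(sum(h$mismatches == 0), 2)
  probes <- data.frame(probe_id = "dup", sequence = probe,
                       stringsAsFactors = FALSE)
  f <- filter_unique(probes, map_probes(probe, genome, 1))
  expect_equal(f$label_mapping, "multi")
  expect_equal(f$n_locations, nrow(h))
})

test_that("unique-location filtering labels unmapped/unique/multi correctly", {
  ann <- tiny_annotation(seed = 8, n_genes = 0, chrom_length = 2000)
  gstr <- as.character(ann$genome[[1]])
  probes <- data.frame(
    probe_id = c("u1", "none"),
    sequence = c(substring(gstr, 501, 525),
                 paste(rep(c("A", "C"), c(13, 12)), collapse = "")),
    stringsAsFactors = FALSE)
  hits <- map_probes(probes$sequence, ann$genome, 0)
  f <- filter_unique(probes, hits)
  expect_equal(f$label_mapping[f$probe_id == "u1"], "unique")
  expect_equal(f$start[f$probe_id == "u1"], 501)
  expect_equal(f$label_mapping[f$probe_id == "none"], "unmapped")
})

test_that("probe labels follow the exon > gene body > intergenic precedence", {
  ann <- fixed_annotation()  # gene [101,400], exons [101,200] and [301,400]
  probes <- data.frame(
    probe_id = c("in_exon", "one_bp_exon", "intron", "straddle_start",
                 "intergenic"),
    chrom = "chrT",
    start = c(120L, 200L, 225L, 90L, 600L),
    end = c(144L, 224L, 249L, 114L, 624L),
    stringsAsFactors = FALSE)
  lab <- label_probes(probes, ann)
  expect_equal(lab, c("exonic", "exonic", "intronic", "exonic", "intergenic"))
  # a probe overlapping the gene start but before the first exon would be
  # intronic only if the gene had upstream non-exonic sequence; check the
  # 3' side: probe [395,419] touches the last exon -> exonic; [401,425] is
  # outside the gene -> intergenic
  lab2 <- label_probes(data.frame(probe_id = c("a", "b"), chrom = "chrT",
                                  start = c(395L, 401L), end = c(419L, 425L)),
                       ann)
  expect_equal(lab2, c("exonic", "intergenic"))
  expect_error(label_probes(data.frame(chrom = "chrX", start = 1, end = 25),
                            ann), "unknown chromosome")
})

test_that("every retained probe gets exactly one label and counts add up", {
  ann <- tiny_annotation(seed = 3)
  probes <- generate_probes(ann, 25, 40)
  lab <- annotate_probes(probes, ann, max_mismatches = 1)
  retained <- lab[lab$label_mapping == "unique", ]
  expect_true(all(retained$label %in% c("exonic", "intronic", "intergenic")))
  expect_equal(sum(table(retained$label)), nrow(retained))
  # oracle: recompute labels per base for a sample of retained probes
  idx <- seq(1, nrow(retained), by = 37)
  for (i in idx) {
    span <- retained$start[i]:retained$end[i]
    on_exon <- any(span >= min(ann$exons$start) &
                     vapply(span, function(b) {
                       any(b >= ann$exons$start & b <= ann$exons$end)
                     }, TRUE))
    on_gene <- any(vapply(span, function(b) {
      any(b >= ann$genes$start & b <= ann$genes$end)
    }, TRUE))
    want <- if (on_exon) "exonic" else if (on_gene) "intronic" else
      "intergenic"
    expect_equal(retained$label[i], want)
  }
})

test_that("intergenic regions are the maximal complement of gene spans", {
  ann <- fixed_annotation()
  ig <- define_intergenic_regions(ann)
  expect_equal(ig$start, c(1, 401))
  expect_equal(ig$end, c(100, 1000))

  # abutting genes merge; brute-force per-base complement agrees
  ann2 <- fixed_annotation()
  ann2$genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chrT",
                           start = c(1L, 101L), end = c(100L, 200L),
                           strand = "+", stringsAsFactors = FALSE)
  ig2 <- define_intergenic_regions(ann2)
  expect_equal(nrow(ig2), 1)
  expect_equal(c(ig2$start, ig2$end), c(201, 1000))
  base_free <- setdiff(1:1000, unlist(Map(seq, ann2$genes$start,
                                          ann2$genes$end)))
  covered <- unlist(Map(seq, ig2$start, ig2$end))
  expect_identical(sort(covered), sort(base_free))
})
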