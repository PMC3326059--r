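test_that("annotation generation is deterministic, non-overlapping and in bounds", {
  spec <- genome_spec(n_chromosomes = 1, chrom_length = 1e6, n_genes = 50)
  a1 <- generate_annotation(spec, seed = 11)
  a2 <- generate_annotation(spec, seed = 11)
  expect_identical(as.character(a1$genome), as.character(a2$genome))
  expect_identical(a1$genes, a2$genes)
  expect_identical(a1$exons, a2$exons)

  expect_equal(nrow(a1$genes), 50)
  # brute-force pairwise interval overlap scan
  g <- a1$genes[order(a1$genes$start), ]
  expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  expect_true(all(g$start >= 1 & g$end <= 1e6))
  # every exon inside its gene
  m <- match(a1$exons$gene_id, a1$genes$gene_id)
  expect_true(all(a1$exons$start >= a1$genes$start[m] &
                    a1$exons$end <= a1$genes$end[m]))
})

test_that("zero genes yields an all-intergenic annotation", {
  a <- generate_annotation(genome_spec(n_chromosomes = 1,
                                       chrom_length = 5000, n_genes = 0),
                           seed = 1)
  expect_equal(nrow(a$genes), 0)
  ig <- define_intergenic_regions(a)
  expect_equal(nrow(ig), 1)
  expect_equal(c(ig$start, ig$end), c(1, 5000))
})

test_that("infeasible gene packing errors out", {
  spec <- genome_spec(n_chromosomes = 1, chrom_length = 5000, n_genes = 10,
                      gene_length_range = c(800, 2400))
  expect_error(generate_annotation(spec, seed = 1), "infeasible")
})

test_that("probe tiling follows the closed-form count and matches the genome", {
  a <- generate_annotation(genome_spec(n_chromosomes = 1, chrom_length = 100,
                                       n_genes = 0), seed = 2)
  p1 <- generate_probes(a, probe_length = 25, step = 25)
  expect_equal(nrow(p1), 4)
  expect_true(all(diff(p1$start) == 25))
  p2 <- generate_probes(a, probe_length = 25, step = 5)
  expect_equal(nrow(p2), floor((100 - 25) / 5) + 1)
  expect_equal(p2$start, seq(1, 76, by = 5))
  expect_identical(p2$sequence,
                   substring(as.character(a$genome[[1]]), p2$start, p2$end))
})

test_that("zero-noise simulation reproduces the planted fold change exactly", {
  ann <- tiny_annotation(seed = 5)
  probes <- generate_probes(ann, 25, 40)
  design <- design_table(n_replicates = 2, stages = "L2")
  eff <- effect_spec(de_gene_fraction = 0.5, log2_fold_change = 2,
                     probe_affinity_sd = 0, background_trend_amplitude = 0,
                     replicate_noise_sd = 0)
  sim <- simulate_intensities(probes, design, eff, ann, seed = 7)
  l2 <- log2(sim$intensities)
  north <- design$array_id[design$cline_end == "North"]
  south <- design$array_id[design$cline_end == "South"]
  # all arrays within a group identical at zero noise
  expect_equal(l2[, north[1]], l2[, north[2]])
  for (i in seq_len(nrow(sim$truth))) {
    gid <- sim$truth$gene_id[i]
    pg <- sim$probe_gene
    sel <- which(pg$gene_id == gid & pg$exonic)
    expect_gt(length(sel), 0)  # every planted gene has exonic probes
    diffs <- rowMeans(l2[sel, north, drop = FALSE]) -
      rowMeans(l2[sel, south, drop = FALSE])
    expect_equal(unname(diffs), rep(sim$truth$log2_fold_change[i],
                                    length(sel)), tolerance = 1e-12)
  }
  # non-DE exonic probes show no group difference
  null_sel <- which(sim$probe_gene$exonic &
                      !sim$probe_gene$gene_id %in% sim$truth$gene_id)
  expect_equal(max(abs(l2[null_sel, north[1]] - l2[null_sel, south[1]])), 0)
})

test_that("simulation is reproducible and plants the stated DE fraction", {
  ann <- tiny_annotation(seed = 5)
  probes <- generate_probes(ann, 25, 40)
  design <- design_table(n_replicates = 3)
  eff <- effect_spec()
  s1 <- simulate_intensities(probes, design, eff, ann, seed = 13)
  s2 <- simulate_intensities(probes, design, eff, ann, seed = 13)
  expect_identical(s1$intensities, s2$intensities)
  expect_identical(s1$truth, s2$truth)
  n_genes <- nrow(ann$genes)
  expect_lte(abs(nrow(s1$truth) - eff$de_gene_fraction * n_genes), 1)
})

test_that("clinal table generator hits its exact and error cases", {
  t0 <- generate_clinal_table(10, slope = 0.05, intercept = 3,
                              noise_sd = 0, seed = 1)
  fit <- latitude_regression(t0)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 0.05, tolerance = 1e-12)

  tflat <- generate_clinal_table(10, slope = 0, intercept = 2,
                                 noise_sd = 0, seed = 1)
  expect_equal(max(abs(tflat$value - 2)), 0)

  expect_error(generate_clinal_table(10, outlier_index = 11), "out of range")
  expect_identical(generate_clinal_table(12, seed = 4),
                   generate_clinal_table(12, seed = 4))
})
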