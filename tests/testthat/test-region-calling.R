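test_that("weighted geometric mean matches closed forms and bounds", {
  expect_equal(weighted_geometric_mean(rep(0.05, 7), runif(7) + 0.1), 0.05)
  expect_equal(weighted_geometric_mean(c(0.01, 1)), 0.1)
  w <- exp(-(-10:10)^2 / 10)
  p <- c(rep(1, 10), 1e-6, rep(1, 10))
  expect_equal(weighted_geometric_mean(p, w), exp(log(1e-6) / sum(w)),
               tolerance = 1e-14)
  expect_error(weighted_geometric_mean(c(0, 0.5)), "positive")
  expect_error(weighted_geometric_mean(0.5, 0), "weights")
  # aggregation bound property on random inputs
  set.seed(61)
  for (i in 1:50) {
    p <- runif(sample(2:20, 1))
    w <- runif(length(p))
    g <- weighted_geometric_mean(p, w)
    expect_true(g >= min(p) - 1e-12 && g <= max(p) + 1e-12)
  }
})

test_that("scenario calling reproduces the worked threshold cases", {
  # isolated probe at 9e-6: short fires, medium does not
  p <- rep(1, 41); p[21] <- 9e-6
  cc <- call_probes(p)
  expect_true(cc$short[21])
  expect_false(cc$medium[21])
  expect_equal((9e-6)^(1/3), 0.0208, tolerance = 1e-3)
  # run of three probes at 0.001: centre is medium-called
  p2 <- rep(1, 21); p2[10:12] <- 0.001
  expect_true(call_probes(p2)$medium[11])
  # all-ones: nothing called
  expect_false(any(call_probes(rep(1, 100))$any))
  # degenerate zero p rejected
  expect_error(call_probes(c(0.5, 0, 0.5)), "positive")
  # unsorted input rejected
  expect_error(call_probes(runif(5), chrom = rep("c1", 5),
                           pos = c(1, 3, 2, 4, 5)), "sorted")
  # non-contiguous chromosome blocks rejected
  expect_error(call_probes(runif(4), chrom = c("a", "b", "a", "b")),
               "contiguous")
})

test_that("windows truncate and renormalize at chromosome ends", {
  th <- scenario_thresholds()
  set.seed(62)
  p <- runif(30, 0.001, 1)
  cc <- call_probes(p, thresholds = th)
  w <- exp(-(-10:10)^2 / (2 * th$gaussian_variance))
  for (i in c(1, 2, 5, 15, 29, 30)) {
    lo <- max(1, i - 10); hi <- min(30, i + 10)
    ww <- w[(lo - i + 11):(hi - i + 11)]
    expect_equal(cc$long[i],
                 weighted_geometric_mean(p[lo:hi], ww) < th$long_p)
    lo3 <- max(1, i - 1); hi3 <- min(30, i + 1)
    expect_equal(cc$medium[i],
                 weighted_geometric_mean(p[lo3:hi3]) < th$medium_p)
  }
  # windows never cross a chromosome boundary
  p2 <- c(rep(1e-4, 10), rep(1, 10))
  joint <- call_probes(p2, chrom = rep(c("c1", "c2"), each = 10))
  sep <- rbind(call_probes(p2[1:10]), call_probes(p2[11:20]))
  expect_equal(joint, sep, ignore_attr = TRUE)
})

test_that("lowering any p-value never removes a call", {
  set.seed(63)
  p <- runif(60, 0.001, 1)
  before <- call_probes(p)
  for (i in sample(60, 8)) {
    q <- p
    q[i] <- p[i] / 10
    after <- call_probes(q)
    expect_true(all(after$short >= before$short))
    expect_true(all(after$medium >= before$medium))
    expect_true(all(after$long >= before$long))
  }
})

test_that("calls summarize into gene and intergenic-region lists", {
  ann <- fixed_annotation()  # gene [101,400], intergenic [1,100]+[401,1000]
  ig <- define_intergenic_regions(ann)
  stats <- data.frame(
    probe_id = sprintf("p%02d", 1:6),
    chrom = "chrT",
    start = c(110, 150, 310, 50, 500, 700),
    end = c(134, 174, 334, 74, 524, 724),
    label = c("exonic", "exonic", "exonic", "intergenic", "intergenic",
              "intergenic"),
    effect = c(2, 2.5, 1.5, 0.2, -0.1, 0.3),
    p = c(1e-7, 1e-6, 1e-8, 0.5, 1e-7, 0.9),
    stringsAsFactors = FALSE)
  calls <- data.frame(short = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
                      medium = FALSE, long = FALSE,
                      any = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE))
  s <- summarize_calls(calls, stats, ann, ig)
  expect_equal(unname(s$counts), c(4, 1, 1))
  expect_equal(s$genes$gene_id, "gT")
  expect_equal(s$genes$direction, "North")
  expect_equal(s$genes$n_probes, 3)
  expect_equal(s$genes$best_p, 1e-8)
  expect_equal(s$intergenic$start, 401)
  # direction flips with the sign of the mean effect
  stats$effect <- -stats$effect
  expect_equal(summarize_calls(calls, stats, ann, ig)$genes$direction,
               "South")
  # a called probe without a label is an error
  stats$label[5] <- NA
  expect_error(summarize_calls(calls, stats, ann, ig), "label")
})

test_that("overlap test matches exhaustive enumeration on small universes", {
  expect_equal(overlap_test(c("a", "b"), c("c", "d"), 10)$p, 1)
  # identical lists reach the minimal tail value 1 / C(N, m)
  m <- 3; N <- 9
  ot <- overlap_test(letters[1:m], letters[1:m], N)
  expect_equal(ot$p, 1 / choose(N, m))
  # full enumeration over all B-subsets for N <= 12
  for (N in c(8, 12)) {
    universe <- seq_len(N)
    for (na in c(2, 4)) for (nb in c(3, 5)) {
      A <- universe[1:na]
      combs <- combn(N, nb)
      for (k in 0:min(na, nb)) {
        frac <- mean(apply(combs, 2, function(B) length(intersect(A, B)) >= k))
        expect_equal(hypergeometric_overlap_p(k, na, nb, N), frac,
                     tolerance = 1e-12)
      }
    }
  }
  expect_error(overlap_test(letters[1:5], letters[1:3], 4), "universe")
})
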