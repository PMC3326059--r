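#' Default pipeline configuration
#'
#' All thresholds default to the published scenario values (short 1e-5,
#' medium 0.01, long 0.1, Gaussian variance 5) and window settings
#' (half-window 500 probes, 5th percentile); the simulation block defaults
#' to the desk-scale fixture (2 chromosomes of 200 kb, ~80 genes, 25-mer
#' probes at step 40, 5+5 arrays per stage).
#'
#' @param outdir output directory for stage files and the manifest.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param ... named overrides merged (recursively for sub-lists) into the
#'   defaults.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = tempfile("clinetile_run_"), seed = 1L,
                            ...) {
  cfg <- list(
    outdir = outdir,
    seed = as.integer(seed),
    genome = list(n_chromosomes = 2L, chrom_length = 200000L, n_genes = 80L,
                  exons_per_gene = 3L, gene_length_range = c(800L, 2400L),
                  intron_length_range = c(60L, 100L),
                  min_intergenic_gap = 800L),
    effects = list(de_gene_fraction = 0.1, log2_fold_change = 2,
                   probe_affinity_sd = 0.5,
                   background_trend_amplitude = 100,
                   replicate_noise_sd = 0.25),
    probe_length = 25L, step = 40L, n_replicates = 5L,
    stages = c("L2", "L3"),
    max_mismatches = 1L,
    half_window = 500L, percentile = 5, loess_span = 0.3,
    thresholds = list(short_p = 1e-5, medium_p = 0.01, medium_flank = 1L,
                      long_p = 0.1, long_halfwidth = 10L,
                      gaussian_variance = 5),
    include_intronic = TRUE,
    n_permutations = 200L,
    enrichment_windows = 4L,
    clinal = list(n_populations = 15L, slope = 0.05, intercept = 3,
                  noise_sd = 0.2, outlier_index = 8L, outlier_shift = 2))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level and nested keys override the defaults of [pipeline_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  required <- c("outdir", "seed", "genome", "effects", "stages",
                "thresholds", "half_window", "percentile", "loess_span")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stopf("pipeline config is missing field(s): %s",
          paste(missing, collapse = ", "))
  }
  invisible(cfg)
}

stage_log <- function(manifest, stage, ...) {
  manifest$log[[stage]] <- list(stage = stage, time = format(Sys.time()),
                                params = list(...))
  message(sprintf("[clinetile] %s", stage))
  manifest
}

#' Run the full synthetic-to-results pipeline
#'
#' Executes the fixed stage order — simulate, annotate, preprocess,
#' probe-wise statistics (per stage), scenario calling and summarization
#' (per stage), between-stage overlap test, positional-category enrichment,
#' and clinal regression with outlier screening — writing each stage's
#' tables under `config$outdir` and returning a manifest of outputs with
#' MD5 checksums. The run is fully determined by the config's seed.
#'
#' @param config a `pipeline_config` (or path to a YAML file).
#' @return the manifest list (also written as `manifest.json`), with the
#'   principal in-memory results attached under `$results`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_config(config)
  cfg <- config
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(cfg$outdir, f)
  manifest <- list(seed = cfg$seed, log = list(), files = character())

  # -- simulate ---------------------------------------------------------
  gspec <- do.call(genome_spec, cfg$genome)
  espec <- do.call(effect_spec, cfg$effects)
  ann <- generate_annotation(gspec, seed = cfg$seed)
  probes <- generate_probes(ann, cfg$probe_length, cfg$step)
  design <- design_table(cfg$n_replicates, cfg$stages)
  sim <- simulate_intensities(probes, design, espec, ann,
                              seed = cfg$seed + 1L)
  clin <- do.call(generate_clinal_table,
                  c(cfg$clinal, list(seed = cfg$seed + 2L)))
  write_annotation(ann, pth("genome.fa"), pth("annotation.gff3"))
  write_tsv(probes, pth("probes.tsv"))
  write_tsv(design, pth("design.tsv"))
  write_tsv(sim$truth, pth("truth.tsv"))
  write_tsv(clin, pth("clinal_table.tsv"))
  int_df <- data.frame(probe_id = rownames(sim$intensities),
                       sim$intensities, check.names = FALSE)
  write_tsv(int_df, pth("intensities_raw.tsv"))
  manifest <- stage_log(manifest, "simulate", seed = cfg$seed,
                        n_probes = nrow(probes), n_arrays = nrow(design))

  # -- annotate ---------------------------------------------------------
  labelled <- annotate_probes(probes, ann, cfg$max_mismatches)
  intergenic <- define_intergenic_regions(ann)
  write_tsv(labelled, pth("probes_labelled.tsv"))
  write_intergenic_bed(intergenic, pth("intergenic.bed"))
  manifest <- stage_log(manifest, "annotate",
                        retained = sum(labelled$label_mapping == "unique"))

  # -- preprocess -------------------------------------------------------
  retained <- labelled[labelled$label_mapping == "unique", ]
  retained <- retained[order(retained$chrom, retained$start), ]
  prep <- preprocess_intensities(sim$intensities[retained$probe_id, ,
                                                 drop = FALSE],
                                 retained, cfg$half_window, cfg$percentile,
                                 cfg$loess_span)
  norm_df <- data.frame(probe_id = rownames(prep$normalized),
                        prep$normalized, check.names = FALSE)
  write_tsv(norm_df, pth("intensities_normalized.tsv"))
  manifest <- stage_log(manifest, "preprocess",
                        half_window = cfg$half_window,
                        percentile = cfg$percentile, span = cfg$loess_span)

  # -- per-stage statistics, calling, summaries -------------------------
  th <- do.call(scenario_thresholds, cfg$thresholds)
  stage_results <- list()
  for (st in cfg$stages) {
    stats <- probe_stats(prep$normalized, design, st, probes = retained)
    calls <- call_probes(stats$p, stats$chrom, stats$start, th)
    summ <- summarize_calls(calls, stats, ann, intergenic,
                            cfg$include_intronic)
    write_tsv(cbind(stats, calls), pth(sprintf("stats_%s.tsv", st)))
    write_tsv(summ$genes, pth(sprintf("genes_%s.tsv", st)))
    stage_results[[st]] <- list(stats = stats, calls = calls,
                                summary = summ)
    manifest <- stage_log(manifest, paste0("teststats_call_", st),
                          counts = as.list(summ$counts))
  }

  # -- between-stage overlap -------------------------------------------
  overlap <- NULL
  if (length(cfg$stages) >= 2) {
    universe <- length(unique(stats::na.omit(
      merge(retained["probe_id"], sim$probe_gene, by = "probe_id")$gene_id)))
    universe <- max(universe, nrow(ann$genes))
    g1 <- stage_results[[cfg$stages[1]]]$summary$genes$gene_id
    g2 <- stage_results[[cfg$stages[2]]]$summary$genes$gene_id
    overlap <- overlap_test(g1, g2, universe)
    jsonlite::write_json(overlap, pth("overlap.json"), auto_unbox = TRUE,
                         digits = NA)
    manifest <- stage_log(manifest, "overlap", k = overlap$k,
                          p = overlap$p)
  }

  # -- enrichment on chromosomal-window categories ----------------------
  enrichment <- list()
  cats <- list()
  for (ch in names(ann$chrom_lengths)) {
    L <- ann$chrom_lengths[[ch]]
    bounds <- round(seq(1, L + 1, length.out = cfg$enrichment_windows + 1))
    for (w in seq_len(cfg$enrichment_windows)) {
      nm <- sprintf("%s:%d-%d", ch, bounds[w], bounds[w + 1] - 1)
      cats[[nm]] <- positional_category(ann, ch, bounds[w],
                                        bounds[w + 1] - 1)
    }
  }
  write_gmt(cats, pth("categories.gmt"))
  for (st in cfg$stages) {
    for (dirn in c("north", "south")) {
      ranked <- rank_genes(stage_results[[st]]$stats, sim$probe_gene, dirn)
      enr <- enrich_categories(ranked, cats, cfg$n_permutations,
                               seed = cfg$seed + 3L)
      key <- sprintf("%s_%s", st, dirn)
      enrichment[[key]] <- enr
      write_tsv(enr, pth(sprintf("enrichment_%s.tsv", key)))
    }
  }
  manifest <- stage_log(manifest, "enrich",
                        n_categories = length(cats),
                        n_permutations = cfg$n_permutations)

  # -- clinal regression ------------------------------------------------
  cline <- cline_outlier_screen(clin)
  cline_report <- list(
    fit = cline$fit[c("slope", "intercept", "r_squared", "p_value", "n")],
    outliers = cline$outliers,
    refit = if (!is.null(cline$refit)) {
      cline$refit[c("slope", "intercept", "r_squared", "p_value", "n")]
    })
  jsonlite::write_json(cline_report, pth("cline.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  manifest <- stage_log(manifest, "cline",
                        r_squared = cline$fit$r_squared)

  files <- list.files(cfg$outdir, full.names = TRUE)
  files <- files[!basename(files) %in% "manifest.json"]
  manifest$files <- data.frame(file = basename(files),
                               md5 = unname(tools::md5sum(files)),
                               stringsAsFactors = FALSE)
  manifest$config <- unclass(cfg)
  jsonlite::write_json(manifest[c("seed", "files")], pth("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$results <- list(annotation = ann, truth = sim$truth,
                           probe_gene = sim$probe_gene,
                           stages = stage_results, overlap = overlap,
                           enrichment = enrichment, cline = cline)
  invisible(manifest)
}
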