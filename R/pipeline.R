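#' Pipeline configuration and stage orchestration
#'
#' A single validated configuration drives five stages — simulate,
#' catalog, sites, enrich, surrogate — each reading its inputs from and
#' writing its outputs under the configured output directory, so a full
#' run is reproducible from one config and one seed. All randomness
#' derives from `rng_seed` via fixed per-stage offsets.
#'
#' @name pipeline
NULL

pipeline_defaults <- function() {
  list(
    out_dir = "pipeline_out",
    rng_seed = 1L,
    # analysis thresholds
    alpha = 0.05,
    min_reads = 100,
    min_fraction = 0.05,
    fraction_denominator = "arm_total",
    min_site_type = "7mer-A1",
    landscape_step = 100L,
    # simulation: study conditions
    hairpin_length = 110L,
    mature_length = 22L,
    read_depth = 1e5,
    tail_A_rate = 0.3,
    n_genes = 2000L,
    n_planted_targets = 200L,
    effect_delta = 1,
    de_noise_sd = 0.5,
    utr_length = 200L,
    n_studies = 124L,
    coupling_beta = -0.4,
    compendium_noise_sd = 0.1,
    target_fraction = 0.05,
    random_set_size = 500L,
    write_fastq = TRUE
  )
}

# Per-stage seed offsets from the single config seed.
stage_seed <- function(config, stage) {
  offsets <- c(locus = 11L, pool = 12L, utrome = 13L, de = 14L,
               compendium = 15L, random = 16L)
  as.integer(config$rng_seed) + offsets[[stage]]
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list; unknown keys are rejected
#' (strict mode), duplicate YAML keys are an error, defaults are filled
#' in, and every threshold is range-checked before any computation.
#'
#' @param raw Path to a YAML file or a named list of settings.
#' @return A `PipelineConfig` (named list with all keys present).
#' @export
validate_config <- function(raw) {
  if (is.character(raw) && length(raw) == 1) {
    lines <- readLines(raw)
    keys <- sub(":.*$", "", grep("^[A-Za-z_][A-Za-z0-9_]*\\s*:", lines,
                                 value = TRUE))
    keys <- trimws(keys)
    if (anyDuplicated(keys)) {
      stop("duplicate config key: ", keys[duplicated(keys)][1])
    }
    raw <- yaml::read_yaml(raw)
    if (is.null(raw)) raw <- list()
  }
  stopifnot(is.list(raw))
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  config <- utils::modifyList(defaults, raw)

  chk <- function(cond, msg) if (!cond) stop("config error: ", msg)
  chk(config$alpha > 0 && config$alpha < 1, "alpha must be in (0,1)")
  chk(config$min_reads >= 0, "min_reads must be >= 0")
  chk(config$min_fraction >= 0 && config$min_fraction < 1,
      "min_fraction must be in [0,1)")
  chk(config$fraction_denominator %in% c("arm_total", "canonical_only"),
      "fraction_denominator must be arm_total or canonical_only")
  chk(config$min_site_type %in% SITE_TYPES,
      "min_site_type must be a canonical site class")
  chk(config$landscape_step >= 1, "landscape_step must be >= 1")
  chk(config$tail_A_rate >= 0 && config$tail_A_rate <= 1,
      "tail_A_rate must be in [0,1]")
  chk(config$read_depth > 0, "read_depth must be > 0")
  chk(config$n_genes >= 2, "n_genes must be >= 2")
  chk(config$n_planted_targets >= 1 &&
        config$n_planted_targets < config$n_genes,
      "n_planted_targets must be in [1, n_genes)")
  chk(config$de_noise_sd >= 0 && config$compendium_noise_sd >= 0,
      "noise sds must be >= 0")
  chk(config$n_studies >= 2, "n_studies must be >= 2")
  chk(config$target_fraction > 0 && config$target_fraction < 1,
      "target_fraction must be in (0,1)")
  chk(config$random_set_size >= 0, "random_set_size must be >= 0")
  class(config) <- c("PipelineConfig", "list")
  config
}

#' Serialize a configuration to YAML
#' @param config A `PipelineConfig`.
#' @param path Output file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

p_dir <- function(config, ...) {
  d <- file.path(config$out_dir, ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (generate locus, read pool, UTRome, DE table and
#' compendium with truth manifests), `catalog` (isomiR catalog, seed
#' groups, 5' calls, tail composition), `sites` (motifs and predicted
#' target sets for the two most abundant seed groups), `enrich`
#' (ranked landscapes and target statistics on the simulated DE table),
#' `surrogate` (host-gene surrogate summaries, regression and trends on
#' the simulated compendium). Later stages read the files earlier
#' stages wrote under `config$out_dir`.
#'
#' @param stage One of simulate/catalog/sites/enrich/surrogate.
#' @param config A `PipelineConfig` (or anything [validate_config()]
#'   accepts).
#' @return Invisible list of the stage's written file paths.
#' @export
run_stage <- function(stage = c("simulate", "catalog", "sites", "enrich",
                                "surrogate"), config) {
  stage <- match.arg(stage)
  if (!inherits(config, "PipelineConfig")) config <- validate_config(config)
  switch(stage,
         simulate = stage_simulate(config),
         catalog = stage_catalog(config),
         sites = stage_sites(config),
         enrich = stage_enrich(config),
         surrogate = stage_surrogate(config))
}

stage_simulate <- function(config) {
  out <- character(0)
  sim <- p_dir(config, "sim")
  locus <- gen_locus(stage_seed(config, "locus"),
                     hairpin_length = config$hairpin_length,
                     mature_length = config$mature_length)
  out <- c(out, write_locus(locus, file.path(sim, "locus")))
  comp <- default_composition(config$read_depth, config$tail_A_rate)
  pool <- gen_read_pool(locus, comp, stage_seed(config, "pool"))
  out <- c(out, write_read_tsv(pool$reads, file.path(sim, "reads.tsv")))
  utils::write.table(pool$truth, file.path(sim, "reads_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out <- c(out, file.path(sim, "reads_truth.tsv"))
  if (isTRUE(config$write_fastq)) {
    out <- c(out, write_read_fastq(pool$reads, file.path(sim, "reads.fastq")))
  }

  # the two isomiR species of the 3p arm: annotated mature and -1 shift
  refs <- mature_refs(locus)
  ref3 <- refs[refs$arm == "3p", ]
  ctx <- locus_context(locus)
  off <- nchar(locus$flank5)
  iso_shift <- substr(ctx, ref3$start + off + 2L,
                      ref3$start + off + 1L + nchar(ref3$sequence))
  isomirs <- c(stats::setNames(iso_shift, paste0(ref3$name, ".1")),
               stats::setNames(ref3$sequence, paste0(ref3$name, ".2")))
  motif_sets <- lapply(names(isomirs),
                       function(n) site_motifs(isomirs[[n]], isomir = n))
  names(motif_sets) <- names(isomirs)

  planted_genes <- paste0("g", seq_len(config$n_planted_targets))
  planting <- data.frame(gene = planted_genes,
                         isomir = names(isomirs)[1],
                         site_type = "8mer",
                         utr_position = 50L, stringsAsFactors = FALSE)
  utrome <- gen_utrome(config$n_genes, planting, motif_sets,
                       stage_seed(config, "utrome"),
                       utr_length = config$utr_length)
  out <- c(out, write_fasta(utrome$utrs, file.path(sim, "utrome.fa")))
  utils::write.table(utrome$truth, file.path(sim, "utrome_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out <- c(out, file.path(sim, "utrome_truth.tsv"))
  writeLines(names(isomirs), file.path(sim, "isomir_ids.txt"))
  out <- c(out, file.path(sim, "isomir_ids.txt"))

  de <- gen_de_table(planted_genes, config$effect_delta, config$de_noise_sd,
                     config$n_genes, stage_seed(config, "de"))
  out <- c(out, write_de_table(de, file.path(sim, "de_table.tsv")))
  writeLines(planted_genes, file.path(sim, "de_targets.txt"))
  out <- c(out, file.path(sim, "de_targets.txt"))

  cspec <- compendium_spec(config$n_studies, host_gene = "HOSTG",
                           coupling_beta = config$coupling_beta,
                           noise_sd = config$compendium_noise_sd,
                           n_genes = config$n_genes,
                           target_fraction = config$target_fraction,
                           rng_seed = stage_seed(config, "compendium"))
  write_compendium(gen_compendium(cspec), file.path(sim, "compendium"))
  out <- c(out, file.path(sim, "compendium"))
  invisible(out)
}

stage_catalog <- function(config) {
  sim <- file.path(config$out_dir, "sim")
  locus <- read_locus(file.path(sim, "locus"))
  reads <- read_read_tsv(file.path(sim, "reads.tsv"))
  res <- build_catalog(reads, mature_refs(locus), locus_context(locus),
                       context_offset = nchar(locus$flank5))
  cat_dir <- p_dir(config, "catalog")
  tw <- function(x, f) {
    utils::write.table(x, file.path(cat_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    file.path(cat_dir, f)
  }
  out <- tw(res$catalog, "catalog.tsv")
  out <- c(out, tw(res$rejects, "rejects.tsv"))
  ref3 <- mature_refs(locus)$name[mature_refs(locus)$arm == "3p"]
  groups <- group_by_seed(res$catalog[res$catalog$ref == ref3, ])
  out <- c(out, tw(groups, "seed_groups.tsv"))
  calls <- call_5p_isomirs(res$catalog, config$min_reads,
                           config$min_fraction, config$fraction_denominator)
  out <- c(out, tw(calls, "five_prime_calls.tsv"))
  tails <- tail_composition(res$catalog)
  out <- c(out, tw(data.frame(nucleotide = names(tails),
                              count = as.numeric(tails)), "tails.tsv"))
  invisible(out)
}

stage_sites <- function(config) {
  out_dir <- p_dir(config, "sites")
  sim <- file.path(config$out_dir, "sim")
  groups <- utils::read.delim(file.path(config$out_dir, "catalog",
                                        "seed_groups.tsv"),
                              stringsAsFactors = FALSE)
  ids <- readLines(file.path(sim, "isomir_ids.txt"))
  # seed groups sorted by abundance carry suffixes .1/.2; reuse those ids
  reps <- utils::head(groups$representative, 2)
  base <- sub("\\.[12]$", "", ids[1])
  motif_sets <- lapply(seq_along(reps), function(i) {
    site_motifs(reps[i], isomir = paste0(base, ".", i))
  })
  names(motif_sets) <- vapply(motif_sets, function(m) m$isomir, character(1))
  utrome <- read_fasta(file.path(sim, "utrome.fa"))
  out <- character(0)
  for (id in names(motif_sets)) {
    ts <- predict_targets(utrome, motif_sets[[id]], config$min_site_type)
    f <- file.path(out_dir, paste0("targets_", id, ".tsv"))
    writeLines(c("gene", ts$genes), f)
    out <- c(out, f)
    hits <- site_table(utrome, motif_sets[[id]])
    f2 <- file.path(out_dir, paste0("site_hits_", id, ".tsv"))
    utils::write.table(hits, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, f2)
  }
  mj <- file.path(out_dir, "motifs.json")
  jsonlite::write_json(lapply(motif_sets, unclass), mj, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(c(out, mj))
}

stage_enrich <- function(config) {
  out_dir <- p_dir(config, "enrich")
  sim <- file.path(config$out_dir, "sim")
  de <- read_de_table(file.path(sim, "de_table.tsv"))
  utrome <- read_fasta(file.path(sim, "utrome.fa"))
  motifs <- jsonlite::read_json(file.path(config$out_dir, "sites",
                                          "motifs.json"),
                                simplifyVector = TRUE)
  ranked <- rank_genes(de)
  out <- character(0)
  summary <- list()
  for (id in names(motifs)) {
    word <- motifs[[id]][["seven_m8"]]
    ls <- word_landscape(ranked, utrome, word,
                         step = min(config$landscape_step, length(ranked)))
    f <- file.path(out_dir, paste0("landscape_", id, ".tsv"))
    utils::write.table(ls, f, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, f)
    tfile <- file.path(config$out_dir, "sites", paste0("targets_", id, ".tsv"))
    targets <- read_target_list(tfile)
    has_targets <- any(de$gene %in% targets)
    curve <- if (has_targets) cumulative_fraction(de, targets)
    all_curve <- cumulative_fraction(de)
    summary[[id]] <- list(
      word = word, landscape_peak = max(ls$value),
      peak_cutoff = ls$cutoff[which.max(ls$value)],
      n_targets = length(targets),
      pct_targets_down = percent_targets(de, targets, "down", config$alpha),
      pct_targets_up = percent_targets(de, targets, "up", config$alpha),
      mean_target_log2fc = target_fc_summary(de, targets, "mean"),
      median_target_log2fc = target_fc_summary(de, targets, "median"),
      cumfrac_at_minus1 = if (has_targets) curve$value_at(-1) else NA,
      cumfrac_all_at_minus1 = all_curve$value_at(-1)
    )
  }
  sj <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, sj, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(c(out, sj))
}

stage_surrogate <- function(config) {
  out_dir <- p_dir(config, "surrogate")
  comp <- read_compendium(file.path(config$out_dir, "sim", "compendium"))
  studies <- study_comparisons(comp$studies, comp$host_gene)
  studies <- filter_studies(studies, alpha = config$alpha)
  target_sets <- list(planted = comp$targets)
  summaries <- summarize_compendium(studies, target_sets,
                                    random_set_size = config$random_set_size,
                                    rng_seed = stage_seed(config, "random"),
                                    alpha = config$alpha)
  out <- file.path(out_dir, "summaries.tsv")
  utils::write.table(summaries, out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  reg <- list()
  for (id in unique(summaries$set_id)) {
    reg[[id]] <- unclass(regress_targets_vs_host(summaries, id))
    tr <- cumulative_mean_trend(summaries[summaries$set_id == id, ],
                                branch = "from_most_down")
    f <- file.path(out_dir, paste0("trend_", id, ".tsv"))
    utils::write.table(tr, f, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, f)
  }
  ct <- group_contrast(summaries[summaries$set_id == "planted", ])
  rj <- file.path(out_dir, "regression.json")
  jsonlite::write_json(list(regressions = reg, host_group_contrast = ct,
                            n_studies_filtered_out =
                              attr(studies, "n_filtered_out")),
                       rj, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(c(out, rj))
}

#' Run the full pipeline and write a run manifest
#'
#' Executes simulate, catalog, sites, enrich and surrogate in order and
#' writes `run_manifest.json` with the config snapshot, per-stage output
#' paths and MD5 checksums of every output file. Identical config and
#' seed produce byte-identical outputs.
#'
#' @param config A `PipelineConfig`, list, or YAML path.
#' @return Invisible manifest list.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "PipelineConfig")) config <- validate_config(config)
  stages <- c("simulate", "catalog", "sites", "enrich", "surrogate")
  paths <- list()
  for (s in stages) paths[[s]] <- as.character(run_stage(s, config))
  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(config$out_dir, "run_manifest.json"))
  checks <- tools::md5sum(files)
  names(checks) <- sub(paste0("^", config$out_dir, "/?"), "", names(checks))
  manifest <- list(config = unclass(config),
                   stages = paths,
                   checksums = as.list(checks))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(manifest)
}
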