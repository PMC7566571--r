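#!/usr/bin/env Rscript
# Stage 4 — ranked-list enrichment and target fold-change statistics.
#
# Ranks the simulated DE table from most down- to most up-regulated,
# computes the signed -log10 hypergeometric landscape for each isomiR's
# 7mer-m8 site word, and summarizes predicted-target repression:
# percent of targets among significantly down/up genes, mean/median
# target log2FC, and cumulative fractions at log2FC -1.
#
# Usage: Rscript analysis/04_enrichment.R [seed]

suppressMessages(library(isomiRscope))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

cfg <- validate_config(list(out_dir = "results/pipeline", rng_seed = seed))
run_stage("enrich", cfg)

summary <- jsonlite::read_json(
  file.path(cfg$out_dir, "enrich", "summary.json"), simplifyVector = TRUE)
for (id in names(summary)) {
  s <- summary[[id]]
  fmt <- function(x) if (is.null(x)) "undefined" else round(unlist(x), 3)
  cat(id, "(site word", s$word, "):\n")
  cat("  landscape peak", round(s$landscape_peak, 1),
      "at leading-set cutoff", s$peak_cutoff, "\n")
  cat("  % targets in down-regulated genes:", fmt(s$pct_targets_down),
      "; in up-regulated:", fmt(s$pct_targets_up), "\n")
  cat("  mean target log2FC:", fmt(s$mean_target_log2fc),
      "; cumulative fraction below -1:", fmt(s$cumfrac_at_minus1),
      "(all genes:", fmt(s$cumfrac_all_at_minus1), ")\n")
}
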