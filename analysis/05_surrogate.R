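#!/usr/bin/env Rscript
# Stage 5 — host-gene surrogate inverse-correlation analysis.
#
# Filters the simulated compendium for studies where the host gene
# changes significantly, summarizes each study (mean target log2FC,
# percent of targets among up/down genes, up/down enrichment ratio,
# plus a 500-gene random control), regresses mean target fold change
# on host fold change, and contrasts host-down vs host-up studies.
#
# Usage: Rscript analysis/05_surrogate.R [seed]

suppressMessages(library(isomiRscope))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

cfg <- validate_config(list(out_dir = "results/pipeline", rng_seed = seed))
run_stage("surrogate", cfg)

reg <- jsonlite::read_json(
  file.path(cfg$out_dir, "surrogate", "regression.json"),
  simplifyVector = TRUE)
cat(reg$n_studies_filtered_out,
    "studies dropped (host change not significant)\n")
for (id in names(reg$regressions)) {
  r <- reg$regressions[[id]]
  cat(sprintf("%s: slope %.3f, r^2 %.3f, P %.3g over %d studies\n",
              id, r$slope, r$r_squared, r$p_value, r$n_studies))
}
ct <- reg$host_group_contrast
cat(sprintf(
  "mean target log2FC: %.3f in host-down vs %.3f in host-up studies (P %.3g)\n",
  ct$mean_host_down, ct$mean_host_up, ct$p_value))
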