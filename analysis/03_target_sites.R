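#!/usr/bin/env Rscript
# Stage 3 — derive site motifs and predict targets per isomiR.
#
# Takes the two most abundant seed groups from the catalog, derives
# their 6mer/7mer-A1/7mer-m8/8mer site motifs, scans the simulated
# UTRome, and writes per-isomiR predicted target sets (default
# stringency 7mer-A1). Also reports the unique-target split between
# the two isomiRs.
#
# Usage: Rscript analysis/03_target_sites.R [seed]

suppressMessages(library(isomiRscope))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

cfg <- validate_config(list(out_dir = "results/pipeline", rng_seed = seed))
run_stage("sites", cfg)

motifs <- jsonlite::read_json(file.path(cfg$out_dir, "sites", "motifs.json"),
                              simplifyVector = TRUE)
sets <- list()
for (id in names(motifs)) {
  cat(id, ": 6mer", motifs[[id]]$six_mer, " 7m8", motifs[[id]]$seven_m8,
      " 8mer", motifs[[id]]$eight_mer, "\n")
  sets[[id]] <- read_target_list(
    file.path(cfg$out_dir, "sites", paste0("targets_", id, ".tsv")))
  cat("  predicted targets at", cfg$min_site_type, ":",
      length(sets[[id]]), "genes\n")
}
ids <- names(sets)
cat("unique to", ids[1], ":",
    length(unique_targets(sets, ids[1], ids[2])), "genes\n")
cat("unique to", ids[2], ":",
    length(unique_targets(sets, ids[2], ids[1])), "genes\n")
cat("shared:", length(intersect(sets[[1]], sets[[2]])), "genes\n")
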