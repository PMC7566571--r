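#!/usr/bin/env Rscript
# Stage 2 — catalogue isomiRs from the simulated read pool.
#
# Aligns every distinct read to the mature references inside the
# hairpin-plus-flank context, classifies isomiR type (canonical /
# 5prime_only / 3prime_only / mixed) and templated status, extracts
# seeds, groups reads by seed heptamer and applies the strict 5' isomiR
# thresholds (>100 reads and >5% of the miRNA's reads).
#
# Usage: Rscript analysis/02_catalog.R [seed]

suppressMessages(library(isomiRscope))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

cfg <- validate_config(list(out_dir = "results/pipeline", rng_seed = seed))
run_stage("catalog", cfg)

catalog <- read.delim(file.path(cfg$out_dir, "catalog", "catalog.tsv"))
catalog$nontemplated_tail[is.na(catalog$nontemplated_tail)] <- ""
total <- sum(catalog$count)
cat("catalogued", total, "reads,", nrow(catalog), "distinct sequences\n")
cat("isomiR type composition (% of reads):\n")
print(round(100 * tapply(catalog$count, catalog$category, sum) / total, 1))
cat("templated reads:",
    round(100 * sum(catalog$count[catalog$templated]) / total, 1), "%\n")

groups <- read.delim(file.path(cfg$out_dir, "catalog", "seed_groups.tsv"),
                     colClasses = c(suffix_name = "character"))
cat("seed groups (suffix, seed, % of miRNA reads):\n")
print(groups[, c("suffix_name", "seed", "fraction_of_mirna")])

calls <- read.delim(file.path(cfg$out_dir, "catalog",
                              "five_prime_calls.tsv"))
cat(sum(calls$passes), "sequences pass the 5' isomiR thresholds\n")
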