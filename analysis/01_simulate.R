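#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic ED registry.
#
# Generates a code universe of ~510 ICD-10 codes in four latent admission-risk
# tiers (centres 4.7%/19.5%/47.8%/78%) with Zipf-like frequencies, then draws
# presentation-level records with covariates and admission outcomes, and
# writes the registry for the downstream stages.
# Usage: Rscript analysis/01_simulate.R [--n 215477] [--seed 1] [--out results/analysis]

suppressPackageStartupMessages(library(edrisk))
args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- which(args == flag); if (length(i)) args[i + 1] else default
}
n <- as.integer(arg("--n", "215477"))
seed <- as.integer(arg("--seed", "1"))
out <- arg("--out", "results/analysis")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_presentations = n, seed = seed)
universe <- generate_code_universe(cfg)
registry <- generate_presentations(universe, cfg)
write_registry(registry, file.path(out, "registry.csv"))
utils::write.csv(universe, file.path(out, "code_universe.csv"),
                 row.names = FALSE)

message(sprintf("simulated %d presentations over %d codes (seed %d)",
                nrow(registry), nrow(universe), seed))
message(sprintf("overall admission rate: %.1f%% (frequency-weighted true risk %.1f%%)",
                100 * mean(registry$admitted),
                100 * sum(universe$frequency_weight * universe$true_risk)))
message(sprintf("tier presentation shares: %s",
                paste(sprintf("%.1f%%", 100 * tapply(
                  universe$frequency_weight, universe$tier, sum)),
                  collapse = ", ")))
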