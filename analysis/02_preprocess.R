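#!/usr/bin/env Rscript
# Stage 2: preprocess the registry.
#
# Drops records without a primary diagnosis or disposition, imputes trivially
# missing fields, categorizes vitals (hypo/normal/hyper at 90-130 mm Hg,
# 60-90 bpm, 35.5-37.5 degC, boundaries inclusive) and CCI (0 / 1-2 / 3-4 /
# >=5), and excludes codes with fewer than 15 presentations.
# Usage: Rscript analysis/02_preprocess.R [--min-count 15] [--dir results/analysis]

suppressPackageStartupMessages(library(edrisk))
args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- which(args == flag); if (length(i)) args[i + 1] else default
}
dir <- arg("--dir", "results/analysis")
min_count <- as.integer(arg("--min-count", "15"))

registry <- read_registry(file.path(dir, "registry.csv"))
prep <- preprocess_registry(registry, min_count = min_count)
write_registry(prep$records, file.path(dir, "registry_filtered.csv"))
jsonlite::write_json(unclass(prep$filter_report),
                     file.path(dir, "filter_report.json"),
                     auto_unbox = TRUE, digits = NA)

print(prep$filter_report)
message(sprintf("dropped (no diagnosis/disposition): %d; imputed cells: %d",
                nrow(prep$dropped), nrow(prep$imputation_log)))
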