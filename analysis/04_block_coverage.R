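#!/usr/bin/env Rscript
# Stage 4: WHO ICD-10 block aggregation, cumulative coverage, dominant blocks.
#
# Maps codes to WHO blocks by 3-character prefix, ranks blocks by frequency
# for the cumulative-coverage reduction (60/70/80/90/100%), identifies blocks
# with >= 75% of their presentations in a single cluster, and exports the
# heatmap proportion matrix for the top-80%-coverage blocks.
# Usage: Rscript analysis/04_block_coverage.R [--dir results/analysis]

suppressPackageStartupMessages(library(edrisk))
args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- which(args == flag); if (length(i)) args[i + 1] else default
}
dir <- arg("--dir", "results/analysis")

records <- read_registry(file.path(dir, "registry_clustered.csv"))
clusters <- utils::read.csv(file.path(dir, "presentation_clusters.csv"))
records$cluster <- clusters$cluster[match(records$id, clusters$id)]

blocks <- icd10_blocks()
bs <- summarize_blocks(records, blocks)
coverage <- cumulative_coverage(bs, c(0.6, 0.7, 0.8, 0.9, 1.0))
utils::write.csv(coverage$ranked, file.path(dir, "coverage.csv"),
                 row.names = FALSE)
message(sprintf("%d nonempty blocks; blocks at 60/70/80/90/100%% coverage: %s",
                nrow(bs$summary),
                paste(coverage$blocks_at_threshold, collapse = ", ")))

k <- bs$k
dominant <- lapply(seq_len(k), function(cl) dominant_blocks(bs, 0.75, cl))
for (cl in seq_len(k)) {
  d <- dominant[[cl]]
  message(sprintf(
    "cluster %d: %d blocks with >=75%% representation, %d presentations (%.1f%% of registry)",
    cl, nrow(d$blocks), d$n_presentations, d$share_pct))
}
jsonlite::write_json(
  lapply(dominant, function(d) list(n_blocks = nrow(d$blocks),
                                    n_presentations = d$n_presentations,
                                    share_pct = d$share_pct,
                                    blocks = d$blocks)),
  file.path(dir, "dominant_blocks.json"), dataframe = "rows",
  auto_unbox = TRUE, digits = NA)

heat <- heatmap_matrix(bs, blocks, coverage_threshold = 0.8)
utils::write.csv(data.frame(block_id = rownames(heat),
                            chapter = attr(heat, "chapter"), heat,
                            row.names = NULL, check.names = FALSE),
                 file.path(dir, "heatmap_matrix.csv"), row.names = FALSE)
message(sprintf("heatmap matrix: %d blocks x %d clusters", nrow(heat), ncol(heat)))
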