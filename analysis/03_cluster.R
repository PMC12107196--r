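#!/usr/bin/env Rscript
# Stage 3: per-code admission risks, cluster-count selection and clustering.
#
# Computes each code's admission risk, evaluates k = 1..8 with the elbow
# (WCSS), gap statistic, silhouette, Calinski-Harabasz and Davies-Bouldin
# indices, then clusters at k = 4 (manual override recorded alongside the
# parsimony and argmax choices) and propagates labels to presentations.
# Usage: Rscript analysis/03_cluster.R [--k 4] [--seed 1] [--dir results/analysis]

suppressPackageStartupMessages(library(edrisk))
args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- which(args == flag); if (length(i)) args[i + 1] else default
}
dir <- arg("--dir", "results/analysis")
k <- as.integer(arg("--k", "4"))
seed <- as.integer(arg("--seed", "1"))

records <- categorize_records(read_registry(file.path(dir, "registry_filtered.csv")))
risks <- compute_code_risks(records)
values <- stats::setNames(risks$risk, risks$code)

report <- cluster_selection_report(values, k_range = 1:8, n_init = 50,
                                   n_reference = 100, seed = seed)
print(report)
sel <- select_k(report, "manual", override = k)
message(sprintf("selected k = %d (gap argmax %d, gap parsimony %d)",
                sel$k, sel$gap_max_k, sel$gap_1se_k))

model <- report$models[[as.character(sel$k)]]
risks$cluster <- unname(model$cluster[risks$code])
clustered <- propagate_clusters(records, model)

utils::write.csv(risks, file.path(dir, "code_risks.csv"), row.names = FALSE)
utils::write.csv(data.frame(code = names(model$cluster),
                            cluster = unname(model$cluster)),
                 file.path(dir, "cluster_assignment.csv"), row.names = FALSE)
jsonlite::write_json(report$summary, file.path(dir, "selection_report.json"),
                     dataframe = "rows", auto_unbox = TRUE, digits = NA,
                     na = "null")
utils::write.csv(descriptive_table(clustered), file.path(dir, "table1.csv"),
                 row.names = FALSE)
write_registry(clustered[, c("id", "icd10", "admitted", "age", "sex",
                             "ethnicity", "sbp", "pulse", "temp", "cci",
                             "prior_ed", "prior_inpt", "prior_surg",
                             "prior_icu", "prior_hd", "prior_ica",
                             "prior_infect")],
               file.path(dir, "registry_clustered.csv"))
utils::write.csv(data.frame(id = clustered$id, cluster = clustered$cluster),
                 file.path(dir, "presentation_clusters.csv"), row.names = FALSE)

rates <- tapply(clustered$admitted, clustered$cluster, mean)
message(sprintf("cluster sizes: %s",
                paste(as.integer(table(clustered$cluster)), collapse = ", ")))
message(sprintf("admission rates: %s",
                paste(sprintf("%.1f%%", 100 * rates), collapse = ", ")))
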