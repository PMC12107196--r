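# edrisk

Admission-risk stratification of emergency department (ED) presentations by
ICD-10 diagnosis code.

A large share of ambulatory, low-acuity ED visits could plausibly be managed
in alternative care pathways (urgent-care or primary-care clinics,
telemedicine). A pragmatic way to find candidate groups is to let the data
stratify themselves: estimate, for every primary ICD-10 diagnosis code, the
fraction of its presentations that ended in inpatient admission, cluster the
codes on that one-dimensional risk scale, and then aggregate the codes into
WHO ICD-10 blocks to get a category set small enough to act on. `edrisk`
implements that full analysis for health-services researchers and ED
operations teams, together with a synthetic-registry generator so the whole
pipeline runs and is tested without access to restricted hospital data.

## What it computes

For code $c$ with $n_c$ presentations and $a_c$ admissions, the admission
risk is $r_c = a_c/n_c$. Codes with fewer than 15 presentations are
excluded. The risk vector is clustered with one-dimensional k-means
(Lloyd's algorithm, 50 restarts), minimising the within-cluster sum of
squares $W = \sum_j \sum_{c \in C_j} (r_c - \mu_j)^2$; an exact
dynamic-programming solver provides the global optimum as a verification
oracle. The number of clusters is assessed with the elbow curve, the gap
statistic $\mathrm{gap}(k) = \tfrac1B \sum_b \log W^*_{kb} - \log W_k$,
silhouette scores, and the Calinski-Harabasz and Davies-Bouldin indices.
Clusters are labelled in order of risk (cluster 1 = lowest).

Codes map to WHO ICD-10 blocks by their first three characters; blocks are
ranked by frequency to find how many cover 60-100% of presentations, and
blocks with ≥75% of their presentations in one cluster are flagged as
dominant for it. Finally, a proportional-odds model
$\mathrm{logit}\,P(Y \le j \mid x) = \theta_j - \beta^\top x$ (fitted by
Newton-Raphson, Wald 95% CIs) relates presentation characteristics — age,
sex, ethnicity, categorized vitals and Charlson index, prior six-month
utilisation — to cluster membership, with $e^\beta > 1$ meaning higher odds
of a higher-risk cluster.

## Worked example

```r
library(edrisk)
run <- run_pipeline(pipeline_config(
  simulation = sim_config(n_presentations = 50000L),
  seed = 42L))
print(run)
#> ED admission-risk stratification run
#>   presentations analyzed: 49471 (of 50000 raw; 0 dropped, 529 filtered)
#>   code-level clustering: 467 units, k = 4
#>   cluster sizes: 32222, 9557, 5419, 2273
#>   admission rates: 5.7%, 21.7%, 48.8%, 77.8%
```

The filter removed 529 presentations (1.1%) spread over rare codes; the 467
surviving codes were clustered at k = 4, giving a large low-risk cluster
(5.7% admitted) and a small high-risk one (77.8% admitted). The selection
report shows why 4 is a defensible choice even though the one-standard-error
gap rule stops at 2:

```r
print(run$selection$report)
#> Cluster-count selection report
#>  k     wcss      gap    s_k silhouette calinski_harabasz davies_bouldin
#>  1 33.73100 -0.01857 0.0400         NA                NA             NA
#>  2  5.85980  0.34530 0.0430      0.750            2211.7          0.403
#>  3  2.81380  0.26570 0.0409      0.712            2549.1          0.373
#>  4  1.08090  0.63920 0.0420      0.696            4662.0          0.374
#>  5  0.83412  0.43700 0.0391      0.666            4555.2          0.452
#>  ...
```

The gap statistic peaks at k = 4 (0.639), where the silhouette is still
0.70 and Calinski-Harabasz jumps to 4662 — the four-tier structure of the
simulated registry is recovered. Dominant low-risk blocks are where
redirection candidates live:

```r
d <- run$dominant$cluster_1
sprintf("%d blocks are >=75%% cluster 1, covering %d presentations (%.1f%%)",
        nrow(d$blocks), d$n_presentations, d$share_pct)
#> "55 blocks are >=75% cluster 1, covering 27194 presentations (55.0%)"
```

So 55 ICD-10 blocks sit almost entirely in the lowest-risk cluster and
account for 55% of all visits in this simulated cohort.

The same stages are available as numbered drivers for a file-based workflow:

```sh
Rscript analysis/01_simulate.R   --n 215477 --seed 1
Rscript analysis/02_preprocess.R
Rscript analysis/03_cluster.R    --k 4
Rscript analysis/04_block_coverage.R
Rscript analysis/05_associate.R
```

each reading and writing delimited text under `results/analysis/`.

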