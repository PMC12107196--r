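---
title: "Stratifying ED presentations by admission risk: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying ED presentations by admission risk: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edrisk)
```

## The problem

Emergency departments see a large volume of ambulatory, low-acuity
presentations, a substantial share of which could plausibly be managed
through alternative care pathways (urgent-care clinics, primary care,
telemedicine). A pragmatic way to find candidate groups is to stratify
presentations by their risk of ending in an inpatient admission, using the
primary ICD-10 diagnosis code as the unit of description: the admission risk
of a code is simply the fraction of presentations carrying that code that
were admitted.

`edrisk` implements that analysis end to end: per-code risk estimation,
one-dimensional k-means clustering of the risks with full model-selection
machinery, aggregation of codes into WHO ICD-10 blocks with a
cumulative-coverage reduction and dominant-block identification, and a
proportional-odds model relating presentation characteristics to risk-cluster
membership. Because presentation-level hospital registries cannot be shared,
the package also ships a synthetic-registry generator that reproduces the
statistical structure the analysis assumes, so every stage is testable
without any data access.

## Per-code risk and one-dimensional k-means

Each presentation contributes one primary diagnosis. For code $c$ with $n_c$
presentations of which $a_c$ were admitted, the risk is $r_c = a_c / n_c$.
Codes with fewer than 15 presentations are excluded beforehand (the filter
keeps risk estimates stable while typically removing well under 1% of
records; 10 is the conventional sensitivity setting).

Clustering operates on the vector of code risks — one point per code,
unweighted by code frequency, since the natural reading of "grouping
diagnosis codes by risk" is that codes, not visits, are the clustered units.
A `weights` argument exists for frequency-weighted variants but is off by
default. Distances are squared Euclidean on the raw risk fraction; risks are
already commensurate on $[0,1]$, so no transform is applied.

`kmeans_1d()` is Lloyd's algorithm: initial centroids drawn without
replacement from the *distinct* values (sampling distinct values avoids
coincident initial centroids when risks tie), nearest-centroid assignment
with ties going to the lower-risk centroid, mean updates, and termination
when the largest centroid movement drops below `tol` (default `1e-10`) or
after `max_iter = 300` iterations. An empty cluster is repaired by reseeding
its centroid at the point farthest from its current centroid, keeping $k$
fixed. The best of `n_init = 50` random restarts by WCSS is returned, and
labels are renumbered so that cluster 1 always has the lowest-risk centroid.

In one dimension the globally optimal partition is computable:
optimal clusters are contiguous intervals of the sorted values, so
`kmeans_1d_exact()` solves the problem by dynamic programming over segment
boundaries (ties in the argmin break toward the smallest segment start, making
it deterministic). The exact solver plays two roles: it is the verification
oracle for Lloyd's algorithm in the test suite (on small instances with 50
restarts the two must agree exactly), and it computes the within-cluster
sums of squares inside the gap statistic, where determinism given the seed
matters more than fidelity to the restarted heuristic.

## Choosing the number of clusters

`cluster_selection_report()` evaluates a contiguous range of $k$ with:

* **WCSS** (the elbow curve), non-increasing in $k$;
* the **gap statistic**, $\mathrm{gap}(k) = \frac{1}{B}\sum_b \log W^*_{kb} -
  \log W_k$, with $B = 100$ reference datasets drawn uniformly on
  $[\min(r), \max(r)]$ and $s_k = \mathrm{sd}_b(\log W^*_{kb})\sqrt{1 + 1/B}$;
* the mean **silhouette** $s_i = (b_i - a_i)/\max(a_i, b_i)$ with absolute
  distance (points in singleton clusters score 0);
* the **Calinski-Harabasz** index $(B/(k-1))/(W/(n-k))$; and
* the **Davies-Bouldin** index, mean over clusters of
  $\max_{j \ne i} (s_i + s_j)/d_{ij}$ with $s_i$ the mean absolute deviation
  from the centroid.

`select_k()` implements three rules. `gap_1se` is the parsimony rule
(smallest $k$ with $\mathrm{gap}(k) \ge \mathrm{gap}(k+1) - s_{k+1}$);
`gap_max` takes the argmax. The pipeline default is `manual` with an
override of 4: on data with the four-tier risk structure this package
targets, the parsimony rule tends to stop at 2 while the gap curve peaks at
4, and the four-way split is the clinically meaningful one (it separates a
"nearly always admitted" tail from a broad low-risk mass). The full report
is always recorded alongside the choice, so the statistical evidence for
other $k$ remains inspectable.

## Block aggregation and coverage reduction

Codes map to WHO ICD-10 blocks by their first three characters
(upper-cased), located in the packaged block table by lexicographic range
containment; the table is a transcription of the WHO ICD-10 (2019) tabular
list block structure (254 blocks, chapters I–XXII) and can be replaced by
any table with the same three columns. Unmapped codes are an error by
default, or can be collected into an `UNMAPPED` pseudo-block.

Blocks are ranked by presentation count (ties alphabetical by block id, for
determinism) and the cumulative-coverage curve reports how many top blocks
are needed to reach 60/70/80/90/100% of presentations. A block is *dominant*
for a cluster when at least 75% of its presentations fall in that cluster —
the comparison is `>=`, reading "75% representation" inclusively.
Proportions are computed over presentations by default; a `basis = "codes"`
flag switches to distinct-code proportions, since both readings of "block
composition" are defensible and presentations are the one that connects to
sample-share percentages.

## The proportional-odds model

Cluster membership (ordered 1 = lowest risk) is modelled as

$$\mathrm{logit}\, P(Y \le j \mid x) = \theta_j - \beta^\top x,
\qquad j = 1, \dots, k - 1,$$

so a positive coefficient — an odds ratio $e^\beta > 1$ — reads "higher odds
of membership in a higher-risk cluster". Covariates are age in years
(untransformed), sex (reference female), ethnicity (reference Chinese, the
modal category), categorized systolic blood pressure, pulse and temperature
(reference normal; hypotension <90, normal 90–130, hypertension >130 mm Hg;
bradycardia <60, normal 60–90, tachycardia >90 bpm; hypothermia <35.5,
normal 35.5–37.5, hyperthermia >37.5 °C — written ranges inclusive at both
ends), categorized Charlson Comorbidity Index (none 0, mild 1–2, moderate
3–4, severe ≥5; reference none), and seven prior six-month utilisation
counts entered per unit.

The fit is maximum likelihood by Newton–Raphson on the joint parameter
vector $(\theta, \beta)$ with analytic gradient and Hessian, step-halving
whenever a step would decrease the log-likelihood or violate the
monotonicity of $\theta$, convergence at score sup-norm below `1e-8`, and at
most 100 iterations. Standard errors come from the inverse observed
information and 95% intervals are Wald, $\exp(\beta \pm 1.96\,\mathrm{se})$.
Diverging coefficients (any $|\beta| > 30$) raise an explicit separation
error rather than a silently absurd fit. The implementation is cross-checked
in the test suite against an independent cumulative-logit fitter with the
same parameterisation, and against simulation: data generated from the model
return the generating coefficient inside the 95% interval at the nominal
rate. No proportional-odds (Brant-type) diagnostic is computed; the design
spec is the natural place to hang one, and the hook is deliberately left to
the user.

## What the synthetic registry emulates — and what it does not

The generator is the package's stand-in for a restricted hospital registry,
and its defaults are the study conditions used throughout the tests:

* **~510 codes in four latent risk tiers** with Beta-distributed true risks
  centred at 4.7%, 19.5%, 47.8% and 78% (concentration `tier_risk_spread`,
  default 500; `Inf` collapses risks onto the centres) and tier sizes
  262/104/66/78 codes.
* **Zipf rank-frequency weights** `rank^-1`. Under the default
  `"tier_mass"` allocation, ranks are dealt to tiers by a greedy
  largest-deficit fill so the tiers' presentation masses track
  61/20.6/12.9/5.5%, which makes the frequency-weighted mean risk — and
  hence the overall admission rate — land near 17.3%. A pure random rank
  permutation (`"random"`) is available, but it gives every tier a
  presentation share equal to its code share and drifts the overall rate
  toward 24%; the mass-targeted default is what keeps the simulated cohort's
  headline rate realistic.
* **Covariates** drawn from marginals matched to an ambulatory ED cohort
  (age truncated-normal 46.2 ± 19.4 years; 53.4% male; vitals calibrated to
  give ~0.1% hypotension, ~41% hypertension, ~3.6% bradycardia, ~27%
  tachycardia, ~2% hypothermia, ~8% hyperthermia; CCI categories
  82/11/3.8/3.4%; sparse overdispersed negative-binomial prior-utilisation
  counts).
* **Admission** drawn per presentation from
  $\mathrm{logit}\,p = \mathrm{logit}(r_{\text{code}}) + \gamma^\top
  (x - \bar{x})$, with default effect magnitudes of the size reported for
  such cohorts (tachycardia 1.46, hyperthermia 2.32, CCI mild/moderate/severe
  2.55/3.50/5.28, recent surgery 1.31, inpatient admission 1.16, and mildly
  protective recent ED/ICU/high-dependency contact at 0.85–0.86, all as odds
  ratios). Centring at the sample means keeps each code's configured risk
  interpretable as its marginal admission probability, up to a small Jensen
  correction.

One structural feature of real data is deliberately absent: in the
generator, *which* code a presentation carries is independent of the
covariates. Covariates shift admission within a code, not the case mix. A
consequence worth knowing: the ordinal model fitted to a synthetic registry
produces odds ratios near 1, because cluster membership is a function of the
code alone. Passing tests therefore demonstrate that the ordinal machinery
recovers known coefficients when data are generated from the
proportional-odds model itself (which is how the recovery and coverage
suites are built), not that the generator reproduces real-world case-mix
correlation. The generator also ignores secondary diagnoses, temporal
shifts in case mix (e.g. epidemic respiratory waves), and the mechanics of
look-back windows — prior-encounter counts are drawn directly.

All randomness flows from one explicit integer seed (the universe uses
`seed`, the presentations `seed + 1`; pipeline stages derive small fixed
offsets), through a scoped RNG so no global state is disturbed. Identical
configuration and seed reproduce results bit for bit.

## Numerical conventions

* Reported percentages are rounded to one decimal, half away from zero.
* Nearest-centroid ties go to the lower-risk centroid; dominant-cluster ties
  to the lower label; coverage ranking ties are alphabetical; the DP argmin
  tie-breaks toward the smallest segment start.
* The gap statistic refuses degenerate (all-equal) inputs; the
  Calinski-Harabasz index refuses zero within-cluster dispersion; the
  Davies-Bouldin index refuses coincident centroids — in each case an error
  beats a misleading number.
* The low-frequency filter is idempotent, and imputation (column mean or
  median for numeric fields, mode for categorical demographics) never
  touches observed values. Records missing a primary diagnosis or
  disposition are dropped and counted, never imputed.

## Problem sizes in the test and acceptance suites

The suites balance fidelity against runtime on a single CPU: exact-oracle
equivalence uses 500 random instances with $n \le 12$, $k \le 4$; the
validity-index oracles 200 random instances; end-to-end tier recovery 10
seeds of a 200,000-presentation, 510-code registry (adjusted Rand index
against the true tiers, mean ≥ 0.95); ordinal recovery one fit at
$n = 100{,}000$ plus 200 replicates at $n = 20{,}000$ for interval coverage;
and the bundled acceptance script one full pipeline at 215,477
presentations. These sizes are choices, not limits; everything scales
linearly except the $O(kn^2)$ dynamic program, which is comfortable into the
low thousands of codes.

## Known limitations

* The analysis treats the primary diagnosis as the whole clinical picture;
  multimorbidity enters only through the Charlson score.
* Admission risk is taken as a property of the code, estimated without
  shrinkage; rare codes near the filter threshold carry binomial noise of
  several percentage points, which is why the filter exists.
* The manual choice of $k = 4$ is a judgment call, supported but not
  dictated by the indices; the report keeps the evidence for alternatives.
* Real registries require a terminology mapping step (e.g. SNOMED CT to
  ICD-10) upstream of this package; that mapping, and the construction of
  the Charlson score from discharge histories, are out of scope — the
  registry format expects a code and a precomputed score per presentation.
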