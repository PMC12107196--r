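#' Silhouette scores for a one-dimensional clustering
#'
#' For each point, `a` is its mean absolute distance to the other members of
#' its own cluster and `b` the smallest mean absolute distance to the members
#' of any other cluster; the silhouette is `s = (b - a) / max(a, b)`. Points
#' in singleton clusters score 0, as do duplicate points with `a = b = 0`.
#' The mean is unweighted over points. Scores near 1 indicate compact,
#' well-separated clusters; scores near 0 a point on a cluster boundary; and
#' negative scores likely misclassification.
#'
#' @param values numeric vector.
#' @param labels integer cluster labels (at least 2 distinct).
#' @return list with `mean` and per-point `scores` in `[-1, 1]`.
#' @export
silhouette_1d <- function(values, labels) {
  v <- as.numeric(values)
  lab <- as.integer(labels)
  stopifnot(length(v) == length(lab))
  ks <- sort(unique(lab))
  if (length(ks) < 2) {
    abort("silhouette requires at least 2 clusters", "edrisk_domain_error")
  }
  n <- length(v)
  d <- abs(outer(v, v, "-"))
  sizes <- as.numeric(table(factor(lab, levels = ks)))
  # mean distance from every point to each cluster (own cluster excludes self)
  colsum <- vapply(ks, function(kk) rowSums(d[, lab == kk, drop = FALSE]),
                   numeric(n))
  scores <- numeric(n)
  for (i in seq_len(n)) {
    own <- match(lab[i], ks)
    if (sizes[own] == 1) { scores[i] <- 0; next }
    a <- colsum[i, own] / (sizes[own] - 1)
    b <- min(colsum[i, -own] / sizes[-own])
    m <- max(a, b)
    scores[i] <- if (m == 0) 0 else (b - a) / m
  }
  list(mean = mean(scores), scores = scores)
}

#' Calinski-Harabasz index
#'
#' Ratio of between-cluster to within-cluster dispersion,
#' `(B / (k - 1)) / (W / (n - k))` with `B` the size-weighted squared
#' deviation of centroids from the grand mean and `W` the within-cluster sum
#' of squares. Higher is better separated.
#'
#' @inheritParams silhouette_1d
#' @return the index (a single number).
#' @export
calinski_harabasz <- function(values, labels) {
  v <- as.numeric(values)
  lab <- as.integer(labels)
  ks <- sort(unique(lab))
  k <- length(ks)
  n <- length(v)
  if (k < 2 || k >= n) {
    abort("Calinski-Harabasz requires 2 <= k < n", "edrisk_domain_error")
  }
  cen <- vapply(ks, function(kk) mean(v[lab == kk]), numeric(1))
  sizes <- vapply(ks, function(kk) sum(lab == kk), numeric(1))
  B <- sum(sizes * (cen - mean(v))^2)
  W <- sum((v - cen[match(lab, ks)])^2)
  if (W == 0) {
    abort("within-cluster dispersion is zero; index undefined",
          "edrisk_domain_error")
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst-case similarity
#' `max_{j != i} (s_i + s_j) / d_ij`, where `s_i` is the mean absolute
#' deviation of cluster `i` from its centroid and `d_ij` the distance between
#' centroids. Lower is better separated.
#'
#' @inheritParams silhouette_1d
#' @return the index (a single number).
#' @export
davies_bouldin <- function(values, labels) {
  v <- as.numeric(values)
  lab <- as.integer(labels)
  ks <- sort(unique(lab))
  k <- length(ks)
  if (k < 2) abort("Davies-Bouldin requires k >= 2", "edrisk_domain_error")
  cen <- vapply(ks, function(kk) mean(v[lab == kk]), numeric(1))
  if (anyDuplicated(cen)) {
    abort("coincident centroids; index undefined", "edrisk_domain_error")
  }
  s <- vapply(seq_along(ks), function(i) mean(abs(v[lab == ks[i]] - cen[i])),
              numeric(1))
  r <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i),
               function(j) (s[i] + s[j]) / abs(cen[i] - cen[j]), numeric(1)))
  }, numeric(1))
  mean(r)
}

#' Gap statistic for choosing the number of clusters
#'
#' Tibshirani's formulation: `gap(k) = mean_b log(W*_kb) - log(W_k)`, where
#' the `W*_kb` are within-cluster sums of squares of `B` reference datasets
#' drawn uniformly on `[min(values), max(values)]` and clustered at `k`, and
#' `s_k = sd_b(log W*_kb) * sqrt(1 + 1/B)`. Both the data and the references
#' are clustered with the exact dynamic program ([kmeans_1d_exact()]), so the
#' statistic is deterministic given `seed`.
#'
#' @param values numeric vector (not all equal).
#' @param k_range integer vector of cluster counts to evaluate.
#' @param n_reference number of uniform reference datasets `B` (>= 10).
#' @param seed integer seed for the reference draws.
#' @return data frame with columns `k`, `wcss`, `log_wcss`, `gap`, `s_k`.
#' @export
gap_statistic <- function(values, k_range, n_reference = 100L, seed = NULL) {
  v <- as.numeric(values)
  if (length(unique(v)) < 2) {
    abort("gap statistic undefined for degenerate (all-equal) values",
          "edrisk_domain_error")
  }
  if (n_reference < 10) abort("n_reference must be >= 10", "edrisk_domain_error")
  k_range <- sort(unique(as.integer(k_range)))
  kmax <- max(k_range)
  if (kmax >= length(unique(v))) {
    abort("max(k_range) must be below the number of distinct values",
          "edrisk_domain_error")
  }
  n <- length(v)
  w1 <- rep(1, n)
  W_data <- kmeans1d_dp(sort(v), w1, kmax)$D[, n][k_range]
  with_rng(seed, {
    logWstar <- matrix(NA_real_, n_reference, length(k_range))
    for (b in seq_len(n_reference)) {
      ref <- sort(stats::runif(n, min(v), max(v)))
      logWstar[b, ] <- log(kmeans1d_dp(ref, w1, kmax)$D[, n][k_range])
    }
    data.frame(
      k = k_range,
      wcss = W_data,
      log_wcss = log(W_data),
      gap = colMeans(logWstar) - log(W_data),
      s_k = apply(logWstar, 2, stats::sd) * sqrt(1 + 1 / n_reference)
    )
  })
}

#' Model-selection report over a range of cluster counts
#'
#' Runs [kmeans_1d()] for each `k`, and collects the WCSS (elbow curve), the
#' gap statistic with its standard error, and the silhouette,
#' Calinski-Harabasz and Davies-Bouldin indices (the latter three are only
#' defined for `k >= 2`).
#'
#' @inheritParams kmeans_1d
#' @param k_range integer vector of cluster counts.
#' @param n_reference reference draws for the gap statistic.
#' @return object of class `cluster_selection_report`: list with `summary`
#'   (one row per k), `models` (the fitted `cluster_model`s) and
#'   `silhouette_scores` (per-point scores per k, for plotting).
#' @export
cluster_selection_report <- function(values, k_range = 1:8, n_init = 50L,
                                     n_reference = 100L, seed = NULL) {
  k_range <- sort(unique(as.integer(k_range)))
  gap <- gap_statistic(values, k_range, n_reference = n_reference,
                       seed = if (is.null(seed)) NULL else seed + 1L)
  models <- list()
  sil_mean <- ch <- db <- rep(NA_real_, length(k_range))
  wcss <- numeric(length(k_range))
  sil_scores <- list()
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    m <- kmeans_1d(values, k, n_init = n_init,
                   seed = if (is.null(seed)) NULL else seed + 100L + k)
    models[[as.character(k)]] <- m
    wcss[i] <- m$wcss
    if (k >= 2) {
      s <- silhouette_1d(values, m$cluster)
      sil_mean[i] <- s$mean
      sil_scores[[as.character(k)]] <- s$scores
      if (k < length(values)) ch[i] <- calinski_harabasz(values, m$cluster)
      db[i] <- davies_bouldin(values, m$cluster)
    }
  }
  structure(list(
    summary = data.frame(k = k_range, wcss = wcss, gap = gap$gap,
                         s_k = gap$s_k, silhouette = sil_mean,
                         calinski_harabasz = ch, davies_bouldin = db),
    models = models,
    silhouette_scores = sil_scores
  ), class = "cluster_selection_report")
}

#' @export
print.cluster_selection_report <- function(x, ...) {
  cat("Cluster-count selection report\n")
  print(transform(x$summary,
                  wcss = signif(wcss, 5), gap = signif(gap, 4),
                  s_k = signif(s_k, 3), silhouette = signif(silhouette, 3),
                  calinski_harabasz = signif(calinski_harabasz, 5),
                  davies_bouldin = signif(davies_bouldin, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Choose the number of clusters from a selection report
#'
#' Strategies: `"gap_1se"` is the parsimony rule (smallest `k` with
#' `gap(k) >= gap(k+1) - s_{k+1}`), `"gap_max"` the argmax of the gap curve,
#' and `"manual"` returns the supplied `override` with the full report
#' attached, for the common case where a larger `k` is preferred on clinical
#' interpretability grounds over the statistically parsimonious choice.
#'
#' @param report a [cluster_selection_report()].
#' @param strategy selection rule.
#' @param override cluster count for `strategy = "manual"`.
#' @return list of class `k_selection` with `k`, `strategy`, `gap_1se_k`,
#'   `gap_max_k` and `report`.
#' @export
select_k <- function(report, strategy = c("gap_1se", "gap_max", "manual"),
                     override = NULL) {
  strategy <- match.arg(strategy)
  s <- report$summary
  gap_max_k <- s$k[which.max(s$gap)]
  gap_1se_k <- s$k[length(s$k)]
  for (i in seq_len(nrow(s) - 1)) {
    if (s$gap[i] >= s$gap[i + 1] - s$s_k[i + 1]) { gap_1se_k <- s$k[i]; break }
  }
  k <- switch(strategy,
    gap_1se = gap_1se_k,
    gap_max = gap_max_k,
    manual = {
      if (is.null(override)) {
        abort("strategy 'manual' requires an override", "edrisk_domain_error")
      }
      if (!override %in% s$k) {
        abort("manual override outside the evaluated k range",
              "edrisk_domain_error")
      }
      as.integer(override)
    }
  )
  structure(list(k = as.integer(k), strategy = strategy,
                 gap_1se_k = as.integer(gap_1se_k),
                 gap_max_k = as.integer(gap_max_k), report = report),
            class = "k_selection")
}
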