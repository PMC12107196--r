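#' One-dimensional k-means (Lloyd's algorithm with random restarts)
#'
#' Clusters a vector of admission risks. Initial centroids are drawn without
#' replacement from the distinct values; each point is then assigned to the
#' nearest centroid (ties to the lower-risk centroid), centroids are
#' recomputed as cluster means, and the loop repeats until the largest
#' centroid movement falls below `tol` or `max_iter` is reached. The best of
#' `n_init` restarts by within-cluster sum of squares (WCSS) is returned,
#' with labels renumbered so that label 1 is the lowest-risk centroid.
#'
#' An empty cluster is repaired by reseeding its centroid at the point
#' currently farthest from its own centroid, keeping `k` fixed.
#'
#' @param values numeric vector (optionally named, e.g. by ICD-10 code; names
#'   are carried through to the assignment).
#' @param k number of clusters (`1 <= k <=` number of distinct values).
#' @param n_init number of random restarts.
#' @param max_iter maximum Lloyd iterations per restart.
#' @param tol convergence tolerance on centroid movement.
#' @param seed integer seed for the restarts.
#' @param weights optional positive per-point weights (frequency weighting);
#'   default unweighted.
#' @return object of class `cluster_model`: list with `k`, `centroids`
#'   (strictly increasing), `cluster` (integer labels, named like `values`),
#'   `sizes`, `wcss`, `iterations`, `converged`, `method`.
#' @export
kmeans_1d <- function(values, k, n_init = 50L, max_iter = 300L, tol = 1e-10,
                      seed = NULL, weights = NULL) {
  v <- as.numeric(values)
  n <- length(v)
  w <- check_cluster_args(v, k, weights)
  distinct <- unique(v)
  with_rng(seed, {
    best <- NULL
    for (run in seq_len(n_init)) {
      cen <- distinct[sample.int(length(distinct), k)]
      iter <- 0L
      converged <- FALSE
      repeat {
        iter <- iter + 1L
        ord <- order(cen)
        cen <- cen[ord]
        lab <- assign_nearest(v, cen)
        # empty-cluster repair: reseed at the point farthest from its centroid
        empty <- setdiff(seq_len(k), unique(lab))
        for (e in empty) {
          far <- which.max(abs(v - cen[lab]))
          cen[e] <- v[far]
          lab <- assign_nearest(v, cen)
        }
        new_cen <- vapply(seq_len(k), function(j) {
          sel <- lab == j
          sum(w[sel] * v[sel]) / sum(w[sel])
        }, numeric(1))
        moved <- max(abs(new_cen - cen))
        cen <- new_cen
        if (moved < tol) { converged <- TRUE; break }
        if (iter >= max_iter) break
      }
      ord <- order(cen)
      cen <- cen[ord]
      lab <- assign_nearest(v, cen)
      wcss <- sum(w * (v - cen[lab])^2)
      if (is.null(best) || wcss < best$wcss) {
        best <- list(centroids = cen, cluster = lab, wcss = wcss,
                     iterations = iter, converged = converged)
      }
    }
    new_cluster_model(best$centroids, best$cluster, best$wcss, k,
                      names(values), w, iterations = best$iterations,
                      converged = best$converged, method = "lloyd")
  })
}

# nearest-centroid assignment with ties to the lower-risk (smaller) centroid;
# centroids must be sorted ascending
assign_nearest <- function(v, cen) {
  d <- abs(outer(v, cen, "-"))
  max.col(-d, ties.method = "first")
}

check_cluster_args <- function(v, k, weights) {
  if (k < 1) abort("k must be >= 1", "edrisk_domain_error")
  if (length(v) < k) abort("need at least k values", "edrisk_domain_error")
  if (length(unique(v)) < k) {
    abort("k exceeds the number of distinct values", "edrisk_domain_error")
  }
  if (is.null(weights)) weights <- rep(1, length(v))
  if (length(weights) != length(v) || any(weights <= 0)) {
    abort("weights must be positive and match values in length",
          "edrisk_domain_error")
  }
  weights
}

new_cluster_model <- function(centroids, cluster, wcss, k, nms, w,
                              iterations, converged, method) {
  if (!is.null(nms)) names(cluster) <- nms
  structure(list(
    k = as.integer(k),
    centroids = centroids,
    cluster = cluster,
    sizes = tabulate(cluster, nbins = k),
    wcss = wcss,
    iterations = iterations,
    converged = converged,
    method = method
  ), class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("1-D k-means (%s): k = %d, wcss = %.6g\n", x$method, x$k, x$wcss))
  cat("centroids:", paste(signif(x$centroids, 4), collapse = ", "), "\n")
  cat("sizes:    ", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

# Dynamic program over sorted values. Optimal 1-D clusters are contiguous in
# sorted order, so D[m, j] = min_i { D[m-1, i-1] + sse(i..j) } solves the
# problem exactly; sse(i..j) comes from prefix sums. Returns WCSS for every
# k up to kmax plus the backtrack table.
kmeans1d_dp <- function(vs, ws, kmax) {
  n <- length(vs)
  cw <- c(0, cumsum(ws))
  cwv <- c(0, cumsum(ws * vs))
  cwv2 <- c(0, cumsum(ws * vs^2))
  sse <- function(i, j) { # vectorised over i
    W <- cw[j + 1] - cw[i]
    S <- cwv[j + 1] - cwv[i]
    pmax(cwv2[j + 1] - cwv2[i] - S^2 / W, 0)
  }
  D <- matrix(Inf, kmax, n)
  B <- matrix(1L, kmax, n) # B[m, j]: start index of the m-th (last) segment
  D[1, ] <- sse(1, seq_len(n))
  if (kmax > 1) {
    for (m in 2:kmax) {
      for (j in m:n) {
        i <- m:j
        cand <- D[m - 1, i - 1] + sse(i, j)
        pick <- which.min(cand) # ties -> smallest start index
        D[m, j] <- cand[pick]
        B[m, j] <- i[pick]
      }
    }
  }
  list(D = D, B = B)
}

#' Exact one-dimensional k-means by dynamic programming
#'
#' Computes the globally WCSS-optimal partition of `values` into `k`
#' clusters. In one dimension the optimal clusters are contiguous intervals
#' of the sorted values, so dynamic programming over segment boundaries finds
#' the exact optimum; this serves as the verification oracle for
#' [kmeans_1d()]. Deterministic.
#'
#' @inheritParams kmeans_1d
#' @return a `cluster_model` (method `"dp"`, `converged = TRUE`).
#' @export
kmeans_1d_exact <- function(values, k, weights = NULL) {
  v <- as.numeric(values)
  n <- length(v)
  w <- check_cluster_args(v, k, weights)
  ord <- order(v)
  dp <- kmeans1d_dp(v[ord], w[ord], k)
  # backtrack segment starts
  lab_sorted <- integer(n)
  j <- n
  for (m in k:1) {
    i <- dp$B[m, j]
    lab_sorted[i:j] <- m
    j <- i - 1L
  }
  lab <- integer(n)
  lab[ord] <- lab_sorted
  cen <- vapply(seq_len(k), function(m) {
    sel <- lab == m
    sum(w[sel] * v[sel]) / sum(w[sel])
  }, numeric(1))
  new_cluster_model(cen, lab, dp$D[k, n], k, names(values), w,
                    iterations = NA_integer_, converged = TRUE, method = "dp")
}
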