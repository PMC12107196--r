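#' Default design specification for the cluster-membership model
#'
#' The covariate set used to model risk-cluster membership: age in years,
#' sex (reference female), ethnicity (reference Chinese), categorized vitals
#' (reference normal), categorized CCI (reference none) and the seven prior
#' six-month utilisation counts entered untransformed per unit.
#'
#' @return list of covariate specifications (name, type, reference) in a
#'   fixed, documented order.
#' @export
default_design_spec <- function() {
  list(
    list(name = "age", type = "continuous"),
    list(name = "sex", type = "categorical", reference = "female"),
    list(name = "ethnicity", type = "categorical", reference = "Chinese"),
    list(name = "sbp_cat", type = "categorical", reference = "normal"),
    list(name = "pulse_cat", type = "categorical", reference = "normal"),
    list(name = "temp_cat", type = "categorical", reference = "normal"),
    list(name = "cci_cat", type = "categorical", reference = "none"),
    list(name = "prior_ed", type = "continuous"),
    list(name = "prior_inpt", type = "continuous"),
    list(name = "prior_surg", type = "continuous"),
    list(name = "prior_icu", type = "continuous"),
    list(name = "prior_hd", type = "continuous"),
    list(name = "prior_ica", type = "continuous"),
    list(name = "prior_infect", type = "continuous")
  )
}

#' Build the design matrix and ordinal outcome
#'
#' Expands categorical covariates to indicator columns against their
#' configured reference level (error if the reference is absent from the
#' data), passes continuous covariates through untransformed, and drops
#' constant columns is an error. Column order follows the specification
#' deterministically.
#'
#' @param records registry data frame with a `cluster` column.
#' @param spec a design specification as from [default_design_spec()].
#' @param outcome name of the ordinal outcome column (default `"cluster"`).
#' @return list with `X` (numeric matrix), `y` (integer vector, levels
#'   `1..k`) and `columns` (the column names).
#' @export
build_design <- function(records, spec = default_design_spec(),
                         outcome = "cluster") {
  stopifnot(outcome %in% names(records))
  y <- as.integer(records[[outcome]])
  cols <- list()
  for (cv in spec) {
    x <- records[[cv$name]]
    if (is.null(x)) {
      abort(paste0("covariate '", cv$name, "' not found"), "edrisk_domain_error")
    }
    if (cv$type == "continuous") {
      cols[[cv$name]] <- as.numeric(x)
    } else {
      x <- as.character(x)
      levs <- sort(unique(x))
      if (!cv$reference %in% levs) {
        abort(paste0("reference level '", cv$reference, "' absent from '",
                     cv$name, "'"), "edrisk_domain_error")
      }
      for (lv in setdiff(levs, cv$reference)) {
        cols[[paste0(cv$name, "_", lv)]] <- as.numeric(x == lv)
      }
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  constant <- vapply(seq_len(ncol(X)), function(j) length(unique(X[, j])) == 1,
                     logical(1))
  if (any(constant)) {
    abort(paste0("constant design column(s): ",
                 paste(colnames(X)[constant], collapse = ", ")),
          "edrisk_domain_error")
  }
  list(X = X, y = y, columns = colnames(X))
}

# log-likelihood, score and Hessian of the cumulative-logit model
# logit P(Y <= j | x) = theta_j - x'beta, phi = (theta, beta)
po_loglik_parts <- function(phi, X, y, K, hessian = TRUE) {
  q <- K - 1L
  p <- ncol(X)
  theta <- phi[seq_len(q)]
  beta <- if (p) phi[q + seq_len(p)] else numeric(0)
  eta <- if (p) as.vector(X %*% beta) else numeric(length(y))

  th_hi <- c(theta, Inf)[y]   # theta_{y}   (Inf for y = K)
  th_lo <- c(-Inf, theta)[y]  # theta_{y-1} (-Inf for y = 1)
  g_hi <- stats::plogis(th_hi - eta)
  g_lo <- stats::plogis(th_lo - eta)
  pi <- pmax(g_hi - g_lo, 1e-300)
  ll <- sum(log(pi))

  d_hi <- g_hi * (1 - g_hi)  # logistic densities at the two cut-points
  d_lo <- g_lo * (1 - g_lo)
  r_hi <- d_hi / pi
  r_lo <- d_lo / pi

  # score: theta_j collects +r_hi from obs with y = j, -r_lo from y - 1 = j
  sc_theta <- vapply(seq_len(q), function(j) {
    sum(r_hi[y == j]) - sum(r_lo[y == j + 1L])
  }, numeric(1))
  sc_beta <- if (p) as.vector(crossprod(X, -(r_hi - r_lo))) else numeric(0)
  score <- c(sc_theta, sc_beta)
  if (!hessian) return(list(ll = ll, score = score))

  h_hi <- d_hi * (1 - 2 * g_hi) # derivative of the density
  h_lo <- d_lo * (1 - 2 * g_lo)
  H <- matrix(0, q + p, q + p)
  for (j in seq_len(q)) {
    up <- y == j       # theta_j is the upper cut for these obs
    dn <- y == j + 1L  # and the lower cut for these
    H[j, j] <- sum(h_hi[up] / pi[up] - r_hi[up]^2) +
      sum(-h_lo[dn] / pi[dn] - r_lo[dn]^2)
    if (j < q) { # adjacent cuts share only obs with y = j + 1
      cr <- sum(r_hi[dn] * r_lo[dn])
      H[j, j + 1L] <- H[j + 1L, j] <- cr
    }
    if (p) {
      wj <- numeric(length(y))
      wj[up] <- -h_hi[up] / pi[up] + r_hi[up] * (r_hi[up] - r_lo[up])
      wj[dn] <- h_lo[dn] / pi[dn] - r_lo[dn] * (r_hi[dn] - r_lo[dn])
      Hjb <- as.vector(crossprod(X, wj))
      H[j, q + seq_len(p)] <- Hjb
      H[q + seq_len(p), j] <- Hjb
    }
  }
  if (p) {
    wb <- (h_hi - h_lo) / pi - (r_hi - r_lo)^2
    H[q + seq_len(p), q + seq_len(p)] <- crossprod(X, X * wb)
  }
  list(ll = ll, score = score, hessian = H)
}

#' Fit the proportional-odds (cumulative-logit) model
#'
#' Maximum-likelihood fit of `logit P(Y <= j | x) = theta_j - beta' x` by
#' Newton-Raphson with step-halving, so a positive coefficient means higher
#' odds of membership in a higher-risk cluster. Wald 95% confidence intervals
#' are `exp(beta +/- 1.96 se)`.
#'
#' @param X numeric design matrix (no intercept; see [build_design()]). A
#'   zero-column matrix fits the intercept-only model.
#' @param y integer ordinal outcome with levels `1..k`, `k >= 2`.
#' @param tol convergence tolerance on the score sup-norm.
#' @param max_iter maximum Newton iterations.
#' @return object of class `ordinal_fit`: `thresholds` (strictly increasing),
#'   `coefficients`, `se`, `odds_ratios`, `ci95` (matrix, OR scale),
#'   `log_likelihood`, `loglik_trace`, `gradient_norm`, `converged`,
#'   `iterations`, `n_used`, `vcov`, `columns`.
#' @export
fit_proportional_odds <- function(X, y, tol = 1e-8, max_iter = 100L) {
  if (is.null(dim(X))) X <- matrix(X, ncol = length(X) > 0)
  y <- as.integer(y)
  K <- max(y)
  if (length(unique(y)) < 2) {
    abort("outcome needs at least 2 observed levels", "edrisk_domain_error")
  }
  if (!identical(sort(unique(y)), seq_len(K))) {
    abort("outcome levels must be 1..k with every level observed",
          "edrisk_domain_error")
  }
  n <- length(y)
  q <- K - 1L
  p <- ncol(X)
  # start at the intercept-only solution: empirical cumulative logits
  cum <- cumsum(tabulate(y, K))[seq_len(q)] / n
  phi <- c(stats::qlogis(cum), rep(0, p))

  cur <- po_loglik_parts(phi, X, y, K)
  trace <- cur$ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(cur$score)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(-cur$hessian, cur$score), error = function(e) NULL)
    if (is.null(step)) {
      abort("Hessian is singular; check the design for collinearity",
            "edrisk_domain_error")
    }
    lambda <- 1
    repeat {
      cand <- phi + lambda * step
      ok_theta <- q < 2 || all(diff(cand[seq_len(q)]) > 0)
      if (ok_theta) {
        nxt <- po_loglik_parts(cand, X, y, K)
        if (is.finite(nxt$ll) && nxt$ll >= cur$ll) break
      }
      lambda <- lambda / 2
      if (lambda < 1e-12) { nxt <- NULL; break }
    }
    if (is.null(nxt)) break # no ascent direction left; report unconverged
    phi <- cand
    cur <- nxt
    trace <- c(trace, cur$ll)
    if (p && max(abs(phi[q + seq_len(p)])) > 30) {
      abort("coefficients diverging; data appear separated",
            "edrisk_separation_error")
    }
    if (max(abs(cur$score)) < tol) { converged <- TRUE; break }
  }
  vcov <- tryCatch(solve(-cur$hessian), error = function(e) {
    matrix(NA_real_, q + p, q + p)
  })
  se <- sqrt(pmax(diag(vcov), 0))
  cn <- colnames(X) %||% if (p) paste0("x", seq_len(p)) else character(0)
  names(phi) <- c(paste0("theta_", seq_len(q)), cn)
  beta <- phi[q + seq_len(p)]
  se_beta <- se[q + seq_len(p)]
  ci <- cbind(lower = exp(beta - 1.96 * se_beta),
              upper = exp(beta + 1.96 * se_beta))
  rownames(ci) <- cn
  structure(list(
    thresholds = phi[seq_len(q)],
    coefficients = beta,
    se = stats::setNames(se_beta, cn),
    odds_ratios = exp(beta),
    ci95 = ci,
    log_likelihood = cur$ll,
    loglik_trace = trace,
    gradient_norm = max(abs(cur$score)),
    converged = converged,
    iterations = iter,
    n_used = n,
    vcov = vcov,
    columns = cn
  ), class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf(
    "Proportional-odds fit: n = %d, k = %d, logLik = %.2f, %s (%d iterations)\n",
    x$n_used, length(x$thresholds) + 1L, x$log_likelihood,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  if (length(x$coefficients)) {
    print(data.frame(OR = round_half_up(x$odds_ratios, 2),
                     ci_low = round_half_up(x$ci95[, "lower"], 2),
                     ci_high = round_half_up(x$ci95[, "upper"], 2)))
  }
  invisible(x)
}

#' Forest-plot table of odds ratios
#'
#' One row per coefficient, in design-column order, with the odds ratio and
#' 95% CI rounded to two decimals (half-up) for reporting.
#'
#' @param fit a converged [fit_proportional_odds()] result.
#' @return data frame with columns `covariate`, `or`, `ci_low`, `ci_high`.
#' @export
forest_table <- function(fit) {
  stopifnot(inherits(fit, "ordinal_fit"))
  if (!fit$converged) {
    abort("refusing to tabulate an unconverged fit", "edrisk_domain_error")
  }
  data.frame(
    covariate = fit$columns,
    or = round_half_up(fit$odds_ratios, 2),
    ci_low = round_half_up(fit$ci95[, "lower"], 2),
    ci_high = round_half_up(fit$ci95[, "upper"], 2),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Simulate ordinal outcomes from the proportional-odds model
#'
#' Draws `Y` with `P(Y <= j | x) = plogis(theta_j - x'beta)`; the ground
#' truth for parameter-recovery and confidence-interval coverage studies.
#'
#' @param X numeric design matrix.
#' @param theta strictly increasing cut-points (length `k - 1`).
#' @param beta coefficient vector (length `ncol(X)`).
#' @param seed integer seed.
#' @return integer vector of outcomes in `1..k`.
#' @export
simulate_ordinal <- function(X, theta, beta, seed = NULL) {
  if (is.null(dim(X))) X <- matrix(X, ncol = length(beta))
  stopifnot(ncol(X) == length(beta), !is.unsorted(theta, strictly = TRUE))
  eta <- as.vector(X %*% beta)
  with_rng(seed, {
    u <- stats::runif(nrow(X))
    cum <- vapply(theta, function(t) stats::plogis(t - eta),
                  numeric(nrow(X)))
    1L + rowSums(u > cum)
  })
}
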