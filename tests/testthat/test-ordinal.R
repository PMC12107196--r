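test_that("design expansion uses configured references in a fixed order", {
  rec <- toy_records(rep("A09", 8),
                     sex = rep(c("female", "male"), 4),
                     cci = c(0L, 0L, 1L, 2L, 3L, 4L, 5L, 7L))
  rec$age <- c(30L, 40L, 50L, 60L, 35L, 45L, 55L, 65L)
  rec$pulse <- c(55L, 75L, 95L, 75L, 75L, 95L, 55L, 75L)
  rec$sbp <- c(85L, 120L, 135L, 120L, 120L, 135L, 120L, 85L)
  rec$temp <- c(35.0, 36.8, 37.8, 36.8, 36.8, 37.8, 36.8, 35.0)
  rec <- categorize_records(rec)
  rec$cluster <- rep(1:2, 4)
  spec <- list(
    list(name = "age", type = "continuous"),
    list(name = "sex", type = "categorical", reference = "female"),
    list(name = "cci_cat", type = "categorical", reference = "none")
  )
  d <- build_design(rec, spec)
  expect_equal(d$columns, c("age", "sex_male", "cci_cat_mild",
                            "cci_cat_moderate", "cci_cat_severe"))
  expect_equal(unname(d$X[, "sex_male"]), rep(c(0, 1), 4))

  bad <- spec
  bad[[2]]$reference <- "unknown"
  expect_error(build_design(rec, bad), "unknown", class = "edrisk_domain_error")
})

test_that("the intercept-only fit recovers empirical cumulative logits", {
  y <- rep(1:3, times = c(50, 30, 20))
  f <- fit_proportional_odds(matrix(numeric(0), length(y), 0), y)
  expect_equal(unname(f$thresholds), c(0, log(0.8 / 0.2)), tolerance = 1e-8)
  expect_true(f$converged)
})

test_that("the fit matches MASS::polr on a nontrivial design", {
  skip_if_not_installed("MASS")
  withr::with_seed(2, {
    n <- 4000
    X <- cbind(a = rbinom(n, 1, 0.3), b = rnorm(n), c = rpois(n, 0.5))
  })
  y <- simulate_ordinal(X, theta = c(-0.5, 1, 2.5),
                        beta = c(0.4, -0.3, 0.2), seed = 4)
  f <- fit_proportional_odds(X, y)
  pf <- MASS::polr(factor(y) ~ a + b + c, data = data.frame(X, y = y),
                   Hess = TRUE)
  expect_equal(unname(f$coefficients), unname(coef(pf)), tolerance = 1e-4)
  expect_equal(unname(f$thresholds), unname(pf$zeta), tolerance = 1e-4)
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(pf))[1:3])),
               tolerance = 1e-4)
  expect_equal(f$log_likelihood, as.numeric(logLik(pf)), tolerance = 1e-8)
})

test_that("likelihood ascends monotonically and the gradient ends tiny", {
  withr::with_seed(6, X <- cbind(x = rnorm(2000)))
  y <- simulate_ordinal(X, theta = c(-1, 0.5, 2), beta = 0.8, seed = 7)
  f <- fit_proportional_odds(X, y, tol = 1e-8)
  expect_true(all(diff(f$loglik_trace) >= 0))
  expect_lt(f$gradient_norm, 1e-8)
  expect_true(f$converged)
})

test_that("fitted cumulative probabilities are monotone for every observation", {
  withr::with_seed(9, X <- cbind(x = rnorm(500), z = rbinom(500, 1, 0.4)))
  y <- simulate_ordinal(X, theta = c(-1, 0, 1.5), beta = c(0.5, -0.7), seed = 1)
  f <- fit_proportional_odds(X, y)
  expect_true(all(diff(f$thresholds) > 0))
  eta <- as.vector(X %*% f$coefficients)
  cum <- vapply(f$thresholds, function(t) plogis(t - eta), numeric(nrow(X)))
  expect_true(all(t(apply(cum, 1, diff)) >= 0))
})

test_that("reversing the outcome ordering negates the coefficients", {
  withr::with_seed(12, X <- cbind(x = rnorm(3000)))
  y <- simulate_ordinal(X, theta = c(-0.8, 0.9), beta = 0.6, seed = 2)
  f1 <- fit_proportional_odds(X, y)
  f2 <- fit_proportional_odds(X, 4L - y) # 3 levels reversed
  expect_equal(unname(f1$coefficients), -unname(f2$coefficients),
               tolerance = 1e-6)
})

test_that("null data yield coefficients within three standard errors of zero", {
  withr::with_seed(14, {
    X <- cbind(a = rnorm(50000), b = rbinom(50000, 1, 0.25))
    y <- sample(1:4, 50000, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  })
  f <- fit_proportional_odds(X, y)
  expect_true(all(abs(f$coefficients) < 3 * f$se))
})

test_that("separated data raise a separation error", {
  X <- cbind(x = c(rep(0, 40), rep(1, 40)))
  y <- c(rep(1L, 40), rep(2L, 40)) # x predicts y perfectly
  expect_error(fit_proportional_odds(X, y), class = "edrisk_separation_error")
})

test_that("degenerate outcomes are rejected", {
  expect_error(fit_proportional_odds(matrix(rnorm(10)), rep(1L, 10)),
               class = "edrisk_domain_error")
  expect_error(fit_proportional_odds(matrix(rnorm(10)), c(1L, 3L, rep(1L, 8))),
               class = "edrisk_domain_error")
})

test_that("the forest table applies the exp transform and 2-decimal rounding", {
  f <- structure(list(
    columns = "tachycardia",
    coefficients = c(tachycardia = 0.3784),
    se = c(tachycardia = 0.0105),
    odds_ratios = exp(c(tachycardia = 0.3784)),
    ci95 = matrix(exp(c(0.3784 - 1.96 * 0.0105, 0.3784 + 1.96 * 0.0105)),
                  1, 2, dimnames = list("tachycardia", c("lower", "upper"))),
    converged = TRUE
  ), class = "ordinal_fit")
  tab <- forest_table(f)
  expect_equal(tab$or, 1.46)
  expect_equal(tab$ci_low, 1.43)
  expect_equal(tab$ci_high, 1.49)

  f$converged <- FALSE
  expect_error(forest_table(f), class = "edrisk_domain_error")
})

test_that("a null coefficient reports OR 1 with a log-symmetric CI", {
  withr::with_seed(21, {
    X <- cbind(x = rnorm(20000))
    y <- sample(1:3, 20000, replace = TRUE)
  })
  f <- fit_proportional_odds(X, y)
  tab <- forest_table(f)
  expect_lt(abs(log(f$odds_ratios[[1]])), 3 * f$se[[1]])
  expect_equal(log(f$ci95[1, "upper"] * f$ci95[1, "lower"]),
               2 * f$coefficients[[1]], tolerance = 1e-10)
  expect_equal(tab, tab[order(match(tab$covariate, f$columns)), ])
})
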