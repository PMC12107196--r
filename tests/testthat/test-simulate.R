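test_that("degenerate spread collapses code risks onto tier centers", {
  cfg <- sim_config(n_presentations = 10L, n_codes = 4L, n_tiers = 2L,
                    tier_risk_centers = c(0.05, 0.80),
                    tier_proportions = c(0.5, 0.5),
                    tier_mass_targets = c(0.5, 0.5),
                    tier_risk_spread = Inf, seed = 3L)
  u <- generate_code_universe(cfg)
  expect_equal(nrow(u), 4L)
  expect_equal(sort(as.integer(table(u$tier))), c(2L, 2L))
  expect_setequal(u$true_risk, c(0.05, 0.80))
  expect_equal(sum(u$true_risk == 0.05), 2L)
})

test_that("the generator is deterministic given the seed", {
  cfg <- small_sim(n = 2000L, seed = 17L)
  u1 <- generate_code_universe(cfg)
  u2 <- generate_code_universe(cfg)
  expect_identical(u1, u2)
  r1 <- generate_presentations(u1, cfg)
  r2 <- generate_presentations(u2, cfg)
  expect_identical(r1, r2)
})

test_that("per-tier mean risks track the Beta centers at moderate spread", {
  centers <- c(0.047, 0.195, 0.478, 0.78)
  cfg <- sim_config(n_presentations = 10L, n_codes = 510L,
                    tier_risk_centers = centers, tier_risk_spread = 200,
                    seed = 5L)
  u <- generate_code_universe(cfg)
  tier_means <- tapply(u$true_risk, u$tier, mean)
  expect_true(all(abs(tier_means - centers) < 0.03))
})

test_that("non-increasing tier centers are rejected", {
  expect_error(sim_config(tier_risk_centers = c(0.5, 0.3, 0.7, 0.8)),
               class = "edrisk_config_error")
  expect_error(sim_config(zipf_exponent = 0), class = "edrisk_config_error")
})

test_that("admission fraction converges to the code risk when effects are off", {
  u <- code_universe("A09", true_risk = 0.5)
  cfg <- sim_config(n_presentations = 100000L, covariate_effects = numeric(0),
                    seed = 2L)
  rec <- generate_presentations(u, cfg)
  expect_equal(mean(rec$admitted), 0.5, tolerance = 0.01)
})

test_that("a configured tachycardia effect is recovered by a logistic refit", {
  u <- code_universe("R07", true_risk = 0.25)
  cfg <- sim_config(n_presentations = 200000L,
                    covariate_effects = c(tachycardia = log(1.46)), seed = 9L)
  rec <- generate_presentations(u, cfg)
  fit <- glm(admitted ~ I(pulse > 90), data = rec, family = binomial())
  expect_gt(exp(coef(fit)[2]), 1.35)
  expect_lt(exp(coef(fit)[2]), 1.58)
})

test_that("zero presentations give an empty registry without error", {
  u <- code_universe(c("A09", "J10"), c(0.1, 0.9))
  rec <- generate_presentations(u, small_sim(n = 0L))
  expect_equal(nrow(rec), 0L)
  expect_true(all(c("id", "icd10", "admitted", "temp") %in% names(rec)))
})

test_that("registry files round-trip field-for-field", {
  cfg <- small_sim(n = 1000L, seed = 4L)
  rec <- generate_presentations(generate_code_universe(cfg), cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(rec, path)
  back <- read_registry(path)
  expect_equal(back, rec)
})

test_that("malformed registry rows fail naming row and column", {
  path <- write_toy_file(c(
    "P1,A09,maybe,40,female,Chinese,120,75,36.8,0,0,0,0,0,0,0,0"))
  expect_error(read_registry(path), "admitted.*row 1",
               class = "edrisk_parse_error")
  path2 <- write_toy_file(c(
    "P1,A09,1,40,female,Chinese,abc,75,36.8,0,0,0,0,0,0,0,0"))
  expect_error(read_registry(path2), "sbp.*row 1",
               class = "edrisk_parse_error")
  path3 <- write_toy_file(c(
    "P1,a9x,1,40,female,Chinese,120,75,36.8,0,0,0,0,0,0,0,0"))
  expect_error(read_registry(path3), "icd10", class = "edrisk_parse_error")
})

test_that("a header-only registry reads as an empty collection", {
  expect_equal(nrow(read_registry(write_toy_file(character(0)))), 0L)
})

test_that("marginal admission rate matches the frequency-weighted code risks", {
  cfg <- sim_config(n_presentations = 50000L, covariate_effects = numeric(0),
                    seed = 21L)
  u <- generate_code_universe(cfg)
  rec <- generate_presentations(u, cfg)
  expected <- sum(u$frequency_weight * u$true_risk)
  se <- sqrt(expected * (1 - expected) / nrow(rec))
  expect_lt(abs(mean(rec$admitted) - expected), 3 * se)
})

test_that("empirical code frequencies follow the configured Zipf law", {
  for (alloc in c("tier_mass", "random")) {
    cfg <- sim_config(n_presentations = 400000L, n_codes = 300L,
                      zipf_exponent = 1, frequency_allocation = alloc,
                      seed = 31L)
    u <- generate_code_universe(cfg)
    rec <- generate_presentations(u, cfg)
    counts <- sort(as.integer(table(rec$icd10)), decreasing = TRUE)
    slope <- coef(lm(log(counts) ~ log(seq_along(counts))))[2]
    expect_lt(abs(slope - (-1)), 0.1)
  }
})

test_that("tier-mass rank allocation steers presentation mass to targets", {
  cfg <- sim_config(seed = 13L)
  u <- generate_code_universe(cfg)
  mass <- tapply(u$frequency_weight, u$tier, sum)
  # lumpy top Zipf ranks limit precision; targets still dominate ordering
  expect_true(all(abs(mass - cfg$tier_mass_targets) < 0.08))
  expect_equal(order(mass, decreasing = TRUE), 1:4)
})
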