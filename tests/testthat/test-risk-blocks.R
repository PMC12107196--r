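test_that("code risks are exact fractions of admissions over presentations", {
  rec <- toy_records(rep("A09", 4), admitted = c(1L, 0L, 0L, 0L))
  prof <- compute_code_risks(rec)
  expect_equal(prof$risk, 0.25)
  expect_equal(prof$n, 4L)

  rec2 <- rbind(toy_records(rep("A09", 3), admitted = 1L, ),
                toy_records(rep("J10", 3), admitted = 0L))
  prof2 <- compute_code_risks(rec2)
  expect_equal(sort(prof2$risk), c(0, 1))
  expect_equal(sum(prof2$n), nrow(rec2))
  expect_equal(nrow(compute_code_risks(rec2[0, ])), 0L)
})

test_that("empirical code risks land near degenerate tier centers", {
  cfg <- sim_config(n_presentations = 40000L, n_codes = 10L, n_tiers = 2L,
                    tier_risk_centers = c(0.05, 0.80),
                    tier_proportions = c(0.5, 0.5),
                    tier_mass_targets = c(0.5, 0.5),
                    tier_risk_spread = Inf, covariate_effects = numeric(0),
                    zipf_exponent = 0.1, # near-uniform so every code is deep
                    seed = 19L)
  u <- generate_code_universe(cfg)
  rec <- generate_presentations(u, cfg)
  prof <- compute_code_risks(rec)
  expect_true(all(prof$n >= 2000))
  truth <- u$true_risk[match(prof$code, u$code)]
  expect_true(all(abs(prof$risk - truth) < 0.03))
})

test_that("block risks pool member codes and conserve counts", {
  blocks <- toy_block_table()
  rec <- rbind(toy_records(rep("J10", 20), admitted = rep(c(1L, 0L), 10)),
               toy_records(rep("J12", 20), admitted = 0L))
  prof <- compute_block_risks(rec, blocks)
  expect_equal(prof$risk[prof$code == "J09-J18"], 0.25)

  one <- compute_block_risks(toy_records(rep("A09", 4), admitted = 1L), blocks)
  expect_equal(one$risk, compute_code_risks(toy_records(rep("A09", 4),
                                                        admitted = 1L))$risk)
  expect_error(compute_block_risks(toy_records("Z99"), blocks),
               "Z99", class = "edrisk_domain_error")
})

test_that("block risk totals conserve the registry on a full synthetic run", {
  cfg <- small_sim(n = 5000L, seed = 23L)
  rec <- generate_presentations(generate_code_universe(cfg), cfg)
  expect_equal(sum(compute_block_risks(rec)$n), sum(compute_code_risks(rec)$n))
})

test_that("presentations inherit their code's cluster and sizes add up", {
  rec <- rbind(toy_records(rep("A09", 6)), toy_records(rep("J10", 4)))
  risks <- compute_code_risks(rec)
  m <- kmeans_1d(setNames(c(0.05, 0.9), c("A09", "J10")), 2, seed = 1)
  out <- propagate_clusters(rec, m)
  expect_equal(unique(out$cluster[out$icd10 == "A09"]), 1L)
  expect_equal(as.integer(table(out$cluster)), c(6L, 4L))
  m_partial <- kmeans_1d(setNames(0.05, "A09"), 1, seed = 1)
  expect_error(propagate_clusters(rec, m_partial), "J10",
               class = "edrisk_domain_error")
})

test_that("size-weighted cluster admission rates reproduce the overall rate", {
  cfg <- sim_config(n_presentations = 30000L, tier_risk_spread = 500, seed = 6L)
  u <- generate_code_universe(cfg)
  rec <- preprocess_registry(generate_presentations(u, cfg))$records
  risks <- compute_code_risks(rec)
  m <- kmeans_1d(setNames(risks$risk, risks$code), 4, seed = 2)
  out <- propagate_clusters(rec, m)
  rates <- tapply(out$admitted, out$cluster, mean)
  sizes <- as.integer(table(out$cluster))
  expect_equal(sum(rates * sizes) / sum(sizes), mean(out$admitted),
               tolerance = 1e-3)
})

test_that("the block table parser validates ranges and rejects overlaps", {
  tab <- toy_block_table("J09-J18,Influenza and pneumonia,X")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$start, "J09")
  expect_error(toy_block_table(c("A00-A09,a,I", "A05-A10,b,I")),
               "overlap", class = "edrisk_parse_error")
  expect_error(toy_block_table("A9-B2,bad,I"), class = "edrisk_parse_error")
  expect_equal(nrow(toy_block_table(character(0))), 0L)
})

test_that("codes map to blocks by 3-character prefix, unmapped as NA", {
  blocks <- toy_block_table()
  expect_equal(code_to_block("J10", blocks), "J09-J18")
  expect_equal(code_to_block("A09", blocks), "A00-A09")
  expect_equal(code_to_block("a091", blocks), "A00-A09") # case/extension
  expect_true(is.na(code_to_block("U07", blocks)))
  expect_true(is.na(code_to_block("J20", blocks)))
})

test_that("the packaged WHO table is valid and covers cross-letter ranges", {
  b <- icd10_blocks()
  expect_s3_class(b, "block_table")
  expect_gt(nrow(b), 250)
  expect_equal(code_to_block("X95", b), "X85-Y09")
  expect_equal(code_to_block("Y05", b), "X85-Y09")
  expect_equal(code_to_block("J09", b), "J09-J18")
})

test_that("block summaries count, normalise and pick dominant clusters", {
  rec <- rbind(toy_records(rep("A09", 80)), toy_records(rep("A00", 20)),
               toy_records(rep("J10", 10)))
  rec$cluster <- c(rep(1L, 80), rep(2L, 20), rep(2L, 10))
  bs <- summarize_blocks(rec, toy_block_table())
  expect_equal(sum(bs$summary$n_presentations), nrow(rec))
  a <- bs$summary[bs$summary$block_id == "A00-A09", ]
  expect_equal(a$dominant_cluster, 1L)
  expect_equal(a$dominant_proportion, 0.8)
  j <- bs$summary[bs$summary$block_id == "J09-J18", ]
  expect_equal(j$dominant_proportion, 1.0)
  expect_equal(unname(rowSums(bs$proportions)), rep(1, 2))

  rec$icd10[1] <- "Z99"
  expect_error(summarize_blocks(rec, toy_block_table()), "Z99",
               class = "edrisk_domain_error")
  collected <- summarize_blocks(rec, toy_block_table(), unmapped = "collect")
  expect_true("UNMAPPED" %in% collected$summary$block_id)
})

test_that("code-level basis counts distinct codes rather than visits", {
  rec <- rbind(toy_records(rep("A09", 80)), toy_records(rep("A00", 20)),
               toy_records(rep("J10", 10)))
  rec$cluster <- c(rep(1L, 80), rep(2L, 20), rep(2L, 10))
  bs <- summarize_blocks(rec, toy_block_table(), basis = "codes")
  a <- bs$summary[bs$summary$block_id == "A00-A09", ]
  expect_equal(a$n_presentations, 2L) # two distinct codes
  expect_equal(a$dominant_proportion, 0.5)
  expect_equal(a$dominant_cluster, 1L) # tie broken toward the lower label
})

test_that("cumulative coverage counts blocks at each threshold", {
  bs <- manual_block_summary(list(A = c(50, 0), B = c(30, 0),
                                  C = c(0, 15), D = c(5, 0)))
  cov <- cumulative_coverage(bs, c(0.8, 0.9, 1.0))
  expect_equal(unname(cov$blocks_at_threshold), c(2L, 3L, 4L))
  expect_equal(cov$ranked$block_id[1:2], c("A", "B"))
  expect_equal(cov$ranked$cumulative_share[4], 1.0)
  expect_error(cumulative_coverage(bs, 1.2), class = "edrisk_domain_error")
  expect_error(cumulative_coverage(bs, 0), class = "edrisk_domain_error")
})

test_that("coverage ranking breaks ties alphabetically", {
  bs <- manual_block_summary(list(B = c(10, 0), A = c(10, 0), C = c(5, 0)))
  cov <- cumulative_coverage(bs, 1)
  expect_equal(cov$ranked$block_id, c("A", "B", "C"))
})

test_that("dominant blocks honour the representation threshold inclusively", {
  bs <- manual_block_summary(list(X = c(80, 20), Y = c(60, 40), Z = c(75, 25)))
  dom <- dominant_blocks(bs, 0.75, cluster = 1)
  expect_setequal(dom$blocks$block_id, c("X", "Z"))
  expect_equal(dom$n_presentations, 200L)
  expect_equal(dom$share_pct, round_half_up(100 * 200 / 300, 1))
  # antitone in the threshold
  expect_lte(nrow(dominant_blocks(bs, 0.9)$blocks),
             nrow(dominant_blocks(bs, 0.75)$blocks))
  expect_equal(nrow(dominant_blocks(bs, 0.75, cluster = 2)$blocks), 0L)
})

test_that("the heatmap matrix keeps top-coverage blocks with unit row sums", {
  bs <- manual_block_summary(list(`A00-A09` = c(50, 0), `J09-J18` = c(20, 10),
                                  `J00-J06` = c(0, 15), `L50-L54` = c(5, 0)))
  m <- heatmap_matrix(bs, icd10_blocks(), coverage_threshold = 0.8)
  expect_equal(nrow(m), 2L) # 50 + 30 presentations reach 80% coverage exactly
  expect_equal(unname(rowSums(m)), rep(1, 2))
  expect_equal(ncol(m), 2L)
  full <- heatmap_matrix(bs, icd10_blocks(), coverage_threshold = 1)
  expect_equal(nrow(full), 4L)
  expect_equal(unname(full["A00-A09", ]), c(1, 0))
})
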