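test_that("cohort simulation is deterministic in the seed and sensitive to it", {
  cfg <- cohort_sim_config(n_samples = 30, n_genes = 25, block_size = 4,
                           seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  cfg2 <- cohort_sim_config(n_samples = 30, n_genes = 25, block_size = 4,
                            seed = 12)
  expect_false(identical(simulate_cohort(cfg2)$values, a$values))
})

test_that("perfect coupling makes block genes exact copies of the driver", {
  cfg <- cohort_sim_config(n_samples = 50, n_genes = 10, block_size = 3,
                           block_coupling = 1, seed = 2)
  co <- simulate_cohort(cfg)
  truth <- attr(co, "truth")
  for (g in truth$block) {
    expect_equal(cor(co$values[truth$driver, ], co$values[g, ]), 1.0)
  }
})

test_that("anti-gene is negatively correlated with the driver", {
  cfg <- cohort_sim_config(n_samples = 400, n_genes = 10, block_size = 3,
                           anti_gene_coupling = 0.6, seed = 5)
  co <- simulate_cohort(cfg)
  truth <- attr(co, "truth")
  expect_lt(cor(co$values[truth$driver, ], co$values[truth$anti_gene, ]),
            -0.3)
})

test_that("positive hazard coefficient shortens survival of driver-high samples", {
  cfg <- cohort_sim_config(n_samples = 500, n_genes = 10, block_size = 2,
                           hazard_coef = 0.7, censor_rate = 0, seed = 8)
  co <- simulate_cohort(cfg)
  driver <- co$values[attr(co, "truth")$driver, ]
  hi <- driver > median(driver)
  expect_lt(mean(co$clinical$time_months[hi]),
            mean(co$clinical$time_months[!hi]))
})

test_that("null hazard gives nominal log-rank type-I error over replicate cohorts", {
  n_rep <- 400
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    cfg <- cohort_sim_config(n_samples = 60, n_genes = 5, block_size = 1,
                             hazard_coef = 0, censor_rate = 0.15,
                             seed = 1000 + i)
    co <- simulate_cohort(cfg)
    strat <- median_split(co, attr(co, "truth")$driver)
    lab <- strat$labels[co$clinical$sample_id]
    lr <- logrank_test(co$clinical$time_months[lab == "high"],
                       co$clinical$event[lab == "high"],
                       co$clinical$time_months[lab == "low"],
                       co$clinical$event[lab == "low"])
    rej[i] <- lr$p_two_sided < 0.05
  }
  # 3 binomial SEs around the nominal 5% level
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("cohort config rejects invalid fields by name", {
  expect_error(cohort_sim_config(n_samples = 0, n_genes = 10), "n_samples")
  expect_error(cohort_sim_config(n_samples = 10, n_genes = 10,
                                 block_size = 9), "n_genes")
  expect_error(cohort_sim_config(n_samples = 10, n_genes = 10,
                                 baseline_hazard = 0), "baseline_hazard")
  expect_error(cohort_sim_config(n_samples = 10, n_genes = 10,
                                 censor_rate = 1), "censor_rate")
  expect_error(cohort_sim_config(n_samples = 10, n_genes = 10,
                                 block_coupling = 1.4), "block_coupling")
})

test_that("null expression margins pass a normality sanity check", {
  cfg <- cohort_sim_config(n_samples = 500, n_genes = 20, block_size = 3,
                           seed = 42)
  co <- simulate_cohort(cfg)
  x <- co$values["RND0001", ]
  expect_gt(shapiro.test(x)$p.value, 0.01)
  expect_equal(mean(x), 8.0, tolerance = 0.2)
})

test_that("simulated profiles carry signed ranks whose magnitudes are a permutation", {
  sig <- gene_signature(c("A", "B", "C"))
  cfg <- ref_sim_config(n_drugs = 6, gene_universe = c("A", "B", "C",
                        sprintf("N%02d", 1:17)), n_replicates_range = c(1, 3),
                        seed = 9)
  lib <- simulate_reference_library(cfg, sig)
  for (mat in lib$refs$drugs) {
    for (k in seq_len(ncol(mat))) {
      expect_identical(sort(abs(unname(mat[, k]))), 1:20)
    }
  }
  expect_identical(lib$refs$N, 6L)
  expect_identical(nrow(lib$truth), 6L)
})

test_that("zero reversal strength leaves planted reversers statistically null", {
  sig <- gene_signature(sprintf("S%02d", 1:8))
  universe <- c(sig$gene, sprintf("N%03d", 1:92))
  zs <- numeric(40)
  for (i in seq_len(40)) {
    cfg <- ref_sim_config(n_drugs = 5, gene_universe = universe,
                          planted_reversers = "drug_0001",
                          reversal_strength = 0, seed = 300 + i)
    lib <- simulate_reference_library(cfg, sig)
    run <- connectivity_run(N = 5)
    zs[i] <- score_drug(lib$refs$drugs[["drug_0001"]], sig, run)$z
  }
  expect_lt(abs(mean(zs)), 3 / sqrt(40))
})

test_that("strong reversal puts every planted reverser above all null drugs", {
  sig <- gene_signature(sprintf("S%02d", 1:8))
  universe <- c(sig$gene, sprintf("N%03d", 1:292))
  cfg <- ref_sim_config(n_drugs = 30, gene_universe = universe,
                        planted_reversers = c("drug_0003", "drug_0011"),
                        reversal_strength = 3, seed = 77)
  lib <- simulate_reference_library(cfg, sig)
  run <- connectivity_run(N = 30)
  z <- vapply(lib$refs$drugs, function(m) score_drug(m, sig, run)$z,
              numeric(1))
  is_rev <- lib$truth$is_reverser
  expect_lt(max(z[is_rev]), min(z[!is_rev]))
})

test_that("library config echoes the screened drug count", {
  sig <- gene_signature("A")
  cfg <- ref_sim_config(n_drugs = 1432, gene_universe = c("A", "B", "C"),
                        n_replicates_range = c(1, 1), seed = 1)
  lib <- simulate_reference_library(cfg, sig)
  expect_identical(lib$refs$N, 1432L)
})

test_that("signature genes outside the universe are rejected with their names", {
  cfg <- ref_sim_config(n_drugs = 3, gene_universe = c("A", "B"), seed = 1)
  expect_error(simulate_reference_library(cfg, gene_signature(c("A", "X"))),
               "X")
  expect_error(ref_sim_config(n_drugs = 3, gene_universe = c("A", "B"),
                              planted_reversers = "drug_9999"),
               "drug_9999")
})
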