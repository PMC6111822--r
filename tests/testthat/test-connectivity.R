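test_that("connection strength sums signed ranks and normalizes by the maximum", {
  pr <- c(g1 = 3L, g2 = -2L, g3 = 1L)
  s1 <- connection_strength(pr, gene_signature("g1"))
  expect_equal(s1$c, 3)
  expect_equal(s1$c_normalized, 1.0)
  s2 <- connection_strength(pr, gene_signature("g2"))
  expect_equal(s2$c, -2)
  expect_equal(s2$c_normalized, -2 / 3)
  s3 <- connection_strength(pr, gene_signature(c("g1", "g2"), c(1L, -1L)))
  expect_equal(s3$c, 5)
  expect_equal(s3$c_normalized, 1.0)  # max attainable is 3 + 2
  expect_error(connection_strength(pr, gene_signature(c("g1", "gX"))), "gX")
})

test_that("negating every signature sign negates the connection strength", {
  for (seed in 1:10) {
    pr <- random_profile(40, seed)
    set.seed(seed)
    genes <- sample(names(pr), 6)
    signs <- sample(c(-1L, 1L), 6, replace = TRUE)
    a <- connection_strength(pr, gene_signature(genes, signs))$c
    b <- connection_strength(pr, gene_signature(genes, -signs))$c
    expect_identical(b, -a)
  }
})

test_that("null moments match the finite-population formulas", {
  pr <- c(g1 = 3L, g2 = -2L, g3 = 1L)
  mom <- null_moments(pr, 1)
  expect_equal(mom$mu, 2 / 3, tolerance = 1e-12)
  expect_equal(mom$var, 38 / 9, tolerance = 1e-12)
  # drawing the whole universe leaves no variance
  expect_equal(null_moments(pr, 3)$var, 0, tolerance = 1e-12)
  # sign-balanced profile has zero mean
  bal <- c(a = 1L, b = -1L, c = 2L, d = -2L)
  expect_equal(null_moments(bal, 2)$mu, 0, tolerance = 1e-12)
  expect_error(null_moments(pr, 4), "1..G")
})

test_that("standardized score and one-tailed p follow the null model", {
  pr <- c(g1 = 3L, g2 = -2L, g3 = 1L)
  run <- connectivity_run(N = 10, null_method = "analytic")
  zp <- connection_pvalue(-2, pr, 1, run)
  expect_equal(zp$z, -8 / sqrt(38), tolerance = 1e-12)
  expect_equal(zp$p, pnorm(-8 / sqrt(38)), tolerance = 1e-12)

  rune <- connectivity_run(N = 10, null_method = "exact")
  expect_equal(connection_pvalue(-2, pr, 1, rune)$p, 1 / 3,
               tolerance = 1e-12)

  # score at the null mean -> z = 0, analytic p = 0.5
  mom <- null_moments(pr, 2)
  expect_equal(connection_pvalue(mom$mu, pr, 2, run)$z, 0,
               tolerance = 1e-12)
  expect_equal(connection_pvalue(mom$mu, pr, 2, run)$p, 0.5,
               tolerance = 1e-12)

  # the positive tail mirrors the negative one
  runp <- connectivity_run(N = 10, tail = "positive")
  expect_equal(connection_pvalue(-2, pr, 1, runp)$p,
               pnorm(-8 / sqrt(38), lower.tail = FALSE), tolerance = 1e-12)

  flat <- c(a = 1L)
  expect_error(connection_pvalue(1, flat, 1, run), "variance")
})

test_that("Monte-Carlo p converges to the exact enumeration p", {
  for (seed in c(3, 14, 25)) {
    G <- sample(6:9, 1)
    pr <- random_profile(G, seed)
    for (m in 1:3) {
      rune <- connectivity_run(N = 10, null_method = "exact")
      runm <- connectivity_run(N = 10, null_method = "monte_carlo",
                               n_draws = 4000, seed = seed)
      sets <- combn(G, m)
      totals <- colSums(matrix(as.numeric(pr)[sets], nrow = m))
      for (c_obs in unique(quantile(totals, c(0.1, 0.5, 0.9), type = 1))) {
        pe <- connection_pvalue(c_obs, pr, m, rune)$p
        pm <- connection_pvalue(c_obs, pr, m, runm)$p
        tol <- 3 * sqrt(pe * (1 - pe) / 4000) + (1 - pe) / 4001
        expect_lt(abs(pm - pe), tol + 1e-12)
      }
    }
  }
})

test_that("analytic z agrees with the empirical Monte-Carlo z in the CLT regime", {
  G <- 200
  m <- 10
  pr <- random_profile(G, 7)
  w <- as.numeric(pr)
  set.seed(123)
  draws <- replicate(1e5, sum(w[sample.int(G, m)]))
  c_obs <- quantile(draws, 0.05)
  z_analytic <- connection_pvalue(c_obs, pr, m,
                                  connectivity_run(N = 10))$z
  z_empirical <- (c_obs - mean(draws)) / sd(draws)
  expect_lt(abs(z_analytic - unname(z_empirical)), 0.05)
})

test_that("replicate combination scales the standardized score by sqrt(n)", {
  pr <- random_profile(50, 4)
  sig <- gene_signature(names(pr)[c(2, 9, 17)])
  run <- connectivity_run(N = 10)
  one <- score_drug(matrix(pr, ncol = 1, dimnames = list(names(pr), NULL)),
                    sig, run)
  four <- score_drug(matrix(rep(pr, 4), ncol = 4,
                            dimnames = list(names(pr), NULL)), sig, run)
  expect_equal(four$z, 2 * one$z, tolerance = 1e-12)
  expect_equal(four$c_total, 4 * one$c_total)
  # a single replicate reduces to connection_pvalue
  direct <- connection_pvalue(one$c_total, pr, 3, run)
  expect_equal(one$z, direct$z, tolerance = 1e-12)
  expect_equal(one$p, direct$p, tolerance = 1e-12)
})

test_that("perturbation stability counts significant leave-one-out signatures", {
  # constructed 4-gene universe where only some leave-one-out scores pass
  pr <- c(a = -4L, b = -3L, c = 2L, d = 1L)
  sig <- gene_signature(c("a", "b"))
  run <- connectivity_run(N = 4, null_method = "exact", threshold = 0.3)
  # leave-one-out singletons: {a} with c=-4 (p=1/4), {b} with c=-3 (p=1/2)
  expect_equal(perturbation_stability(matrix(pr, ncol = 1,
                                             dimnames = list(names(pr), NULL)),
                                      sig, run), 0.5)
  expect_error(perturbation_stability(matrix(pr, ncol = 1,
                                             dimnames = list(names(pr), NULL)),
                                      gene_signature("a"), run),
               "at least 2")
})

test_that("stability hits 1 for strong reversers and 0 for inert drugs", {
  sig <- gene_signature(sprintf("S%02d", 1:8))
  universe <- c(sig$gene, sprintf("N%03d", 1:492))
  cfg <- ref_sim_config(n_drugs = 10, gene_universe = universe,
                        planted_reversers = "drug_0002",
                        reversal_strength = 4,
                        n_replicates_range = c(3, 3), seed = 15)
  lib <- simulate_reference_library(cfg, sig)
  run <- connectivity_run(N = 1432)
  expect_equal(perturbation_stability(lib$refs$drugs[["drug_0002"]], sig,
                                      run), 1.0)
  expect_equal(perturbation_stability(lib$refs$drugs[["drug_0001"]], sig,
                                      run), 0.0)
})

test_that("stability never decreases when reversal strength grows (matched seeds)", {
  sig <- gene_signature(sprintf("S%02d", 1:6))
  universe <- c(sig$gene, sprintf("N%03d", 1:294))
  run <- connectivity_run(N = 100)
  for (seed in c(5, 6)) {
    stab <- vapply(c(1, 2, 4), function(strength) {
      cfg <- ref_sim_config(n_drugs = 4, gene_universe = universe,
                            planted_reversers = "drug_0001",
                            reversal_strength = strength,
                            n_replicates_range = c(2, 2), seed = seed)
      lib <- simulate_reference_library(cfg, sig)
      perturbation_stability(lib$refs$drugs[["drug_0001"]], sig, run)
    }, numeric(1))
    expect_true(all(diff(stab) >= 0))
  }
})

test_that("significance threshold is exactly 1/N with its control rationale", {
  thr <- significance_threshold(1432)
  expect_equal(as.numeric(thr), 1 / 1432, tolerance = 1e-15)
  expect_match(attr(thr, "rationale"), "expected number")
  expect_equal(as.numeric(significance_threshold(1)), 1.0)
  expect_equal(as.numeric(significance_threshold(1000)), 0.001)
  expect_error(significance_threshold(0), "positive")
})

test_that("expected false discovery is the reciprocal of the significant count", {
  expect_equal(expected_false_discovery(95), 1 / 95, tolerance = 1e-15)
  expect_equal(expected_false_discovery(1), 1.0)
  expect_equal(expected_false_discovery(200), 0.005)
  expect_warning(out <- expected_false_discovery(0), "no significant")
  expect_true(is.na(out))
})

test_that("drugs are ranked by p, then stability, then score, then id", {
  res <- data.frame(
    drug_id = c("d_late", "d_early", "d_unstable", "d_stable", "d_b", "d_a"),
    replicate_count = 1L,
    c_total = 0,
    z = c(-5, -6, -3, -3, -1, -1),
    p = c(1e-9, 1e-11, 1e-4, 1e-4, 0.5, 0.5),
    significance_mark = c(1L, 1L, 1L, 1L, 0L, 0L),
    perturb_stability = c(1, 1, 0.5, 1, 0, 0),
    stringsAsFactors = FALSE)
  ranked <- rank_drugs(res)
  expect_identical(ranked$drug_id,
                   c("d_early", "d_late", "d_stable", "d_unstable",
                     "d_a", "d_b"))
})

test_that("significance line sits at -log10(1/N)", {
  res <- data.frame(drug_id = c("a", "b"), replicate_count = 1L,
                    c_total = c(-10, 5), z = c(-4, 1),
                    p = c(1e-5, 0.7), significance_mark = c(1L, 0L),
                    perturb_stability = c(1, 0), stringsAsFactors = FALSE)
  png_path <- withr::local_tempfile(fileext = ".png")
  y <- significance_plot(res, as.numeric(significance_threshold(1432)),
                         out_path = png_path)
  expect_equal(round(y, 2), 3.16)
  expect_true(file.exists(png_path))
  expect_equal(significance_plot(res, as.numeric(significance_threshold(10)),
                                 out_path = png_path), 1.0)
  expect_error(significance_plot(res[0, ], 0.1), "no results")
})

test_that("cmap_screen scores, stabilizes, marks and ranks a whole library", {
  sig <- gene_signature(sprintf("S%02d", 1:6))
  universe <- c(sig$gene, sprintf("N%03d", 1:194))
  cfg <- ref_sim_config(n_drugs = 25, gene_universe = universe,
                        planted_reversers = c("drug_0004", "drug_0018"),
                        reversal_strength = 4, seed = 33)
  lib <- simulate_reference_library(cfg, sig)
  scr <- cmap_screen(sig, lib$refs, seed = 33)
  expect_s3_class(scr, "cmap_screen")
  expect_identical(nrow(scr$results), 25L)
  top2 <- scr$results$drug_id[1:2]
  expect_setequal(top2, c("drug_0004", "drug_0018"))
  expect_true(all(scr$results$significance_mark[1:2] == 1))
  expect_true(all(diff(scr$results$p) >= 0 |
                  diff(scr$results$p) == 0))
  expect_identical(scr$n_significant,
                   sum(scr$results$significance_mark))
  # p-values always in (0, 1]
  expect_true(all(scr$results$p > 0 & scr$results$p <= 1))
  # stability values live on the m-point grid
  stab <- scr$results$perturb_stability
  expect_true(all(abs(stab * 6 - round(stab * 6)) < 1e-12))
  expect_output(print(scr), "connectivity screen")
  expect_output(summary(scr), "drugs screened")
})

test_that("single-gene signatures skip stability with a warning", {
  sig <- gene_signature("S01")
  cfg <- ref_sim_config(n_drugs = 4, gene_universe = c("S01",
                        sprintf("N%02d", 1:19)), seed = 2)
  lib <- simulate_reference_library(cfg, sig)
  expect_warning(scr <- cmap_screen(sig, lib$refs), "stability")
  expect_true(all(is.na(scr$results$perturb_stability)))
})
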