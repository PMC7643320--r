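test_that("exact test agrees with brute-force conditional enumeration (small totals)", {
  set.seed(101)
  for (i in 1:200) {
    n_a <- sample(1:4, 1); n_b <- sample(1:4, 1)
    phi <- sample(c(0, 0.05, 0.2, 1), 1)
    S <- sample(0:30, 1)
    S_a <- sample(0:S, 1)
    # equal library sizes: feed per-sample counts summing to S_a / S - S_a
    ca <- diff(c(0, sort(sample(0:S_a, n_a - 1, replace = TRUE)), S_a))
    cb <- diff(c(0, sort(sample(0:(S - S_a), n_b - 1, replace = TRUE)),
                 S - S_a))
    got <- nb_exact_test(ca, cb, rep(1e6, n_a), rep(1e6, n_b), phi)
    if (S == 0) {
      expect_equal(got$p_value, 1)
    } else {
      expect_equal(got$p_value, oracle_exact_p(S_a, S - S_a, n_a, n_b, phi),
                   tolerance = 1e-12)
    }
  }
})

test_that("Poisson limit 10 vs 0 with equal sizes gives the binomial closed form", {
  r <- nb_exact_test(10, 0, 1, 1, phi = 0)
  expect_equal(r$p_value, 2 / 1024)
  expect_equal(r$log2_fc, log2(10.5 / 0.5))
})

test_that("identical groups give p = 1 and zero fold change", {
  r <- nb_exact_test(c(5, 7, 9), c(5, 7, 9), rep(1e6, 3), rep(1e6, 3),
                     phi = 0.1)
  expect_equal(r$log2_fc, 0)
  expect_equal(r$p_value, 1)
})

test_that("swapping groups negates log2FC and preserves the p-value", {
  set.seed(7)
  for (i in 1:25) {
    ca <- rpois(4, 30); cb <- rpois(3, 50)
    la <- runif(4, 0.8e6, 1.2e6); lb <- runif(3, 0.8e6, 1.2e6)
    r1 <- nb_exact_test(ca, cb, la, lb, phi = 0.15)
    r2 <- nb_exact_test(cb, ca, lb, la, phi = 0.15)
    expect_equal(r1$p_value, r2$p_value)
    expect_equal(r1$log2_fc, -r2$log2_fc)
  }
})

test_that("nb_exact_test rejects negative counts and dispersion", {
  expect_error(nb_exact_test(-1, 2, 1, 1, 0.1), "negative")
  expect_error(nb_exact_test(1, 2, 1, 1, -0.1), "phi")
})

test_that("test_all_windows matches the single-window test and is deterministic", {
  s <- small_sim()
  m <- s$counts
  eff <- effective_lib_sizes(m)
  res <- test_all_windows(m, phi = 0.1, eff_lib_sizes = eff)
  expect_equal(nrow(res), nrow(m$counts))
  a <- m$samples$group == "disease"
  for (w in c(1, 500, 1500)) {
    single <- nb_exact_test(m$counts[w, a], m$counts[w, !a],
                            eff[a], eff[!a], phi = 0.1)
    expect_equal(res$p_value[w], single$p_value, tolerance = 1e-12)
    expect_equal(res$log2_fc[w], single$log2_fc, tolerance = 1e-12)
  }
  expect_identical(res, test_all_windows(m, phi = 0.1, eff_lib_sizes = eff))
})

test_that("coverage floor marks low-count windows untested with p = 1", {
  w <- tile_genome(c(chr1 = 3000), 1000)
  x <- matrix(c(0, 0, 50, 0, 1, 60, 0, 0, 55, 0, 0, 52), nrow = 3)
  colnames(x) <- paste0("s", 1:4)
  m <- window_counts(x, w, groups = c("disease", "disease",
                                      "no_disease", "no_disease"))
  res <- test_all_windows(m, phi = 0.1, min_mean_count = 1,
                          eff_lib_sizes = rep(100, 4))
  expect_equal(res$tested, c(FALSE, FALSE, TRUE))
  expect_equal(res$p_value[1:2], c(1, 1))
  res_all_low <- test_all_windows(m, phi = 0.1, min_mean_count = 1000,
                                  eff_lib_sizes = rep(100, 4))
  expect_true(all(!res_all_low$tested))
  expect_true(all(res_all_low$p_value == 1))
})

test_that("planted windows rank at the bottom of the p-value ordering", {
  s <- small_sim()
  res <- test_all_windows(s$counts, phi = estimate_common_dispersion(s$counts))
  in_dmr <- rep(FALSE, nrow(res))
  for (i in seq_len(nrow(s$truth)))
    in_dmr[res$chrom == s$truth$chrom[i] & res$start >= s$truth$start[i] &
             res$end <= s$truth$end[i]] <- TRUE
  expect_lt(median(res$p_value[in_dmr]), 1e-8)
  expect_lt(median(res$p_value[in_dmr]), median(res$p_value[!in_dmr]))
})

test_that("dispersion estimation recovers the simulation parameter", {
  # Poisson data: phi-hat pinned near zero
  cfg0 <- sim_config(n_chromosomes = 1, windows_per_chromosome = 10000,
                     n_dmrs = 0, dispersion = 0, baseline_mean = 50,
                     libsize_factor_sd = 0.05, n_disease = 5, n_control = 5,
                     seed = 17)
  g0 <- simulate_genome(cfg0)
  m0 <- simulate_window_counts(g0, plant_epimutations(g0, cfg0), cfg0)
  expect_lte(estimate_common_dispersion(m0)$common_dispersion, 0.01)
  # NB data with phi = 0.2, 10 vs 10
  cfg <- sim_config(n_chromosomes = 1, windows_per_chromosome = 10000,
                    n_dmrs = 0, dispersion = 0.2, baseline_mean = 50,
                    libsize_factor_sd = 0.05, n_disease = 10, n_control = 10,
                    seed = 18)
  g <- simulate_genome(cfg)
  m <- simulate_window_counts(g, plant_epimutations(g, cfg), cfg)
  phi_hat <- estimate_common_dispersion(m)$common_dispersion
  expect_gte(phi_hat, 0.15)
  expect_lte(phi_hat, 0.25)
  # all-constant counts -> zero dispersion
  w <- tile_genome(c(chr1 = 100000), 1000)
  mc <- window_counts(matrix(20, 100, 4,
                             dimnames = list(NULL, paste0("s", 1:4))),
                      w[1:100, ],
                      groups = rep(c("disease", "no_disease"), each = 2))
  expect_equal(estimate_common_dispersion(
    mc, eff_lib_sizes = rep(2000, 4))$common_dispersion, 0)
  expect_error(estimate_common_dispersion(
    window_counts(matrix(5, 100, 2, dimnames = list(NULL, c("a", "b"))),
                  w[1:100, ], groups = c("disease", "no_disease"))),
    "2 samples")
})

test_that("exact test is distributionally calibrated against edgeR on shared data", {
  skip_if_not_installed("edgeR")
  cfg <- sim_config(n_chromosomes = 1, windows_per_chromosome = 2000,
                    n_dmrs = 0, dispersion = 0.1, baseline_mean = 50,
                    libsize_factor_sd = 0.05, n_disease = 6, n_control = 6,
                    seed = 23)
  g <- simulate_genome(cfg)
  m <- simulate_window_counts(g, plant_epimutations(g, cfg), cfg)
  res <- test_all_windows(m, phi = 0.1)
  dge <- edgeR::DGEList(counts = m$counts, group = m$samples$group)
  dge <- edgeR::calcNormFactors(dge)
  et <- edgeR::exactTest(dge, dispersion = 0.1,
                         pair = c("no_disease", "disease"))
  # same model family and data: p-values strongly rank-correlated
  expect_gt(cor(res$p_value, et$table$PValue, method = "spearman"), 0.95)
})

test_that("BH adjustment matches the hand example and a quadratic reference", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  set.seed(55)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q[order(p)] == cummax(q[order(p)]) | diff(range(p)) == 0))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
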