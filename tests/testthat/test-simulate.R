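test_that("genome tiling matches the configured geometry and is seeded", {
  cfg <- sim_config(n_chromosomes = 1, windows_per_chromosome = 10,
                    window_size = 1000, seed = 3)
  g <- simulate_genome(cfg)
  expect_equal(unname(g$chrom_lengths), 10000)
  expect_equal(nrow(g$windows), 10)
  expect_equal(g$windows$end - g$windows$start, rep(1000, 10))
  expect_true(all(g$windows$cpg <= 500))
  g2 <- simulate_genome(cfg)
  expect_identical(g, g2)
  g3 <- simulate_genome(sim_config(n_chromosomes = 1,
                                   windows_per_chromosome = 10, seed = 4))
  expect_false(identical(g$windows$cpg, g3$windows$cpg))
})

test_that("per-window CpG counts average to the configured rate", {
  cfg <- sim_config(n_chromosomes = 1, windows_per_chromosome = 20000,
                    cpg_rate = 2, seed = 11)
  g <- simulate_genome(cfg)
  # Poisson(20): MC standard error of the mean = sqrt(20/n)
  se <- sqrt(20 / nrow(g$windows))
  expect_lt(abs(mean(g$windows$cpg) - 20), 4 * se)
})

test_that("config validation rejects degenerate dimensions", {
  expect_error(sim_config(n_chromosomes = 0), "strictly positive")
  expect_error(sim_config(window_size = -5), "strictly positive")
  expect_error(sim_config(dispersion = -0.1), ">= 0")
  expect_silent(sim_config(dispersion = 0, effect_log2 = 0))
})

test_that("planted regions are grid-aligned, disjoint, and span-correct", {
  cfg <- sim_config(n_chromosomes = 2, windows_per_chromosome = 200,
                    n_dmrs = 5, dmr_span = 3, seed = 9)
  g <- simulate_genome(cfg)
  t <- plant_epimutations(g, cfg)
  expect_equal(nrow(t), 5)
  expect_true(all(t$end - t$start == 3000))
  expect_true(all(t$start %% 1000 == 0))
  for (ch in unique(t$chrom)) {
    x <- t[t$chrom == ch, ]
    if (nrow(x) > 1)
      expect_true(all(x$start[-1] >= x$end[-nrow(x)]))
  }
  # empty truth set
  cfg0 <- sim_config(n_chromosomes = 1, windows_per_chromosome = 100,
                     n_dmrs = 0)
  expect_equal(nrow(plant_epimutations(simulate_genome(cfg0), cfg0)), 0)
  # insufficient space
  cfg_big <- sim_config(n_chromosomes = 1, windows_per_chromosome = 10,
                        n_dmrs = 5, dmr_span = 3)
  expect_error(plant_epimutations(simulate_genome(cfg_big), cfg_big),
               "too small|non-overlapping")
})

test_that("different seeds move placements but keep counts and spans", {
  base <- list(n_chromosomes = 1, windows_per_chromosome = 500,
               n_dmrs = 8, dmr_span = 2)
  t1 <- do.call(sim_config, c(base, seed = 21))
  t2 <- do.call(sim_config, c(base, seed = 22))
  a <- plant_epimutations(simulate_genome(t1), t1)
  b <- plant_epimutations(simulate_genome(t2), t2)
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$end - a$start, b$end - b$start)
  expect_false(identical(a$start, b$start))
  # balanced direction split
  expect_equal(sum(a$direction == "hyper"), 4)
})

test_that("count moments match the NB model on non-planted windows", {
  cfg <- sim_config(n_chromosomes = 1, windows_per_chromosome = 10000,
                    n_dmrs = 0, baseline_mean = 50, dispersion = 0.1,
                    libsize_factor_sd = 1e-9, n_disease = 4, n_control = 4,
                    seed = 5)
  g <- simulate_genome(cfg)
  t <- plant_epimutations(g, cfg)
  m <- simulate_window_counts(g, t, cfg)
  x <- as.vector(m$counts)
  n <- length(x)
  expect_lt(abs(mean(x) - 50), 3 * sqrt((50 + 0.1 * 2500) / n))
  # empirical variance near mu + phi mu^2 = 300
  expect_lt(abs(var(x) - 300) / 300, 0.05)
  # Poisson limit: variance ~ mean
  cfg0 <- sim_config(n_chromosomes = 1, windows_per_chromosome = 10000,
                     n_dmrs = 0, baseline_mean = 50, dispersion = 0,
                     libsize_factor_sd = 1e-9, n_disease = 2, n_control = 2,
                     seed = 6)
  m0 <- simulate_window_counts(simulate_genome(cfg0),
                               plant_epimutations(simulate_genome(cfg0), cfg0),
                               cfg0)
  x0 <- as.vector(m0$counts)
  expect_lt(abs(var(x0) / mean(x0) - 1), 0.05)
})

test_that("planted effect is recovered in the group mean log2 ratio", {
  s <- small_sim()
  m <- s$counts
  in_dmr <- rep(FALSE, nrow(m$counts))
  for (i in seq_len(nrow(s$truth)))
    in_dmr[m$windows$chrom == s$truth$chrom[i] &
             m$windows$start >= s$truth$start[i] &
             m$windows$end <= s$truth$end[i]] <- TRUE
  # adjust for per-sample depth so the ratio isolates the planted effect
  cs <- colSums(m$counts)
  xn <- sweep(m$counts, 2, cs / exp(mean(log(cs))), "/")
  dis <- rowMeans(xn[, m$samples$group == "disease"])
  ctl <- rowMeans(xn[, m$samples$group == "no_disease"])
  ratio <- log2(dis[in_dmr] / ctl[in_dmr])
  sign_truth <- rep(sign(s$truth$effect_log2), each = s$cfg$dmr_span)
  expect_lt(mean(abs(ratio * sign_truth - 2)), 0.35)
  # background windows centred at ratio 0
  expect_lt(abs(mean(log2(dis[!in_dmr] / ctl[!in_dmr]))), 0.05)
})

test_that("identical config and seed reproduce the count matrix exactly", {
  cfg <- sim_config(n_chromosomes = 1, windows_per_chromosome = 200,
                    n_dmrs = 2, seed = 31)
  run <- function() {
    g <- simulate_genome(cfg)
    simulate_window_counts(g, plant_epimutations(g, cfg), cfg)
  }
  expect_identical(run()$counts, run()$counts)
})

test_that("FASTA output reproduces the model CpG counts", {
  skip_if_not_installed("Biostrings")
  cfg <- sim_config(n_chromosomes = 2, windows_per_chromosome = 20,
                    window_size = 500, cpg_rate = 3, seed = 13)
  g <- simulate_genome(cfg)
  path <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g, path)
  seqs <- Biostrings::readDNAStringSet(path)
  expect_equal(unname(Biostrings::width(seqs)), unname(g$chrom_lengths))
  for (ch in names(g$chrom_lengths)) {
    w <- g$windows[g$windows$chrom == ch, ]
    counted <- vapply(seq_len(nrow(w)), function(i)
      Biostrings::countPattern("CG", Biostrings::subseq(seqs[[ch]],
                                                        w$start[i] + 1,
                                                        w$end[i])),
      integer(1))
    expect_equal(counted, w$cpg)
  }
})
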