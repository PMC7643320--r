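test_that("tile_genome tiles chromosomes exactly, truncating the last window", {
  w <- tile_genome(c(chr1 = 10000), 1000)
  expect_equal(nrow(w), 10)
  expect_equal(w$start[10], 9000)
  expect_equal(w$end[10], 10000)
  w2 <- tile_genome(c(chrA = 2500), 1000)
  expect_equal(nrow(w2), 3)
  expect_equal(c(w2$start[3], w2$end[3]), c(2000, 2500))
  expect_equal(sum(w2$end - w2$start), 2500)
  expect_error(tile_genome(c(chr1 = 0), 1000), "positive")
})

test_that("bin_reads assigns by midpoint with half-open convention and conserves reads", {
  w <- tile_genome(c(chr1 = 5000), 1000)
  reads <- data.frame(chrom = "chr1",
                      start = c(1400, 500, 999),
                      end = c(1600, 1500, 1001))
  # midpoints 1500, 1000, 1000 -> all in window [1000, 2000)
  r <- bin_reads(reads, w)
  expect_equal(r$counts, c(0L, 3L, 0L, 0L, 0L))
  expect_equal(r$skipped, 0L)
  # unknown chromosome is skipped and logged
  reads2 <- rbind(reads, data.frame(chrom = "chrX", start = 0, end = 100))
  expect_message(r2 <- bin_reads(reads2, w), "unknown chromosome")
  expect_equal(sum(r2$counts) + r2$skipped, nrow(reads2))
  expect_error(bin_reads(data.frame(chrom = "chr1", start = 10, end = 10), w),
               "malformed")
})

test_that("rpkm matches its definition and is depth-scale invariant", {
  w <- tile_genome(c(chr1 = 2000), 1000)
  m <- window_counts(matrix(c(10, 0, 20, 40), 2, 2,
                            dimnames = list(NULL, c("s1", "s2"))),
                     w, groups = c("disease", "no_disease"),
                     lib_sizes = c(1e6, 2e6))
  rp <- rpkm_matrix(m)
  expect_equal(as.numeric(rp[1, 1]), 10)
  expect_equal(as.numeric(rp[2, 1]), 0)
  expect_equal(as.numeric(rp[1, 2]), 10)   # 20 reads at 2M depth
  # doubling counts and depth together leaves RPKM unchanged
  m2 <- window_counts(m$counts * 2, w, groups = m$samples$group,
                      lib_sizes = m$samples$lib_size * 2)
  expect_equal(rpkm_matrix(m2), rpkm_matrix(m))
  expect_error(rpkm_matrix(m, lib_sizes = c(0, 1)), "library size")
})

test_that("tmm factors: symmetry, doubled-column ratio, geometric mean one", {
  w <- tile_genome(c(chr1 = 200000), 1000)
  set.seed(1)
  base <- rpois(200, 50) + 1
  m_id <- window_counts(cbind(a = base, b = base, c = base), w[1:200, ],
                        groups = c("disease", "disease", "no_disease"))
  expect_equal(unname(tmm_factors(m_id)), rep(1, 3))
  m_double <- window_counts(cbind(a = base, b = 2 * base), w[1:200, ],
                            groups = c("disease", "no_disease"))
  f <- tmm_factors(m_double)
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(f[["b"]] / f[["a"]]), 2)
  # geometric mean 1 on arbitrary data
  set.seed(2)
  x <- matrix(rnbinom(1000 * 4, mu = 30, size = 5), ncol = 4)
  colnames(x) <- paste0("s", 1:4)
  m4 <- window_counts(x, tile_genome(c(chr1 = 1e6), 1000),
                      groups = c("disease", "disease", "no_disease",
                                 "no_disease"))
  f4 <- tmm_factors(m4)
  expect_equal(exp(mean(log(f4))), 1)
  # permuting the samples permutes the factors
  perm <- c(3, 1, 4, 2)
  mp <- window_counts(x[, perm], tile_genome(c(chr1 = 1e6), 1000),
                      groups = c("no_disease", "disease", "no_disease",
                                 "disease"))
  expect_equal(unname(tmm_factors(mp)), unname(f4[perm]))
  expect_error(tmm_factors(window_counts(cbind(a = base, z = 0 * base),
                                         w[1:200, ],
                                         groups = c("disease", "no_disease"))),
               "all-zero")
})

test_that("effective library sizes reduce to raw sizes for pure depth differences", {
  w <- tile_genome(c(chr1 = 300000), 1000)[1:300, ]
  set.seed(3)
  base <- rpois(300, 40) + 1
  m <- window_counts(cbind(a = base, b = 3 * base), w,
                     groups = c("disease", "no_disease"))
  eff <- effective_lib_sizes(m)
  expect_equal(unname(eff), unname(m$samples$lib_size), tolerance = 1e-6)
  eff_tc <- effective_lib_sizes(m, method = "total-count")
  expect_equal(unname(eff_tc), m$samples$lib_size)
})

test_that("counts round-trip through TSV with groups intact", {
  s <- small_sim()
  m <- s$counts
  cpath <- withr::local_tempfile(fileext = ".tsv")
  gpath <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(m, cpath)
  write_groups_tsv(m, gpath)
  m2 <- read_counts_tsv(cpath, gpath)
  expect_equal(unname(m2$counts), unname(m$counts))
  expect_equal(m2$windows, m$windows, ignore_attr = TRUE)
  expect_equal(m2$samples$group, m$samples$group)
  # malformed cell is reported with its position
  lines <- readLines(cpath)
  lines[3] <- sub("\t\\d+\t", "\tnot_a_count\t", lines[3])
  writeLines(lines, cpath)
  expect_error(read_counts_tsv(cpath, gpath), "non-integer")
})

test_that("window_counts validates its invariants", {
  w <- tile_genome(c(chr1 = 2000), 1000)
  expect_error(window_counts(matrix(-1, 2, 2), w,
                             groups = c("disease", "no_disease")),
               "negative")
  expect_error(window_counts(matrix(1, 2, 2), w, groups = c("x", "y")),
               "disease")
  expect_error(window_counts(matrix(5, 2, 2), w,
                             groups = c("disease", "no_disease"),
                             lib_sizes = c(1, 1)),
               "library size")
})
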