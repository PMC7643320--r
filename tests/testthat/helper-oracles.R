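# Independent brute-force oracles used to pin down the analytic routines.
# These are written from the definitions, not from the package's code paths.

# NB pmf via explicit log-gamma formula (size r, mean mu)
nb_logpmf <- function(x, mu, r) {
  lgamma(x + r) - lgamma(r) - lgamma(x + 1) +
    r * (log(r) - log(r + mu)) + x * (log(mu) - log(r + mu))
}

# Brute-force conditional exact test: enumerate s = 0..S directly from the
# joint law of (S_A, S_B), normalize, and sum outcomes no more likely than
# the observed one.
oracle_exact_p <- function(S_a, S_b, n_a, n_b, phi) {
  S <- S_a + S_b
  mu <- S / (n_a + n_b)
  s <- 0:S
  lp <- if (phi <= 0) {
    dpois(s, n_a * mu, log = TRUE) + dpois(S - s, n_b * mu, log = TRUE)
  } else {
    nb_logpmf(s, n_a * mu, n_a / phi) + nb_logpmf(S - s, n_b * mu, n_b / phi)
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[S_a + 1] * (1 + 1e-12)]))
}

# Quadratic-time BH reference: q_i = min over j with p_j >= p_i of m*p_j/rank_j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[o[j]] / j, numeric(1))
    q_sorted[i] <- min(1, min(vals))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Full hypergeometric enumeration for a 2x2 Fisher test (fixed margins)
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  pr <- vapply(lo:hi, function(x)
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)),
    numeric(1))
  obs <- pr[a - lo + 1]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# small deterministic window-test table on a 1 kb grid for assembly tests
toy_results <- function(p, chrom = "chr1", tested = rep(TRUE, length(p)),
                        log2_fc = rep(1, length(p))) {
  n <- length(p)
  structure(data.frame(chrom = chrom, start = (0:(n - 1)) * 1000,
                       end = (1:n) * 1000, p_value = p, log2_fc = log2_fc,
                       mean_disease = 10, mean_no_disease = 10,
                       tested = tested, stringsAsFactors = FALSE),
            class = c("window_tests", "data.frame"))
}

# shared small simulation (cached per session) for simulation-based tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_chromosomes = 1, windows_per_chromosome = 3000,
                        n_dmrs = 10, seed = 42)
      g <- simulate_genome(cfg)
      t <- plant_epimutations(g, cfg)
      m <- simulate_window_counts(g, t, cfg)
      cache <<- list(cfg = cfg, genome = g, truth = t, counts = m)
    }
    cache
  }
})
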