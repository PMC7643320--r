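#' Estimate a common negative binomial dispersion
#'
#' Method-of-moments estimate of the dispersion phi in
#' `variance = mu + phi * mu^2`, computed from counts adjusted to a common
#' effective library size. Per window, the pooled within-group variance `v`
#' and overall mean `m` of the adjusted counts give
#' `phi_w = max(0, (v - m) / m^2)`; the common value is the mean of `phi_w`
#' over tested windows, weighted proportionally to `m` (deeper windows are
#' more informative).
#'
#' @param mat a [window_counts()] object with >= 2 samples in at least one
#'   group.
#' @param min_mean_count windows with mean raw count below this are excluded.
#' @param eff_lib_sizes effective library sizes; default [effective_lib_sizes()].
#' @return list of class `dispersion_estimate`: `common_dispersion`,
#'   `n_windows_used`, `method`.
#' @export
estimate_common_dispersion <- function(mat, min_mean_count = 1,
                                       eff_lib_sizes = effective_lib_sizes(mat)) {
  g <- mat$samples$group
  n_by_g <- table(g)
  if (!any(n_by_g >= 2))
    stop("estimate_common_dispersion: need >= 2 samples in a group",
         call. = FALSE)
  keep <- rowMeans(mat$counts) >= min_mean_count
  if (sum(keep) < 50)
    stop("estimate_common_dispersion: fewer than 50 windows pass the ",
         "coverage filter", call. = FALSE)
  scale <- exp(mean(log(eff_lib_sizes))) / eff_lib_sizes
  x <- sweep(mat$counts[keep, , drop = FALSE], 2, scale, "*")
  m <- rowMeans(x)

  ss <- 0; df <- 0
  for (lev in names(n_by_g)) {
    if (n_by_g[[lev]] < 2) next
    xs <- x[, g == lev, drop = FALSE]
    mu_g <- rowMeans(xs)
    ss <- ss + rowSums((xs - mu_g)^2)
    df <- df + (ncol(xs) - 1)
  }
  v <- ss / df
  ok <- m > 0
  phi_w <- pmax(0, (v[ok] - m[ok]) / m[ok]^2)
  phi <- sum(phi_w * m[ok]) / sum(m[ok])
  structure(list(common_dispersion = phi, n_windows_used = sum(ok),
                 method = "moments-pooled"),
            class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat("Common NB dispersion (", x$method, "): phi =",
      signif(x$common_dispersion, 4), "from", x$n_windows_used, "windows\n")
  invisible(x)
}

# Conditional pmf of the group-A sum given the total S, for equalized
# libraries: S_A ~ NB(nA*mu, phi/nA), S_B ~ NB(nB*mu, phi/nB), mu = S/(nA+nB).
# Returns the vector P(S_A = s | S) for s = 0..S.
cond_pmf <- function(S, n_a, n_b, phi) {
  s <- 0:S
  mu <- S / (n_a + n_b)
  if (phi <= 0) {
    lp <- stats::dpois(s, n_a * mu, log = TRUE) +
      stats::dpois(S - s, n_b * mu, log = TRUE)
  } else {
    lp <- stats::dnbinom(s, mu = n_a * mu, size = n_a / phi, log = TRUE) +
      stats::dnbinom(S - s, mu = n_b * mu, size = n_b / phi, log = TRUE)
  }
  p <- exp(lp - max(lp))
  p / sum(p)
}

# Two-sided minimum-likelihood p-value from a conditional pmf: the summed
# probability of outcomes no more likely than the observed one (tiny relative
# tolerance absorbs floating-point ties).
pval_from_pmf <- function(pmf, observed) {
  min(1, sum(pmf[pmf <= pmf[observed + 1L] * (1 + 1e-12)]))
}

#' Negative binomial exact test for one window
#'
#' Two-group exact test of differential coverage. Counts are scaled to a
#' common library size (the geometric mean of the effective sizes) and
#' rounded to integers (ties to even); group sums `S_A`, `S_B` are formed;
#' conditional on the total `S = S_A + S_B`, the two-sided p-value sums the
#' probabilities of all outcomes no more likely than the observed one, under
#' `S_A ~ NB(n_A * mu, phi / n_A)` and `S_B ~ NB(n_B * mu, phi / n_B)` with
#' `mu = S / (n_A + n_B)`. `phi = 0` gives the Poisson limit (a binomial
#' conditional law). The log2 fold change uses a 0.5 pseudo-count per group
#' mean: `log2((S_A/n_A + 0.5) / (S_B/n_B + 0.5))`.
#'
#' @param counts_a,counts_b raw counts for the window, one per sample.
#' @param lib_a,lib_b effective library sizes per sample.
#' @param phi common dispersion (>= 0).
#' @return list with `p_value` and `log2_fc` (group A over group B).
#' @examples
#' # Poisson limit, 10 vs 0 with equal sizes: conditional Binomial(10, 1/2)
#' nb_exact_test(10, 0, 1, 1, phi = 0)$p_value  # 2/1024
#' @export
nb_exact_test <- function(counts_a, counts_b, lib_a, lib_b, phi) {
  if (any(c(counts_a, counts_b) < 0))
    stop("nb_exact_test: negative counts", call. = FALSE)
  if (phi < 0) stop("nb_exact_test: phi must be >= 0", call. = FALSE)
  eff <- c(lib_a, lib_b)
  common <- exp(mean(log(eff)))
  eq <- round(c(counts_a, counts_b) * common / eff)
  n_a <- length(counts_a); n_b <- length(counts_b)
  S_a <- sum(eq[seq_len(n_a)]); S_b <- sum(eq[-seq_len(n_a)])
  S <- S_a + S_b
  l2fc <- log2((S_a / n_a + 0.5) / (S_b / n_b + 0.5))
  if (S == 0) return(list(p_value = 1, log2_fc = 0))
  pmf <- cond_pmf(S, n_a, n_b, phi)
  list(p_value = pval_from_pmf(pmf, S_a), log2_fc = l2fc)
}

#' Test every window for differential coverage
#'
#' Applies the exact test to each window. Windows whose mean raw count falls
#' below `min_mean_count` are marked untested and carry `p = 1`. The
#' conditional law depends only on the equalized total `S`, so the pmf is
#' computed once per distinct total and reused.
#'
#' @param mat a [window_counts()] object.
#' @param phi common dispersion (a number or a `dispersion_estimate`).
#' @param min_mean_count coverage floor in mean raw reads per window.
#' @param eff_lib_sizes effective library sizes; default [effective_lib_sizes()].
#' @return data.frame of class `window_tests`: `chrom`, `start`, `end`,
#'   `p_value`, `log2_fc` (disease over no_disease), `mean_disease`,
#'   `mean_no_disease` (normalized per-group means), `tested`.
#' @export
test_all_windows <- function(mat, phi = estimate_common_dispersion(mat),
                             min_mean_count = 1,
                             eff_lib_sizes = effective_lib_sizes(mat)) {
  if (inherits(phi, "dispersion_estimate")) phi <- phi$common_dispersion
  g <- mat$samples$group
  if (!all(c("disease", "no_disease") %in% g))
    stop("test_all_windows: both groups must be present", call. = FALSE)
  a <- g == "disease"; b <- g == "no_disease"
  n_a <- sum(a); n_b <- sum(b)
  common <- exp(mean(log(eff_lib_sizes)))
  eq <- round(sweep(mat$counts, 2, common / eff_lib_sizes, "*"))
  S_a <- rowSums(eq[, a, drop = FALSE])
  S_b <- rowSums(eq[, b, drop = FALSE])
  S <- S_a + S_b
  tested <- rowMeans(mat$counts) >= min_mean_count
  p <- rep(1, nrow(eq))

  idx <- which(tested & S > 0)
  if (length(idx)) {
    by_total <- split(idx, S[idx])
    for (tot_chr in names(by_total)) {
      tot <- as.numeric(tot_chr)
      pmf <- cond_pmf(tot, n_a, n_b, phi)
      ii <- by_total[[tot_chr]]
      thr <- pmf[S_a[ii] + 1L] * (1 + 1e-12)
      srt <- sort(pmf)
      cs <- cumsum(srt)
      p[ii] <- pmin(1, cs[findInterval(thr, srt)])
    }
  }
  l2fc <- log2((S_a / n_a + 0.5) / (S_b / n_b + 0.5))
  out <- data.frame(mat$windows[c("chrom", "start", "end")],
                    p_value = p, log2_fc = l2fc,
                    mean_disease = S_a / n_a, mean_no_disease = S_b / n_b,
                    tested = tested, stringsAsFactors = FALSE)
  class(out) <- c("window_tests", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false discovery rate adjustment,
#' `q_(i) = min_{j >= i} (m * p_(j) / j)` clipped at 1, returned in the input
#' order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("bh_adjust: p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
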