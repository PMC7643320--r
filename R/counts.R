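#' Tile chromosomes into fixed-width genomic windows
#'
#' Windows are 0-based, half-open, and tile each chromosome without gaps or
#' overlaps; the last window of a chromosome is truncated at the chromosome
#' end.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param window_size window width in bp.
#' @return data.frame with columns `chrom`, `start`, `end`, ordered by
#'   chromosome then position.
#' @examples
#' tile_genome(c(chr1 = 2500), 1000)  # 3 windows, last [2000,2500)
#' @export
tile_genome <- function(chrom_lengths, window_size) {
  if (any(chrom_lengths <= 0) || window_size <= 0)
    stop("tile_genome: lengths and window_size must be positive", call. = FALSE)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  res <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = window_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size, len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Assign reads to genomic windows by midpoint
#'
#' Each read interval (0-based, half-open) is assigned to exactly one window:
#' the one containing its midpoint `floor((start + end) / 2)`, so a midpoint
#' falling on a window boundary belongs to the right-hand window. Reads on
#' chromosomes absent from the window grid are counted as skipped.
#'
#' @param reads data.frame with `chrom`, `start`, `end`.
#' @param windows a [tile_genome()] result (fixed-width grid).
#' @return list with `counts` (integer vector parallel to `windows`) and
#'   `skipped` (number of reads on unknown chromosomes).
#' @export
bin_reads <- function(reads, windows) {
  if (any(reads$start >= reads$end))
    stop("bin_reads: malformed read interval (start >= end)", call. = FALSE)
  counts <- integer(nrow(windows))
  skipped <- 0L
  width <- windows$end[1] - windows$start[1]
  per_chrom <- split(seq_len(nrow(windows)), windows$chrom)
  mid <- (reads$start + reads$end) %/% 2L
  for (ch in unique(reads$chrom)) {
    sel <- reads$chrom == ch
    idx <- per_chrom[[ch]]
    if (is.null(idx)) {
      skipped <- skipped + sum(sel)
      message("bin_reads: skipped ", sum(sel), " reads on unknown chromosome ", ch)
      next
    }
    m <- mid[sel]
    wi <- m %/% width + 1L                       # grid lookup within chromosome
    ok <- wi >= 1L & wi <= length(idx)
    skipped <- skipped + sum(!ok)
    tab <- tabulate(wi[ok], nbins = length(idx))
    counts[idx] <- counts[idx] + tab
  }
  list(counts = counts, skipped = skipped)
}

#' Window-by-sample count matrix container
#'
#' The pipeline's central object: raw read counts over non-overlapping
#' genomic windows for a set of samples split into `"disease"` and
#' `"no_disease"` groups, together with per-sample library sizes and
#' normalization factors (see [tmm_factors()]). Modeled on the light list
#' containers of count-based differential analysis packages.
#'
#' @param counts integer matrix, windows x samples (column names = sample IDs).
#' @param windows data.frame `chrom`, `start`, `end` parallel to rows.
#' @param groups character vector per sample, values in
#'   `c("disease", "no_disease")`.
#' @param lib_sizes per-sample total mapped reads; defaults to column sums.
#' @param norm_factors per-sample scaling factors; default 1.
#' @param cpg optional per-window CpG counts.
#' @return Object of class `window_counts`.
#' @export
window_counts <- function(counts, windows, groups,
                          lib_sizes = colSums(counts),
                          norm_factors = rep(1, ncol(counts)),
                          cpg = NULL) {
  counts <- as.matrix(counts)
  if (nrow(windows) != nrow(counts))
    stop("window_counts: windows and counts disagree on row count", call. = FALSE)
  if (length(groups) != ncol(counts))
    stop("window_counts: one group label per sample required", call. = FALSE)
  if (any(counts < 0)) stop("window_counts: negative counts", call. = FALSE)
  if (!all(groups %in% c("disease", "no_disease")))
    stop("window_counts: groups must be 'disease' or 'no_disease'", call. = FALSE)
  if (any(lib_sizes < colSums(counts) - 1e-8))
    stop("window_counts: library size below column sum", call. = FALSE)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  structure(list(counts = counts,
                 windows = as.data.frame(windows, stringsAsFactors = FALSE),
                 samples = data.frame(sample = colnames(counts),
                                      group = groups,
                                      lib_size = as.numeric(lib_sizes),
                                      norm_factor = as.numeric(norm_factors),
                                      stringsAsFactors = FALSE),
                 cpg = cpg),
            class = "window_counts")
}

#' @export
print.window_counts <- function(x, ...) {
  cat("window_counts:", nrow(x$counts), "windows x", ncol(x$counts),
      "samples (", sum(x$samples$group == "disease"), "disease /",
      sum(x$samples$group == "no_disease"), "no_disease )\n")
  cat("  library sizes:", paste(format(range(x$samples$lib_size)),
                                collapse = " - "), "\n")
  invisible(x)
}

#' @export
dim.window_counts <- function(x) dim(x$counts)

#' RPKM matrix
#'
#' Reads per kilobase of window per million mapped reads:
#' `count / (window_kb * lib_size / 1e6)`.
#'
#' @param mat a [window_counts()] object.
#' @param lib_sizes library sizes to normalize by; defaults to the stored
#'   raw sizes.
#' @return numeric matrix of the same shape as `mat$counts`.
#' @export
rpkm_matrix <- function(mat, lib_sizes = mat$samples$lib_size) {
  if (any(lib_sizes <= 0))
    stop("rpkm_matrix: zero or negative library size", call. = FALSE)
  kb <- (mat$windows$end - mat$windows$start) / 1000
  sweep(mat$counts / kb, 2, lib_sizes / 1e6, "/")
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Computes per-sample scaling factors from raw counts by a trimmed mean of
#' M-values (log2 ratios) against a reference sample: windows with a zero in
#' either sample are dropped, the 30% most extreme M-values and 5% most
#' extreme A-values (average log2 abundance) are trimmed, and the factor is
#' `2^trimmed_mean(M)`. The reference is the sample whose upper-quartile
#' count is closest to the mean upper quartile; factors are normalized to
#' geometric mean 1. Because the M-values are taken on raw (not
#' depth-adjusted) counts, the factors absorb sequencing-depth differences
#' as well as composition bias: duplicating a sample's counts doubles its
#' factor relative to the rest.
#'
#' @param mat a [window_counts()] object (>= 2 samples).
#' @param trim_m,trim_a total trimmed fractions of M- and A-values.
#' @return numeric vector of factors, one per sample, geometric mean 1.
#' @seealso [effective_lib_sizes()]
#' @export
tmm_factors <- function(mat, trim_m = 0.3, trim_a = 0.05) {
  x <- mat$counts
  if (ncol(x) < 2) stop("tmm_factors: >= 2 samples required", call. = FALSE)
  zero <- colSums(x) == 0
  if (any(zero))
    stop("tmm_factors: sample(s) with all-zero counts: ",
         paste(colnames(x)[zero], collapse = ", "), call. = FALSE)
  uq <- apply(x, 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(x)), function(j) {
    if (j == ref) return(1)
    ok <- x[, j] > 0 & x[, ref] > 0
    if (!any(ok)) return(1)
    m <- log2(x[ok, j] / x[ok, ref])
    a <- 0.5 * log2(as.numeric(x[ok, j]) * x[ok, ref])
    keep_m <- m >= stats::quantile(m, trim_m / 2) &
      m <= stats::quantile(m, 1 - trim_m / 2)
    keep_a <- a >= stats::quantile(a, trim_a / 2) &
      a <= stats::quantile(a, 1 - trim_a / 2)
    keep <- keep_m & keep_a
    if (!any(keep)) keep <- keep_m
    2^mean(m[keep])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(x)
  f
}

#' Effective library sizes
#'
#' The scaling used for count equalization in the exact test. With
#' `method = "tmm"` the TMM factors already carry depth differences (they are
#' computed on raw counts), so the effective size of sample *s* is the
#' geometric-mean raw library size times its factor; with
#' `method = "total-count"` the raw library sizes are used unchanged.
#'
#' @param mat a [window_counts()] object.
#' @param method `"tmm"` (default) or `"total-count"`.
#' @return numeric vector of effective sizes per sample.
#' @export
effective_lib_sizes <- function(mat, method = c("tmm", "total-count")) {
  method <- match.arg(method)
  L <- mat$samples$lib_size
  if (method == "total-count") return(stats::setNames(L, mat$samples$sample))
  f <- tmm_factors(mat)
  stats::setNames(exp(mean(log(L))) * f, mat$samples$sample)
}
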