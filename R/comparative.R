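#' Overlapping interval pairs between two DMR sets
#'
#' Two DMRs overlap when their intervals share at least one bp (half-open
#' semantics; a DMR ending at 2000 does not overlap one starting at 2000).
#' An optional minimum-overlap fraction of the smaller interval can tighten
#' the rule.
#'
#' @param set_a,set_b data.frames with `chrom`, `start`, `stop` (or `end`),
#'   each sorted and internally disjoint.
#' @param min_fraction minimum shared fraction of the shorter interval
#'   (default 0 = any shared bp).
#' @return data.frame `a`, `b` of row indices of overlapping pairs.
#' @export
interval_overlap <- function(set_a, set_b, min_fraction = 0) {
  check_sorted_set(set_a, "set_a")
  check_sorted_set(set_b, "set_b")
  if (nrow(set_a) == 0L || nrow(set_b) == 0L)
    return(data.frame(a = integer(0), b = integer(0)))
  sq <- union(set_a$chrom, set_b$chrom)
  gr_a <- as_granges(set_a, seqlevels = sq)
  gr_b <- as_granges(set_b, seqlevels = sq)
  h <- GenomicRanges::findOverlaps(gr_a, gr_b)
  out <- data.frame(a = S4Vectors::queryHits(h), b = S4Vectors::subjectHits(h))
  if (min_fraction > 0 && nrow(out)) {
    ov <- GenomicRanges::width(IRanges::pintersect(gr_a[out$a], gr_b[out$b]))
    shorter <- pmin(GenomicRanges::width(gr_a[out$a]),
                    GenomicRanges::width(gr_b[out$b]))
    out <- out[ov / shorter >= min_fraction, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

check_sorted_set <- function(s, what) {
  end <- if ("stop" %in% names(s)) s$stop else s$end
  if (nrow(s) < 2) return(invisible(TRUE))
  o <- order(s$chrom, s$start)
  if (!identical(o, seq_len(nrow(s))))
    stop("interval sets must be sorted (", what, ")", call. = FALSE)
  same <- s$chrom[-1] == s$chrom[-nrow(s)]
  if (any(same & s$start[-1] < end[-nrow(s)]))
    stop("intervals within ", what, " must be disjoint", call. = FALSE)
  invisible(TRUE)
}

#' Venn region counts for 2-4 DMR sets
#'
#' Each DMR of each set is assigned a membership signature by interval
#' overlap against every other set; because the sets have different
#' cardinalities a shared "element" is an overlap relation, not a merged
#' interval, so region counts are reported per set: for each set, the number
#' of its DMRs falling in each region of its own partition. Per set, the
#' region counts sum to the set's cardinality.
#'
#' @param sets named list of 2-4 DMR data.frames.
#' @param min_fraction passed to [interval_overlap()].
#' @return data.frame `set`, `region` (e.g. `"kidney&prostate"`), `count`.
#' @export
venn_counts <- function(sets, min_fraction = 0) {
  k <- length(sets)
  if (k < 2 || k > 4)
    stop("venn_counts: 2-4 sets supported", call. = FALSE)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_len(k))
  out <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    n <- nrow(s)
    member <- matrix(FALSE, nrow = n, ncol = k,
                     dimnames = list(NULL, names(sets)))
    member[, nm] <- TRUE
    for (other in setdiff(names(sets), nm)) {
      ov <- interval_overlap(s, sets[[other]], min_fraction)
      member[unique(ov$a), other] <- TRUE
    }
    if (n == 0L)
      return(data.frame(set = character(0), region = character(0),
                        count = integer(0)))
    sig <- apply(member, 1, function(r)
      paste(names(sets)[r], collapse = "&"))
    tab <- table(sig)
    data.frame(set = nm, region = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Extended overlap of a strict DMR set against a relaxed set
#'
#' Counts how many DMRs of a strict (seed-threshold) set overlap the other
#' comparison's DMRs assembled at a relaxed threshold, and the percentage of
#' the strict set this represents. Comparing a set against its own relaxed
#' assembly yields 100% by construction, the expected diagonal of the
#' extended-overlap matrix.
#'
#' @param strict_set DMR data.frame at the seed threshold.
#' @param relaxed_set DMR data.frame of the other comparison at the relaxed
#'   threshold (e.g. assembled with `seed_threshold = 0.05`).
#' @param min_fraction passed to [interval_overlap()].
#' @return list `n_overlap`, `n_total`, `percent` (`NA` if the strict set is
#'   empty).
#' @export
extended_overlap <- function(strict_set, relaxed_set, min_fraction = 0) {
  n <- nrow(strict_set)
  if (n == 0L) return(list(n_overlap = 0L, n_total = 0L, percent = NA_real_))
  ov <- interval_overlap(strict_set, relaxed_set, min_fraction)
  n_ov <- length(unique(ov$a))
  list(n_overlap = n_ov, n_total = n, percent = 100 * n_ov / n)
}

#' Common core of intervals shared by all sets
#'
#' Intervals of the first set that overlap every other set, optionally
#' re-checked against a second family of (strict) sets.
#'
#' @param sets named list of >= 2 DMR data.frames (typically at a relaxed
#'   threshold).
#' @param strict_sets optional list of strict sets; core intervals are kept
#'   only if they also overlap every strict set.
#' @param min_fraction passed to [interval_overlap()].
#' @return subset of the first set's rows forming the core.
#' @export
common_core <- function(sets, strict_sets = NULL, min_fraction = 0) {
  if (length(sets) < 2) stop("common_core: >= 2 sets required", call. = FALSE)
  base <- sets[[1]]
  keep <- rep(TRUE, nrow(base))
  for (other in sets[-1]) {
    ov <- interval_overlap(base, other, min_fraction)
    keep <- keep & seq_len(nrow(base)) %in% ov$a
  }
  core <- base[keep, , drop = FALSE]
  if (!is.null(strict_sets) && nrow(core)) {
    keep2 <- rep(TRUE, nrow(core))
    for (s in strict_sets) {
      ov <- interval_overlap(core, s, min_fraction)
      keep2 <- keep2 & seq_len(nrow(core)) %in% ov$a
    }
    core <- core[keep2, , drop = FALSE]
  }
  rownames(core) <- NULL
  core
}

#' PCA of RPKM depths at DMR windows
#'
#' Samples are the observations; window features are centered (no scaling by
#' default, RPKM being already depth-normalized). Coordinates come from the
#' two leading singular directions; the sign of each component is fixed by
#' forcing its largest-magnitude loading positive.
#'
#' @param rpkm numeric matrix, windows x samples.
#' @param groups character vector of per-sample labels.
#' @param scale. scale features to unit variance (default `FALSE`).
#' @return list of class `dmr_pca`: `coords` (data.frame `sample`, `group`,
#'   `PC1`, `PC2`), `var_explained` (length-2 fractions).
#' @export
pca_rpkm <- function(rpkm, groups, scale. = FALSE) {
  if (ncol(rpkm) < 2 || nrow(rpkm) < 2)
    stop("pca_rpkm: need >= 2 samples and >= 2 windows", call. = FALSE)
  x <- t(rpkm)                                # samples x features
  keep_var <- apply(x, 2, stats::var) > 0
  if (!any(keep_var)) {
    warning("pca_rpkm: constant matrix, coordinates set to zero")
    coords <- data.frame(sample = colnames(rpkm) %||% seq_len(ncol(rpkm)),
                         group = groups, PC1 = 0, PC2 = 0)
    return(structure(list(coords = coords, var_explained = c(0, 0)),
                     class = "dmr_pca"))
  }
  pc <- stats::prcomp(x[, keep_var, drop = FALSE], center = TRUE,
                      scale. = scale.)
  for (j in 1:2) {
    if (j > ncol(pc$rotation)) break
    flip <- sign(pc$rotation[which.max(abs(pc$rotation[, j])), j])
    if (flip < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  get_pc <- function(j) if (j <= ncol(pc$x)) pc$x[, j] else rep(0, nrow(x))
  coords <- data.frame(sample = colnames(rpkm) %||% seq_len(ncol(rpkm)),
                       group = groups, PC1 = get_pc(1), PC2 = get_pc(2),
                       stringsAsFactors = FALSE)
  rownames(coords) <- NULL
  structure(list(coords = coords,
                 var_explained = c(ve[1], if (length(ve) > 1) ve[2] else 0)),
            class = "dmr_pca")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dmr_pca <- function(x, ...) {
  cat("PCA of RPKM at DMR windows:", nrow(x$coords), "samples; PC1/PC2",
      "explain", paste(sprintf("%.1f%%", 100 * x$var_explained),
                       collapse = " / "), "\n")
  invisible(x)
}

#' Mean silhouette of group labels on PC1/PC2
#'
#' Measures how well samples separate by group in the first two principal
#' components; positive values indicate clustering by label.
#'
#' @param pca a [pca_rpkm()] result.
#' @return mean silhouette width (numeric).
#' @export
pca_group_silhouette <- function(pca) {
  cl <- as.integer(factor(pca$coords$group))
  if (length(unique(cl)) < 2)
    stop("pca_group_silhouette: >= 2 groups required", call. = FALSE)
  d <- stats::dist(pca$coords[, c("PC1", "PC2")])
  mean(cluster::silhouette(cl, d)[, "sil_width"])
}
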