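#' Select significant seed windows
#'
#' Tested windows with `p < seed_threshold` (strict inequality; ties at the
#' threshold are excluded).
#'
#' @param results a [test_all_windows()] data.frame, ordered by position.
#' @param seed_threshold seed p-value cutoff.
#' @return integer row indices of seed windows.
#' @export
seed_select <- function(results, seed_threshold) {
  which(results$tested & results$p_value < seed_threshold)
}

# validate that windows are sorted and non-overlapping per chromosome
check_window_order <- function(results) {
  ord <- order(results$chrom, results$start)
  if (!identical(ord, seq_len(nrow(results))))
    stop("assemble_dmrs: windows must be sorted by chromosome and start",
         call. = FALSE)
  by_ch <- split(seq_len(nrow(results)), results$chrom)
  for (idx in by_ch) {
    if (length(idx) > 1 &&
        any(results$start[idx][-1] < results$end[idx][-length(idx)]))
      stop("assemble_dmrs: overlapping windows", call. = FALSE)
  }
  invisible(TRUE)
}

#' Assemble DMRs by seed-and-extend
#'
#' Initializes one region per maximal run of adjacent seed windows
#' (`p < seed_threshold`), then iterates to a fixed point: any tested window
#' with `p < extend_threshold` whose whole span lies within `reach` bp of a
#' region's current edge is absorbed, extending the edge; regions that come
#' to touch or overlap are merged. On a 1 kb grid with `reach = 1000` only
#' windows adjacent to a region qualify, so a single window with
#' `p >= extend_threshold` blocks further extension. Untested (low-coverage)
#' windows behave as `p = 1` and block extension. Absorbed extension windows
#' widen the reported interval but do not count toward
#' `n_significant_windows`, which tallies member windows at the seed
#' threshold only.
#'
#' @param results a [test_all_windows()] data.frame (sorted, non-overlapping
#'   windows tiling each chromosome).
#' @param seed_threshold strict seed cutoff (default 1e-4).
#' @param extend_threshold strict extension cutoff (default 0.1).
#' @param reach extension reach in bp (default 1000).
#' @param genome optional [simulate_genome()] model (or any list with a
#'   `windows` data.frame carrying `chrom`, `start`, `cpg`) used to attach
#'   CpG counts.
#' @return data.frame of class `dmr_set`: `name`, `chrom`, `start`, `stop`,
#'   `length`, `n_significant_windows`, `min_p`, `max_log2_fc` (signed value
#'   of largest magnitude among member windows), `cpg_number`, `cpg_density`
#'   (per 100 bp; `NA` without CpG information), sorted and pairwise
#'   disjoint.
#' @export
assemble_dmrs <- function(results, seed_threshold = 1e-4,
                          extend_threshold = 0.1, reach = 1000,
                          genome = NULL) {
  stopifnot(seed_threshold > 0, seed_threshold <= 1,
            extend_threshold > 0, extend_threshold <= 1, reach >= 0)
  check_window_order(results)
  empty <- data.frame(name = character(0), chrom = character(0),
                      start = numeric(0), stop = numeric(0),
                      length = numeric(0), n_significant_windows = integer(0),
                      min_p = numeric(0), max_log2_fc = numeric(0),
                      cpg_number = numeric(0), cpg_density = numeric(0),
                      stringsAsFactors = FALSE)
  seeds <- seed_select(results, seed_threshold)
  if (length(seeds) == 0L)
    return(structure(empty, class = c("dmr_set", "data.frame")))

  cpg <- attach_cpg(results, genome)
  ext_ok <- results$tested & results$p_value < extend_threshold

  out <- lapply(split(seq_len(nrow(results)), results$chrom), function(idx) {
    s <- intersect(seeds, idx)
    if (length(s) == 0L) return(NULL)
    loc <- match(s, idx)                    # positions within the chromosome
    runs <- split(loc, cumsum(c(1L, diff(loc) != 1L)))
    # regions as [first, last] window positions on this chromosome
    reg <- do.call(rbind, lapply(runs, function(r) c(min(r), max(r))))
    ext <- which(ext_ok[idx])
    start_bp <- results$start[idx]; end_bp <- results$end[idx]
    repeat {
      changed <- FALSE
      for (k in seq_len(nrow(reg))) {
        # extend left
        repeat {
          cand <- reg[k, 1] - 1L
          if (cand < 1L || !(cand %in% ext)) break
          if (start_bp[reg[k, 1]] - start_bp[cand] > reach) break
          reg[k, 1] <- cand; changed <- TRUE
        }
        # extend right
        repeat {
          cand <- reg[k, 2] + 1L
          if (cand > length(idx) || !(cand %in% ext)) break
          if (end_bp[cand] - end_bp[reg[k, 2]] > reach) break
          reg[k, 2] <- cand; changed <- TRUE
        }
      }
      # merge touching/overlapping regions
      o <- order(reg[, 1])
      reg <- reg[o, , drop = FALSE]
      merged <- reg[1, , drop = FALSE]
      for (k in seq_len(nrow(reg))[-1]) {
        last <- nrow(merged)
        if (reg[k, 1] <= merged[last, 2] + 1L) {
          if (reg[k, 2] > merged[last, 2]) merged[last, 2] <- reg[k, 2]
        } else merged <- rbind(merged, reg[k, , drop = FALSE])
      }
      if (nrow(merged) < nrow(reg)) changed <- TRUE
      reg <- merged
      if (!changed) break
    }
    do.call(rbind, lapply(seq_len(nrow(reg)), function(k) {
      members <- idx[reg[k, 1]:reg[k, 2]]
      summarize_dmr(members, results, cpg, seed_threshold)
    }))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$n_significant_windows <- as.integer(out$n_significant_windows)
  rownames(out) <- NULL
  structure(out, class = c("dmr_set", "data.frame"))
}

# per-window CpG counts aligned to `results` rows, or NULL
attach_cpg <- function(results, genome) {
  if (is.null(genome)) return(NULL)
  gw <- genome$windows
  key_r <- paste(results$chrom, results$start)
  key_g <- paste(gw$chrom, gw$start)
  gw$cpg[match(key_r, key_g)]
}

#' Summarize one DMR from its member windows
#'
#' @param members row indices (into `results`) of the DMR's member windows.
#' @param results a [test_all_windows()] data.frame.
#' @param cpg optional per-window CpG counts parallel to `results`.
#' @param seed_threshold seed cutoff used for the significant-window tally.
#' @return one-row data.frame with the DMR summary record (see
#'   [assemble_dmrs()]).
#' @export
summarize_dmr <- function(members, results, cpg = NULL,
                          seed_threshold = 1e-4) {
  if (length(members) == 0L)
    stop("summarize_dmr: empty member set", call. = FALSE)
  p <- results$p_value[members]
  fc <- results$log2_fc[members]
  start <- min(results$start[members]); stop <- max(results$end[members])
  n_cpg <- if (is.null(cpg)) NA_real_ else sum(cpg[members])
  data.frame(name = paste0(results$chrom[members[1]], ":", start),
             chrom = results$chrom[members[1]],
             start = start, stop = stop, length = stop - start,
             n_significant_windows =
               sum(results$tested[members] & p < seed_threshold),
             min_p = min(p),
             max_log2_fc = fc[which.max(abs(fc))],
             cpg_number = n_cpg,
             cpg_density = 100 * n_cpg / (stop - start),
             stringsAsFactors = FALSE)
}

#' @export
print.dmr_set <- function(x, ...) {
  cat("dmr_set:", nrow(x), "DMRs (",
      sum(x$n_significant_windows >= 2), "with >= 2 significant windows )\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  invisible(x)
}

#' Sweep DMR counts over seed thresholds
#'
#' Runs the full seed-and-extend assembly at each threshold and records the
#' number of DMRs overall ("all window") and the number containing at least
#' two windows significant at the seed threshold ("multiple window").
#'
#' @param results a [test_all_windows()] data.frame.
#' @param thresholds seed thresholds, sorted descending (default
#'   `1e-2 ... 1e-7`).
#' @param ... passed to [assemble_dmrs()].
#' @return data.frame `threshold`, `all_window`, `multiple_window`.
#' @export
threshold_sweep <- function(results, thresholds = 10^-(2:7), ...) {
  if (is.unsorted(rev(thresholds)))
    stop("threshold_sweep: thresholds must be sorted descending", call. = FALSE)
  rows <- lapply(thresholds, function(th) {
    d <- assemble_dmrs(results, seed_threshold = th, ...)
    data.frame(threshold = th, all_window = nrow(d),
               multiple_window = sum(d$n_significant_windows >= 2))
  })
  do.call(rbind, rows)
}

#' Classify DMR methylation direction
#'
#' Direction is the sign of the DMR's maximal-magnitude log2 fold change
#' (disease over no-disease): positive = increased methylation ("hyper").
#' DMRs with a zero fold change get direction `"none"` and are excluded from
#' the hyper-fraction denominator.
#'
#' @param dmrs a [assemble_dmrs()] result.
#' @return list with `direction` (character per DMR) and `hyper_fraction`
#'   (`NA` if no directed DMRs).
#' @export
classify_direction <- function(dmrs) {
  if (nrow(dmrs) == 0L)
    return(list(direction = character(0), hyper_fraction = NA_real_))
  dir <- ifelse(dmrs$max_log2_fc > 0, "hyper",
                ifelse(dmrs$max_log2_fc < 0, "hypo", "none"))
  n_dir <- sum(dir != "none")
  list(direction = dir,
       hyper_fraction = if (n_dir == 0) NA_real_ else
         sum(dir == "hyper") / n_dir)
}
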