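#' Simulation configuration for synthetic MeDIP-seq window counts
#'
#' Bundles every parameter of the synthetic-data generator: genome geometry,
#' group sizes, the negative binomial count model (variance = mu + phi * mu^2),
#' library-size variation, and the planted epimutations. The defaults describe
#' a desk-scale study: two chromosomes of 10,000 non-overlapping 1 kb windows,
#' 8 diseased vs 8 non-diseased samples, a baseline depth of 50 reads per
#' window (about one million reads per sample over a 20 Mb genome), mild
#' overdispersion (phi = 0.1), and 20 planted three-window regions at a
#' four-fold (|log2 FC| = 2) methylation difference.
#'
#' @param n_chromosomes number of chromosomes.
#' @param windows_per_chromosome number of windows tiling each chromosome.
#' @param window_size window width in bp.
#' @param n_disease,n_control samples per group.
#' @param baseline_mean expected reads per window for an average library.
#' @param dispersion negative binomial dispersion phi >= 0 (0 = Poisson).
#' @param libsize_factor_sd standard deviation, on the log scale, of the
#'   lognormal per-sample depth factors.
#' @param n_dmrs number of planted differentially methylated regions.
#' @param dmr_span windows per planted region.
#' @param effect_log2 planted |log2 fold change| (disease over control).
#' @param cpg_rate expected CpG dinucleotides per 100 bp.
#' @param seed integer RNG seed; every stage derives its stream from it.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, windows_per_chromosome = 100)
#' @export
sim_config <- function(n_chromosomes = 2L, windows_per_chromosome = 10000L,
                       window_size = 1000L, n_disease = 8L, n_control = 8L,
                       baseline_mean = 50, dispersion = 0.1,
                       libsize_factor_sd = 0.1, n_dmrs = 20L, dmr_span = 3L,
                       effect_log2 = 2, cpg_rate = 2, seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              windows_per_chromosome = as.integer(windows_per_chromosome),
              window_size = as.integer(window_size),
              n_disease = as.integer(n_disease),
              n_control = as.integer(n_control),
              baseline_mean = as.numeric(baseline_mean),
              dispersion = as.numeric(dispersion),
              libsize_factor_sd = as.numeric(libsize_factor_sd),
              n_dmrs = as.integer(n_dmrs), dmr_span = as.integer(dmr_span),
              effect_log2 = as.numeric(effect_log2),
              cpg_rate = as.numeric(cpg_rate), seed = as.integer(seed))
  pos <- c("n_chromosomes", "windows_per_chromosome", "window_size",
           "n_disease", "n_control", "baseline_mean", "libsize_factor_sd",
           "dmr_span", "cpg_rate")
  for (f in pos)
    if (is.na(cfg[[f]]) || cfg[[f]] <= 0)
      stop("sim_config: '", f, "' must be strictly positive", call. = FALSE)
  if (is.na(cfg$dispersion) || cfg$dispersion < 0)
    stop("sim_config: 'dispersion' must be >= 0", call. = FALSE)
  if (is.na(cfg$n_dmrs) || cfg$n_dmrs < 0)
    stop("sim_config: 'n_dmrs' must be >= 0", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# deterministic per-stage sub-stream (kept well below .Machine$integer.max)
stage_seed <- function(config, offset) {
  (config$seed %% 1000000L) * 1000L + offset
}

#' Generate a synthetic genome model
#'
#' Builds a window grid tiling `n_chromosomes` chromosomes and draws a CpG
#' dinucleotide count for each window (Poisson around
#' `cpg_rate * window_size / 100`, capped at the geometric maximum of one CpG
#' per 2 bp). The model stands in for a real reference genome in downstream
#' CpG-density summaries.
#'
#' @param config a [sim_config()].
#' @return An object of class `genome_model`: list with `chrom_lengths`
#'   (named vector, bp) and `windows` (data.frame `chrom`, `start`, `end`,
#'   `cpg`, 0-based half-open coordinates).
#' @seealso [plant_epimutations()], [simulate_window_counts()],
#'   [write_genome_fasta()]
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, 1L))
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  len <- config$windows_per_chromosome * config$window_size
  chrom_lengths <- stats::setNames(rep(len, config$n_chromosomes), chroms)
  windows <- tile_genome(chrom_lengths, config$window_size)
  cpg_mean <- config$cpg_rate * config$window_size / 100
  cpg <- stats::rpois(nrow(windows), cpg_mean)
  cpg <- pmin(cpg, config$window_size %/% 2L)
  windows$cpg <- cpg
  structure(list(chrom_lengths = chrom_lengths, windows = windows,
                 window_size = config$window_size),
            class = "genome_model")
}

#' Plant differentially methylated regions into a genome model
#'
#' Chooses `n_dmrs` non-overlapping runs of `dmr_span` consecutive windows,
#' aligned to the window grid, and assigns each a direction. Exactly half
#' (rounded down) of the regions are hypermethylated in the disease group and
#' the rest hypomethylated, shuffled at random, emulating the roughly even
#' split of methylation gains and losses seen among disease-associated sperm
#' DMRs.
#'
#' @param genome a [simulate_genome()] result.
#' @param config the matching [sim_config()].
#' @return Object of class `truth_set`: data.frame with `chrom`, `start`,
#'   `end` (bp, 0-based half-open), `effect_log2` (signed) and `direction`
#'   (`"hyper"`/`"hypo"`).
#' @export
plant_epimutations <- function(genome, config) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "sim_config"))
  set.seed(stage_seed(config, 2L))
  w <- genome$windows
  n <- config$n_dmrs
  span <- config$dmr_span
  out <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                    effect_log2 = numeric(0), direction = character(0),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(structure(out, class = c("truth_set", "data.frame")))

  # candidate start windows: runs of `span` windows within one chromosome
  per_chrom <- split(seq_len(nrow(w)), w$chrom)
  starts <- unlist(lapply(per_chrom, function(idx) {
    if (length(idx) < span) integer(0) else idx[seq_len(length(idx) - span + 1L)]
  }), use.names = FALSE)
  if (n * span > nrow(w) || length(starts) < n)
    stop("plant_epimutations: genome too small for ", n, " regions of ",
         span, " windows", call. = FALSE)

  chosen <- integer(0)
  avail <- starts
  for (i in seq_len(n)) {
    if (length(avail) == 0L)
      stop("plant_epimutations: could not place ", n,
           " non-overlapping regions", call. = FALSE)
    pick <- avail[sample.int(length(avail), 1L)]
    chosen <- c(chosen, pick)
    # drop candidates whose span would overlap the placed region
    avail <- avail[abs(avail - pick) >= span |
                     w$chrom[avail] != w$chrom[pick]]
  }
  chosen <- sort(chosen)
  dir <- rep("hypo", n)
  dir[sample.int(n, n %/% 2L)] <- "hyper"
  out <- data.frame(chrom = w$chrom[chosen], start = w$start[chosen],
                    end = w$end[chosen + span - 1L],
                    effect_log2 = ifelse(dir == "hyper", 1, -1) * config$effect_log2,
                    direction = dir, stringsAsFactors = FALSE)
  structure(out[order(out$chrom, out$start), , drop = FALSE],
            class = c("truth_set", "data.frame"))
}

#' Simulate a MeDIP-seq-like window count matrix
#'
#' Draws per-window, per-sample read counts from a negative binomial model,
#' `count ~ NB(mean = baseline_mean * f_s * 2^(d * effect), dispersion phi)`
#' with variance `mu + phi mu^2`; `f_s` is the sample's lognormal depth
#' factor and the signed effect applies only to planted windows in diseased
#' samples. `dispersion = 0` gives the Poisson limit.
#'
#' @param genome a [simulate_genome()] result.
#' @param truth a [plant_epimutations()] result (may be empty).
#' @param config the matching [sim_config()].
#' @return A [window_counts()] object with group labels
#'   `"disease"` / `"no_disease"`.
#' @export
simulate_window_counts <- function(genome, truth, config) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "sim_config"))
  set.seed(stage_seed(config, 3L))
  w <- genome$windows
  nw <- nrow(w)
  ns <- config$n_disease + config$n_control
  groups <- c(rep("disease", config$n_disease),
              rep("no_disease", config$n_control))
  ids <- c(sprintf("D%02d", seq_len(config$n_disease)),
           sprintf("N%02d", seq_len(config$n_control)))
  libfac <- exp(stats::rnorm(ns, 0, config$libsize_factor_sd))

  effect <- numeric(nw)   # signed log2 effect per window
  if (nrow(truth) > 0L) {
    for (i in seq_len(nrow(truth)))
      effect[w$chrom == truth$chrom[i] & w$start >= truth$start[i] &
               w$end <= truth$end[i]] <- truth$effect_log2[i]
  }
  counts <- matrix(0L, nrow = nw, ncol = ns,
                   dimnames = list(NULL, ids))
  for (s in seq_len(ns)) {
    mu <- config$baseline_mean * libfac[s] *
      (if (groups[s] == "disease") 2^effect else rep(1, nw))
    counts[, s] <- if (config$dispersion == 0)
      stats::rpois(nw, mu)
    else
      stats::rnbinom(nw, mu = mu, size = 1 / config$dispersion)
  }
  window_counts(counts = counts, windows = w[c("chrom", "start", "end")],
                groups = groups, cpg = w$cpg)
}

#' Write a genome model as FASTA
#'
#' Materializes a nucleotide sequence consistent with the model's per-window
#' CpG counts: each window is an A/T background with its `cpg` CpG
#' dinucleotides placed at evenly spaced positions, so re-counting CG
#' dinucleotides in the written sequence reproduces the model exactly.
#'
#' @param genome a [simulate_genome()] result.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "genome_model"))
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("write_genome_fasta requires the Biostrings package", call. = FALSE)
  ws <- genome$window_size
  seqs <- vapply(names(genome$chrom_lengths), function(ch) {
    w <- genome$windows[genome$windows$chrom == ch, , drop = FALSE]
    paste(vapply(seq_len(nrow(w)), function(i) {
      n <- w$end[i] - w$start[i]
      k <- w$cpg[i]
      base <- rep(c("A", "T"), length.out = n)
      if (k > 0) {
        # CpGs at stride >= 2 so no accidental CG forms at junctions
        pos <- floor(seq(1, n - 1, length.out = k))
        base[pos] <- "C"; base[pos + 1] <- "G"
      }
      paste(base, collapse = "")
    }, character(1)), collapse = "")
  }, character(1))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(genome$chrom_lengths)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_chromosomes, "chr x",
      x$windows_per_chromosome, "windows of", x$window_size, "bp;",
      x$n_disease, "disease vs", x$n_control, "control;\n  NB mean",
      x$baseline_mean, "phi", x$dispersion, ";", x$n_dmrs, "planted DMRs of",
      x$dmr_span, "windows at |log2FC|", x$effect_log2,
      "; seed", x$seed, "\n")
  invisible(x)
}

#' @export
print.truth_set <- function(x, ...) {
  cat("Truth set:", nrow(x), "planted regions (",
      sum(x$direction == "hyper"), "hyper /",
      sum(x$direction == "hypo"), "hypo )\n")
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}
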