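#' Run the full synthetic EWAS pipeline
#'
#' Chains every stage on synthetic data: simulate (genome, planted
#' epimutations, counts) -> normalize -> per-window exact tests -> DMR
#' assembly and threshold sweep -> genomic context (histograms, clusters,
#' gene association when an annotation is supplied) -> comparative (RPKM PCA
#' at DMR windows) -> outputs. Every file is a plain-text TSV/BED/JSON and a
#' rerun with the same config reproduces them byte-identically; a manifest
#' records the configuration echo and per-stage row counts.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if missing).
#' @param seed_threshold,extend_threshold,reach DMR assembly parameters.
#' @param sweep_thresholds seed thresholds for the sweep table.
#' @param annotation optional gene annotation data.frame (`gene`, `chrom`,
#'   `start`, `end`) for the context stage.
#' @param categories optional gene-category mapping (`gene`, `category`).
#' @param min_mean_count coverage floor for testing.
#' @return invisibly, a list with the in-memory stage results (`genome`,
#'   `truth`, `counts`, `dispersion`, `results`, `dmrs`, `sweep`, `pca`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, outdir,
                         seed_threshold = 1e-4, extend_threshold = 0.1,
                         reach = 1000, sweep_thresholds = 10^-(2:7),
                         annotation = NULL, categories = NULL,
                         min_mean_count = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(annotation) && !is.data.frame(annotation))
    stop("run_pipeline: annotation must be a data.frame", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("epidmr")),
                   config = unclass(config),
                   parameters = list(seed_threshold = seed_threshold,
                                     extend_threshold = extend_threshold,
                                     reach_bp = reach,
                                     min_mean_count = min_mean_count,
                                     overlap_rule = ">=1bp",
                                     gene_distance_bp = 10000),
                   stages = list())
  mark <- function(stage, n) manifest$stages[[stage]] <<- list(rows = n)

  genome <- simulate_genome(config)
  truth <- plant_epimutations(genome, config)
  write_bed(truth, file.path(outdir, "truth.bed"),
            score = abs(truth$effect_log2))
  mark("simulate_genome", nrow(genome$windows))
  mark("plant_epimutations", nrow(truth))

  counts <- simulate_window_counts(genome, truth, config)
  write_counts_tsv(counts, file.path(outdir, "counts.tsv"))
  write_groups_tsv(counts, file.path(outdir, "groups.tsv"))
  mark("simulate_window_counts", nrow(counts$counts))

  eff <- effective_lib_sizes(counts)
  utils::write.table(
    data.frame(sample = names(eff), factor = tmm_factors(counts),
               effective_lib_size = as.numeric(eff)),
    file.path(outdir, "norm_factors.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  disp <- estimate_common_dispersion(counts, min_mean_count, eff)
  results <- test_all_windows(counts, disp, min_mean_count, eff)
  write_window_results(results, file.path(outdir, "windows.tsv"))
  mark("test_all_windows", sum(results$tested))

  dmrs <- assemble_dmrs(results, seed_threshold, extend_threshold, reach,
                        genome = genome)
  utils::write.table(as.data.frame(dmrs), file.path(outdir, "dmrs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(dmrs, file.path(outdir, "dmrs.bed"),
            score = round(-log10(dmrs$min_p), 3))
  sweep <- threshold_sweep(results, sweep_thresholds,
                           extend_threshold = extend_threshold, reach = reach)
  utils::write.table(sweep, file.path(outdir, "threshold_sweep.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mark("assemble_dmrs", nrow(dmrs))

  utils::write.table(cpg_density_histogram(dmrs),
                     file.path(outdir, "cpg_density_histogram.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(length_histogram(dmrs),
                     file.path(outdir, "length_histogram.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  clusters <- find_dmr_clusters(dmrs)
  write_bed(clusters, file.path(outdir, "dmr_clusters.bed"))
  if (!is.null(annotation)) {
    dmrs_g <- associate_genes(dmrs, annotation)
    utils::write.table(as.data.frame(dmrs_g)[c("name", "genes")],
                       file.path(outdir, "dmr_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(categories))
      utils::write.table(categorize_genes(dmrs_g$genes, categories),
                         file.path(outdir, "gene_categories.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  mark("genomic_context", nrow(clusters))

  pca <- NULL
  if (nrow(dmrs) > 0) {
    at_dmr <- overlaps_any(results, dmrs)
    if (sum(at_dmr) >= 2) {
      rp <- rpkm_matrix(counts)[at_dmr, , drop = FALSE]
      pca <- pca_rpkm(rp, counts$samples$group)
      utils::write.table(pca$coords, file.path(outdir, "pca_coords.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  mark("comparative", if (is.null(pca)) 0L else nrow(pca$coords))

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(genome = genome, truth = truth, counts = counts,
                 dispersion = disp, results = results, dmrs = dmrs,
                 sweep = sweep, pca = pca, manifest = manifest))
}

# logical: which windows of `results` fall inside any interval of `set`
overlaps_any <- function(results, set) {
  if (nrow(set) == 0) return(rep(FALSE, nrow(results)))
  sq <- union(results$chrom, set$chrom)
  w <- GenomicRanges::GRanges(factor(results$chrom, levels = sq),
                              IRanges::IRanges(results$start + 1L,
                                               results$end))
  s <- as_granges(set, seqlevels = sq)
  GenomicRanges::countOverlaps(w, s) > 0
}

#' Compare planted truth with recovered DMRs
#'
#' Matches recovered DMRs to planted regions by reciprocal interval overlap:
#' a pair matches when the shared span is at least `fraction` of both
#' intervals. Reports sensitivity (planted regions recovered) and precision
#' (recovered DMRs matching a planted region).
#'
#' @param truth a [plant_epimutations()] truth set.
#' @param dmrs a [assemble_dmrs()] result.
#' @param fraction reciprocal overlap fraction (default 0.5).
#' @return list `sensitivity`, `precision`, `n_truth`, `n_called`,
#'   `matched_truth`, `matched_called`.
#' @export
dmr_recovery <- function(truth, dmrs, fraction = 0.5) {
  n_t <- nrow(truth); n_c <- nrow(dmrs)
  if (n_t == 0 || n_c == 0)
    return(list(sensitivity = if (n_t == 0) NA_real_ else 0,
                precision = if (n_c == 0) NA_real_ else 0,
                n_truth = n_t, n_called = n_c,
                matched_truth = 0L, matched_called = 0L))
  sq <- union(truth$chrom, dmrs$chrom)
  gt <- as_granges(truth, end_col = "end", seqlevels = sq)
  gc_ <- as_granges(dmrs, seqlevels = sq)
  h <- GenomicRanges::findOverlaps(gt, gc_)
  if (length(h) == 0)
    return(list(sensitivity = 0, precision = 0, n_truth = n_t,
                n_called = n_c, matched_truth = 0L, matched_called = 0L))
  qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
  ov <- GenomicRanges::width(IRanges::pintersect(gt[qi], gc_[si]))
  ok <- ov >= fraction * GenomicRanges::width(gt[qi]) &
    ov >= fraction * GenomicRanges::width(gc_[si])
  list(sensitivity = length(unique(qi[ok])) / n_t,
       precision = length(unique(si[ok])) / n_c,
       n_truth = n_t, n_called = n_c,
       matched_truth = length(unique(qi[ok])),
       matched_called = length(unique(si[ok])))
}
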