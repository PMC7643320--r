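#' CpG density histogram of DMRs
#'
#' Bins each DMR's CpG density (CpG per 100 bp) by `floor(density)`; bins run
#' 0..10 with an overflow `"10+"` bin. Counts sum to the number of DMRs.
#'
#' @param dmrs a [assemble_dmrs()] result with `cpg_density`.
#' @return data.frame `bin` (character), `count`.
#' @export
cpg_density_histogram <- function(dmrs) {
  labs <- c(as.character(0:9), "10+")
  counts <- stats::setNames(integer(11), labs)
  if (nrow(dmrs)) {
    b <- pmin(floor(dmrs$cpg_density), 10)
    tab <- table(factor(b, levels = 0:10))
    counts[] <- as.integer(tab)
  }
  data.frame(bin = labs, count = as.integer(counts), stringsAsFactors = FALSE)
}

#' Length histogram of DMRs
#'
#' Bins DMR lengths into `bin`-bp classes: a DMR of length `L` falls in bin
#' `ceiling(L / bin)` (so a one-window 1000 bp DMR is in the 1 kb bin).
#'
#' @param dmrs a [assemble_dmrs()] result.
#' @param bin bin width in bp (default 1000).
#' @return data.frame `length_kb` (upper bin edge in units of `bin`),
#'   `count`.
#' @export
length_histogram <- function(dmrs, bin = 1000) {
  if (nrow(dmrs) == 0L)
    return(data.frame(length_kb = integer(0), count = integer(0)))
  b <- ceiling(dmrs$length / bin)
  tab <- table(factor(b, levels = seq_len(max(b))))
  data.frame(length_kb = as.integer(names(tab)), count = as.integer(tab))
}

#' Detect chromosomal DMR clusters
#'
#' A cluster is a maximal run of at least `min_cluster_size` DMRs on one
#' chromosome in which consecutive members are at most `cluster_window` bp
#' apart (gap measured between intervals).
#'
#' @param dmrs a [assemble_dmrs()] result.
#' @param cluster_window maximum gap between consecutive members (default
#'   2 Mb).
#' @param min_cluster_size minimum members per cluster (default 3).
#' @return data.frame `chrom`, `start`, `end`, `n_members`, `members`
#'   (comma-separated DMR names).
#' @export
find_dmr_clusters <- function(dmrs, cluster_window = 2e6,
                              min_cluster_size = 3) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_members = integer(0),
                      members = character(0), stringsAsFactors = FALSE)
  if (nrow(dmrs) == 0L) return(empty)
  d <- dmrs[order(dmrs$chrom, dmrs$start), , drop = FALSE]
  out <- lapply(split(d, d$chrom), function(x) {
    gap <- x$start[-1] - x$stop[-nrow(x)]
    grp <- cumsum(c(1L, gap > cluster_window))
    runs <- split(seq_len(nrow(x)), grp)
    runs <- runs[vapply(runs, length, integer(1)) >= min_cluster_size]
    if (!length(runs)) return(NULL)
    do.call(rbind, lapply(runs, function(r)
      data.frame(chrom = x$chrom[r[1]], start = min(x$start[r]),
                 end = max(x$stop[r]), n_members = length(r),
                 members = paste(x$name[r], collapse = ","),
                 stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

# GRanges from a DMR/interval data.frame (0-based half-open in, 1-based in);
# `seqlevels` lets paired objects share a level set so set operations stay
# silent when their chromosomes differ
as_granges <- function(df, start_col = "start", end_col = "stop",
                       seqlevels = NULL) {
  end <- if (end_col %in% names(df)) df[[end_col]] else df$end
  sq <- if (is.null(seqlevels)) unique(df$chrom) else seqlevels
  GenomicRanges::GRanges(factor(df$chrom, levels = sq),
                         IRanges::IRanges(start = df[[start_col]] + 1L,
                                          end = end))
}

#' Associate genes with DMRs by genomic distance
#'
#' A gene is associated with a DMR when the minimum genomic distance between
#' the DMR interval and the gene body is at most `max_distance` bp (0 =
#' overlap; inclusive at the boundary). All qualifying genes are listed.
#' Annotation entries on chromosomes absent from the DMR set are simply
#' never matched.
#'
#' @param dmrs a [assemble_dmrs()] result.
#' @param annotation data.frame `gene`, `chrom`, `start`, `end` (0-based
#'   half-open), optional `strand`.
#' @param max_distance association distance in bp (default 10 kb).
#' @return `dmrs` with an added `genes` column (comma-separated, `""` when
#'   none).
#' @export
associate_genes <- function(dmrs, annotation, max_distance = 10000) {
  dmrs$genes <- rep("", nrow(dmrs))
  if (nrow(dmrs) == 0L || nrow(annotation) == 0L) return(dmrs)
  if (any(annotation$end <= annotation$start))
    stop("associate_genes: gene with end <= start", call. = FALSE)
  sq <- union(dmrs$chrom, annotation$chrom)
  gr_d <- as_granges(dmrs, seqlevels = sq)
  gr_g <- as_granges(annotation, end_col = "end", seqlevels = sq)
  # candidate pairs by overlap against intervals widened past the distance
  # rule, then the exact (boundary-inclusive) distance check
  gr_w <- suppressWarnings(GenomicRanges::resize(
    gr_d, GenomicRanges::width(gr_d) + 2 * (max_distance + 1), fix = "center"))
  hits <- GenomicRanges::findOverlaps(gr_w, gr_g)
  pairs <- data.frame(d = S4Vectors::queryHits(hits),
                      g = S4Vectors::subjectHits(hits))
  dist <- GenomicRanges::distance(gr_d[pairs$d], gr_g[pairs$g])
  pairs <- pairs[!is.na(dist) & dist <= max_distance, , drop = FALSE]
  if (nrow(pairs)) {
    lst <- split(annotation$gene[pairs$g], pairs$d)
    for (k in names(lst))
      dmrs$genes[as.integer(k)] <-
        paste(sort(unique(lst[[k]])), collapse = ",")
  }
  dmrs
}

#' Tabulate functional categories of DMR-associated genes
#'
#' Each gene carries a single category; genes absent from the mapping count
#' as `"unknown"`. A gene associated with several DMRs counts once.
#'
#' @param genes character vector of gene names (or the comma-separated
#'   `genes` column from [associate_genes()]).
#' @param categories data.frame `gene`, `category` mapping each gene to one
#'   category.
#' @return data.frame `category`, `n_genes`, sorted by decreasing count.
#' @export
categorize_genes <- function(genes, categories) {
  if (anyDuplicated(categories$gene))
    stop("categorize_genes: a gene maps to multiple categories", call. = FALSE)
  g <- unique(unlist(strsplit(genes[nzchar(genes)], ",")))
  if (length(g) == 0L)
    return(data.frame(category = character(0), n_genes = integer(0)))
  cat <- categories$category[match(g, categories$gene)]
  cat[is.na(cat)] <- "unknown"
  tab <- sort(table(cat), decreasing = TRUE)
  data.frame(category = names(tab), n_genes = as.integer(tab),
             stringsAsFactors = FALSE)
}
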