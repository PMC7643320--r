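#' Write a window count matrix as TSV
#'
#' Rows are windows labeled `chrom:start-end` (0-based, half-open), columns
#' are sample IDs. The companion group table goes to a 2-column TSV
#' (`sample`, `group`) via [write_groups_tsv()].
#'
#' @param mat a [window_counts()] object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(mat, path) {
  m <- mat$counts
  rn <- sprintf("%s:%d-%d", mat$windows$chrom, mat$windows$start,
                mat$windows$end)
  df <- data.frame(window = rn, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
write_groups_tsv <- function(mat, path) {
  utils::write.table(mat$samples[c("sample", "group")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a window count matrix from TSV
#'
#' Inverse of [write_counts_tsv()] / [write_groups_tsv()]; a round trip
#' reproduces the counts, window grid and group labels exactly.
#'
#' @param counts_path counts TSV (first column `window` as
#'   `chrom:start-end`).
#' @param groups_path groups TSV (`sample`, `group`).
#' @return a [window_counts()] object.
#' @export
read_counts_tsv <- function(counts_path, groups_path) {
  df <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || any(m != floor(m))) {
    chr <- as.matrix(df[, -1, drop = FALSE])
    bad <- arrayInd(which(!grepl("^[0-9]+$", chr))[1], dim(chr))
    stop("read_counts_tsv: non-integer count at row ", bad[1, 1],
         ", column ", colnames(df)[bad[1, 2] + 1], call. = FALSE)
  }
  parts <- regmatches(df$window,
                      regexec("^(.+):([0-9]+)-([0-9]+)$", df$window))
  if (any(vapply(parts, length, integer(1)) != 4))
    stop("read_counts_tsv: malformed window label at line ",
         which(vapply(parts, length, integer(1)) != 4)[1] + 1, call. = FALSE)
  windows <- data.frame(
    chrom = vapply(parts, `[`, character(1), 2),
    start = as.integer(vapply(parts, `[`, character(1), 3)),
    end = as.integer(vapply(parts, `[`, character(1), 4)),
    stringsAsFactors = FALSE)
  g <- utils::read.table(groups_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  g <- g[match(colnames(m), g$sample), ]
  if (any(is.na(g$group)))
    stop("read_counts_tsv: samples missing from groups file", call. = FALSE)
  window_counts(counts = m, windows = windows, groups = g$group)
}

#' Write intervals as BED
#'
#' 0-based, half-open, tab-delimited; six columns when `name`/`score`/
#' `strand` are available (DMR sets use `-log10(min_p)` as the score).
#'
#' @param df data.frame with `chrom`, `start` and `stop` (or `end`);
#'   optionally `name`.
#' @param path output path.
#' @param score optional numeric score column to write.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, score = NULL) {
  end <- if ("stop" %in% names(df)) df$stop else df$end
  out <- data.frame(chrom = df$chrom, start = df$start, end = end,
                    stringsAsFactors = FALSE)
  if (!is.null(df$name) || !is.null(score)) {
    out$name <- if (is.null(df$name)) "." else df$name
    out$score <- if (is.null(score)) 0 else score
    out$strand <- if (is.null(df$strand)) "." else df$strand
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path BED path (>= 3 columns, 0-based half-open; empty file allowed).
#' @return data.frame `chrom`, `start`, `end`, and `name` when present.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("read_bed: fewer than 3 columns", call. = FALSE)
  bad <- which(!is.numeric(df[[2]]) | !is.numeric(df[[3]]))
  if (length(bad))
    stop("read_bed: malformed line ", bad[1], call. = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df
}

#' Write per-window test results as TSV
#'
#' @param results a [test_all_windows()] data.frame; a `q_value` column is
#'   added over tested windows (untested windows carry `NA`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_window_results <- function(results, path) {
  out <- as.data.frame(results)
  out$q_value <- NA_real_
  out$q_value[out$tested] <- bh_adjust(out$p_value[out$tested])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-window test results written by [write_window_results()]
#'
#' @param path TSV path.
#' @return data.frame of class `window_tests`.
#' @export
read_window_results <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("window_tests", "data.frame")
  out
}
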