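#' Histopathological abnormality density
#'
#' Number of abnormalities per mm^2 of tissue section.
#'
#' @param count non-negative abnormality count.
#' @param area_mm2 section area in mm^2 (> 0).
#' @return density per mm^2 (vectorized).
#' @export
abnormality_density <- function(count, area_mm2) {
  if (any(area_mm2 <= 0))
    stop("abnormality_density: section area must be positive", call. = FALSE)
  if (any(count < 0))
    stop("abnormality_density: negative abnormality count", call. = FALSE)
  count / area_mm2
}

#' Control-derived disease threshold
#'
#' The cutoff above which a tissue is scored diseased: the control-group mean
#' abnormality density plus two sample standard deviations (n-1 denominator).
#'
#' @param control_densities >= 2 per-mm^2 densities from control tissues.
#' @return cutoff per mm^2.
#' @examples
#' control_threshold(c(1, 2, 3))  # 2 + 2*1 = 4
#' @export
control_threshold <- function(control_densities) {
  if (length(control_densities) < 2)
    stop("control_threshold: >= 2 control values required", call. = FALSE)
  mean(control_densities) + 2 * stats::sd(control_densities)
}

#' Observer-consensus disease call
#'
#' A tissue is declared diseased when at least two of the available observer
#' calls (two, or three when the first two disagree) are diseased.
#'
#' @param calls logical vector of per-observer diseased flags (length >= 1).
#' @return logical.
#' @export
consensus_disease_call <- function(calls) {
  if (length(calls) == 0)
    stop("consensus_disease_call: empty call list", call. = FALSE)
  sum(calls) >= 2
}

#' Per-tissue disease calls from abnormality records
#'
#' Applies the full classification chain: per-record densities, a
#' control-derived two-standard-deviation cutoff per tissue and observer,
#' per-observer diseased flags, and the two-of-three observer consensus. By
#' default the cutoff applies to each observer's summed abnormality density
#' per tissue; with `per_type = TRUE` (requires a `type` column) cutoffs are
#' formed per abnormality type and an observer scores a tissue diseased when
#' any type exceeds its cutoff.
#'
#' @param records data.frame `animal`, `tissue`, `observer`, `count`,
#'   `area_mm2`, optional `type`.
#' @param control_animals animal IDs forming the control group.
#' @param per_type apply the cutoff per abnormality type.
#' @return data.frame `animal`, `tissue`, `diseased`.
#' @export
tissue_disease_calls <- function(records, control_animals, per_type = FALSE) {
  need <- c("animal", "tissue", "observer", "count", "area_mm2")
  if (!all(need %in% names(records)))
    stop("tissue_disease_calls: records need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (per_type && !"type" %in% names(records))
    stop("tissue_disease_calls: per_type = TRUE requires a 'type' column",
         call. = FALSE)
  records$density <- abnormality_density(records$count, records$area_mm2)
  keys <- if (per_type) c("tissue", "observer", "type") else
    c("tissue", "observer")
  # summed density per animal within each (tissue, observer[, type]) stratum
  agg <- stats::aggregate(
    records["density"],
    by = records[c("animal", keys)], FUN = sum)
  strata <- split(agg, agg[keys], drop = TRUE)
  flags <- do.call(rbind, lapply(strata, function(s) {
    ctrl <- s$density[s$animal %in% control_animals]
    cut <- control_threshold(ctrl)
    data.frame(animal = s$animal, tissue = s$tissue,
               observer = s$observer, flag = s$density > cut,
               stringsAsFactors = FALSE)
  }))
  # per_type: an observer flags the tissue if any type exceeds its cutoff
  obs <- stats::aggregate(flags["flag"],
                          by = flags[c("animal", "tissue", "observer")],
                          FUN = any)
  res <- stats::aggregate(list(diseased = obs$flag),
                          by = obs[c("animal", "tissue")],
                          FUN = consensus_disease_call)
  res[order(res$animal, res$tissue), , drop = FALSE]
}

PATHOLOGY_COLUMNS <- c("late_puberty", "testis", "prostate", "kidney",
                       "obesity", "tumor")

#' Parse a per-animal disease presence table
#'
#' Reads a table of `+` / `-` / `n/a` entries (one row per animal, one column
#' per pathology) into a disease table: flags are mapped to
#' present/absent/missing, the per-animal total-disease count is the number
#' of present flags among the six primary pathologies (missing entries do
#' not count), and the multiple-disease flag marks animals with a total of
#' at least two.
#'
#' @param df data.frame whose first column is the animal ID and remaining
#'   columns are the six pathology columns (in the order late puberty,
#'   testis, prostate, kidney, obesity, tumor), entries in
#'   `+`, `-` (or en-dash), `n/a`, `na`, `NA`, `""`.
#' @return data.frame of class `disease_table`: `animal`, one
#'   present/absent/`NA` character column per pathology, `total_disease`,
#'   `multiple_disease`.
#' @export
parse_disease_table <- function(df) {
  if (ncol(df) < 7)
    stop("parse_disease_table: need an ID column plus 6 pathology columns",
         call. = FALSE)
  out <- data.frame(animal = as.character(df[[1]]), stringsAsFactors = FALSE)
  for (j in seq_along(PATHOLOGY_COLUMNS)) {
    raw <- trimws(as.character(df[[j + 1]]))
    flag <- ifelse(raw == "+", "present",
                   ifelse(raw %in% c("-", "−", "–"), "absent",
                          ifelse(tolower(raw) %in% c("n/a", "na", "") |
                                   is.na(raw), NA, "bad")))
    bad <- which(flag == "bad")
    if (length(bad))
      stop("parse_disease_table: unknown symbol '", raw[bad[1]],
           "' in row ", bad[1], " (animal ", out$animal[bad[1]],
           "), column ", PATHOLOGY_COLUMNS[j], call. = FALSE)
    out[[PATHOLOGY_COLUMNS[j]]] <- flag
  }
  present <- sapply(out[PATHOLOGY_COLUMNS],
                    function(x) !is.na(x) & x == "present")
  out$total_disease <- as.integer(rowSums(present))
  out$multiple_disease <- out$total_disease >= 2L
  structure(out, class = c("disease_table", "data.frame"))
}

#' Read a disease table from TSV/CSV
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (`.csv` = comma, otherwise tab).
#' @return a [parse_disease_table()] result.
#' @export
read_disease_table <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          check.names = FALSE, na.strings = NULL)
  parse_disease_table(df)
}

# round half up (printed-table style; R's round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

#' Disease incidence summary
#'
#' For each pathology (the six primary columns plus the derived
#' multiple-disease flag): animals positive, animals evaluable (non-missing),
#' and the percentage rounded half-up to a whole percent, matching the
#' printed-table style of incidence totals.
#'
#' @param table a [parse_disease_table()] result.
#' @return data.frame `pathology`, `n_positive`, `n_evaluable`, `percent`.
#' @export
incidence_summary <- function(table) {
  rows <- lapply(c(PATHOLOGY_COLUMNS, "multiple_disease"), function(col) {
    if (col == "multiple_disease") {
      pos <- sum(table$multiple_disease)
      ev <- nrow(table)
    } else {
      x <- table[[col]]
      pos <- sum(!is.na(x) & x == "present")
      ev <- sum(!is.na(x))
    }
    if (ev == 0)
      stop("incidence_summary: no evaluable animals for ", col, call. = FALSE)
    data.frame(pathology = col, n_positive = pos, n_evaluable = ev,
               percent = round_half_up(100 * pos / ev),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.disease_table <- function(x, ...) {
  cat("disease_table:", nrow(x), "animals;",
      sum(x$multiple_disease), "with multiple disease\n")
  print.data.frame(utils::head(as.data.frame(x), 8))
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Incidence comparison between groups: the two-sided p-value sums the
#' hypergeometric probabilities (margins fixed) of every table no more
#' probable than the observed one (minimum-likelihood method).
#'
#' @param a,b,c,d non-negative cell counts, rows = groups, columns =
#'   affected/unaffected (`a`,`b` = group 1).
#' @return two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(0, 5, 5, 0)  # 2/252
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0))
    stop("fisher_exact_2x2: negative cell count", call. = FALSE)
  if (sum(a, b, c, d) == 0)
    stop("fisher_exact_2x2: empty table", call. = FALSE)
  stats::fisher.test(matrix(c(a, c, b, d), nrow = 2))$p.value
}
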