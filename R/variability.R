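#' Classify alignment columns
#'
#' Each column is labelled using unambiguous bases (A/C/G/T) only; gaps, N
#' and IUPAC ambiguity codes count as missing. A column is `indeterminate`
#' if it has fewer than 2 unambiguous characters, `constant` if it shows one
#' state, `parsimony_informative` if at least two states each occur in at
#' least two sequences, and `singleton_variable` otherwise.
#'
#' @param x A `concat_dataset` or `region_alignment`.
#' @param sample_subset Optional character vector of sample ids.
#' @return Character vector, one label per column.
#' @export
classify_sites <- function(x, sample_subset = NULL) {
  aln <- if (inherits(x, "concat_dataset")) x$alignment else x
  stopifnot(inherits(aln, "region_alignment"))
  mat <- aln$seq
  if (!is.null(sample_subset)) {
    miss <- setdiff(sample_subset, rownames(mat))
    if (length(miss))
      stop_ctx("unknown sample(s): ", paste(miss, collapse = ", "),
               class = "format_error")
    mat <- mat[sample_subset, , drop = FALSE]
  }
  if (nrow(mat) == 0L || ncol(mat) == 0L)
    stop_ctx("empty alignment", class = "alignment_error")
  # per-column counts of each unambiguous base, vectorised over the matrix
  counts <- vapply(UNAMBIG, function(b) colSums(mat == b),
                   numeric(ncol(mat)))
  if (ncol(mat) == 1L) counts <- matrix(counts, nrow = 1L)
  n_unamb <- rowSums(counts)
  n_states <- rowSums(counts > 0)
  n_deep <- rowSums(counts >= 2)  # states present in >= 2 sequences
  labels <- rep("constant", ncol(mat))
  labels[n_states >= 2] <- "singleton_variable"
  labels[n_states >= 2 & n_deep >= 2] <- "parsimony_informative"
  labels[n_unamb < 2] <- "indeterminate"
  labels
}

#' Variability report for one data set
#'
#' Counts variable and parsimony-informative sites and renders the two
#' percentages (100 * count / alignment length) rounded half-up to 3
#' decimals, matching the rendering of printed variability tables.
#'
#' @inheritParams classify_sites
#' @return A one-row data.frame: `code`, `length`, `n_variable`,
#'   `n_parsimony_informative`, `pct_variable`, `pct_parsimony_informative`.
#' @export
summarize_variability <- function(x, sample_subset = NULL) {
  labels <- classify_sites(x, sample_subset)
  code <- if (inherits(x, "concat_dataset")) x$code else x$region
  len <- length(labels)
  n_var <- sum(labels %in% c("singleton_variable", "parsimony_informative"))
  n_pi <- sum(labels == "parsimony_informative")
  data.frame(code = code, length = len,
             n_variable = n_var, n_parsimony_informative = n_pi,
             pct_variable = pct_of(n_var, len),
             pct_parsimony_informative = pct_of(n_pi, len),
             stringsAsFactors = FALSE)
}

# Percentage of a count over a length, rounded half-up to 3 decimals.
pct_of <- function(count, length) round_half_up(100 * count / length, 3L)

#' Variability table over several data sets
#'
#' @param datasets Named list of `concat_dataset`s.
#' @inheritParams classify_sites
#' @return Data.frame with one row per data set.
#' @export
variability_table <- function(datasets, sample_subset = NULL) {
  do.call(rbind, lapply(datasets, summarize_variability,
                        sample_subset = sample_subset))
}

#' Rank data sets by percent variable sites
#'
#' Codes are ordered by `pct_variable` descending; ties are broken
#' alphabetically by code.
#'
#' @param reports Data.frame as from [variability_table()] (needs columns
#'   `code` and `pct_variable`).
#' @return Character vector of codes, most variable first.
#' @export
rank_datasets <- function(reports) {
  stopifnot(nrow(reports) >= 1L)
  reports$code[order(-reports$pct_variable, reports$code)]
}

#' Detect divergence hotspots
#'
#' Flags regions whose variability value strictly exceeds the threshold
#' T = mean + 2 * SD (sample standard deviation, n-1 denominator) across
#' regions — the standard screen for significantly higher-than-average
#' variability.
#'
#' @param values Named numeric vector of per-region variability values
#'   (typically percent variable sites).
#' @return List with `threshold`, `values` and `flagged` (region names).
#' @export
detect_hotspots <- function(values) {
  if (length(values) < 2L)
    stop_ctx("hotspot detection needs at least 2 regions", class = "config_error")
  thr <- mean(values) + 2 * sd(values)
  list(threshold = thr, values = values,
       flagged = names(values)[values > thr] %||% character(0))
}

#' Per-region variability of a multi-region data set
#'
#' Computes percent variable sites for each region of a synthetic data set or
#' a named list of region alignments; the result feeds [detect_hotspots()].
#'
#' @param regions A `synthetic_dataset` or named list of `region_alignment`s.
#' @inheritParams classify_sites
#' @return Named numeric vector, region -> pct_variable.
#' @export
per_region_variability <- function(regions, sample_subset = NULL) {
  if (inherits(regions, "synthetic_dataset")) regions <- regions$regions
  vapply(regions, function(r)
    summarize_variability(r, sample_subset)$pct_variable, numeric(1))
}
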