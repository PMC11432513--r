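#' Barcoding-gap (distance-based) delimitation criterion for one taxon
#'
#' A taxon is successfully delimited when its minimum interspecific K2P
#' distance (over all pairs of one in-taxon and one out-taxon sample)
#' strictly exceeds its maximum intraspecific distance (over all within-taxon
#' pairs). Pairwise extremes are used, not group means.
#'
#' @param D Symmetric K2P distance matrix labelled by sample id.
#' @param metadata Data.frame with `sample_id` and `taxon`.
#' @param taxon Taxon to assess.
#' @return List with `verdict` (`"success"`/`"failure"`/`"not_assessable"`),
#'   `max_intra` and `min_inter`.
#' @export
barcoding_gap_test <- function(D, metadata, taxon) {
  ins <- intersect(rownames(D), metadata$sample_id[metadata$taxon == taxon])
  outs <- setdiff(rownames(D), ins)
  if (length(ins) < 2L)
    return(list(verdict = "not_assessable", max_intra = NA_real_,
                min_inter = NA_real_))
  if (length(outs) < 1L)
    stop_ctx("no samples outside taxon '", taxon, "'", class = "config_error")
  intra <- D[ins, ins][upper.tri(D[ins, ins])]
  inter <- D[ins, outs, drop = FALSE]
  if (anyNA(intra) || anyNA(inter))
    stop_ctx("masked (saturated) pair needed by the gap test for taxon '",
             taxon, "'", class = "distance_error")
  max_intra <- max(intra)
  min_inter <- min(inter)
  list(verdict = if (min_inter > max_intra) "success" else "failure",
       max_intra = max_intra, min_inter = min_inter)
}

#' Apply one delimitation method to every taxon
#'
#' @param method `"tree"`, `"distance"` or `"asap"`.
#' @param code Data-set code the result refers to.
#' @param metadata Data.frame with `sample_id` and `taxon`.
#' @param ... Method inputs: `tree` (phylo with supports) and
#'   `support_threshold` for `"tree"`; `D` (distance matrix) for
#'   `"distance"`; `partition` (a `PartitionCandidate`-style list with a
#'   `grouping`) for `"asap"`.
#' @return A `delimitation_result` data.frame: one row per taxon with
#'   `code`, `method`, `taxon`, `verdict` and diagnostics.
#' @export
delimit_taxa <- function(method = c("tree", "distance", "asap"), code,
                         metadata, ...) {
  method <- match.arg(method)
  args <- list(...)
  taxa <- unique(metadata$taxon)
  rows <- lapply(taxa, function(tx) {
    if (method == "tree") {
      r <- taxon_monophyly(args$tree, metadata, tx,
                           support_threshold = args$support_threshold %||% 50)
      data.frame(code = code, method = method, taxon = tx,
                 verdict = r$verdict, support = r$support,
                 max_intra = NA_real_, min_inter = NA_real_,
                 stringsAsFactors = FALSE)
    } else if (method == "distance") {
      r <- barcoding_gap_test(args$D, metadata, tx)
      data.frame(code = code, method = method, taxon = tx,
                 verdict = r$verdict, support = NA_real_,
                 max_intra = r$max_intra, min_inter = r$min_inter,
                 stringsAsFactors = FALSE)
    } else {
      v <- asap_taxon_verdicts(args$partition, metadata)
      data.frame(code = code, method = method, taxon = tx,
                 verdict = v[[tx]], support = NA_real_,
                 max_intra = NA_real_, min_inter = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("delimitation_result", class(out))
  out
}

#' Discrimination-rate summary (Table-2 style)
#'
#' Aggregates per-taxon verdicts to one row per data set x method:
#' `n_success` / `n_taxa` and the rate 100 * n_success / n_taxa rounded
#' half-up to 2 decimals. Non-assessable taxa count as failures so the
#' denominator stays fixed at the taxon count.
#'
#' @param results One or more `delimitation_result` data.frames (rbind-able).
#' @return Data.frame with `code`, `method`, `n_success`, `n_taxa`, `rate`,
#'   and `cell` rendered as "k/n (xx.xx\%)".
#' @export
summarize_discrimination <- function(results) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, results)
  if (is.null(results) || nrow(results) == 0L)
    stop_ctx("no delimitation results to summarise", class = "config_error")
  taxa <- sort(unique(results$taxon))
  split_by <- interaction(results$code, results$method, drop = TRUE)
  rows <- lapply(split(results, split_by), function(g) {
    if (!setequal(g$taxon, taxa))
      stop_ctx("all results must reference the same taxon set", class = "config_error")
    n_succ <- sum(g$verdict == "success")
    n <- nrow(g)
    rate <- discrimination_rate(n_succ, n)
    data.frame(code = g$code[1L], method = g$method[1L],
               n_success = n_succ, n_taxa = n, rate = rate,
               cell = sprintf("%d/%d (%.2f%%)", n_succ, n, rate),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$code, out$method), ]
}

#' Discrimination rate as a percentage
#'
#' @param n_success,n_taxa Counts.
#' @return 100 * n_success / n_taxa rounded half-up to 2 decimals.
#' @export
discrimination_rate <- function(n_success, n_taxa) {
  stopifnot(n_taxa >= 1L, n_success >= 0L, n_success <= n_taxa)
  round_half_up(100 * n_success / n_taxa, 2L)
}

#' Render a Table-2-style discrimination TSV (data sets x methods)
#'
#' @param summary Output of [summarize_discrimination()].
#' @param path Output path.
#' @export
write_discrimination_tsv <- function(summary, path) {
  wide <- stats::reshape(summary[c("code", "method", "cell")],
                         idvar = "code", timevar = "method",
                         direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  write.table(wide[order(wide$code), ], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
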