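#' Build the nested partition ladder (ASAP-style candidates)
#'
#' Single-linkage clustering of the distance matrix is cut at every midpoint
#' between consecutive distinct pairwise distances, plus thresholds 0 and
#' infinity; duplicate groupings are removed. The result is a nested ladder
#' of candidate species partitions from all-singletons to one group.
#'
#' @param D Symmetric distance matrix (no masked pairs).
#' @param linkage `"single"` (default; threshold-connectivity semantics) or
#'   `"average"`.
#' @return List of candidates, each a list with `threshold`, `grouping`
#'   (named integer vector sample -> group id) and `n_groups`.
#' @export
build_partition_ladder <- function(D, linkage = c("single", "average")) {
  linkage <- match.arg(linkage)
  if (any(is.na(D))) stop_ctx("masked pairs in distance matrix", class = "distance_error")
  n <- nrow(D)
  if (n < 3L) stop_ctx("need at least 3 samples", class = "config_error")
  hc <- hclust(as.dist(D), method = if (linkage == "single") "single" else "average")
  dists <- sort(unique(D[upper.tri(D)]))
  mids <- if (length(dists) > 1L) (dists[-1L] + dists[-length(dists)]) / 2 else numeric(0)
  thresholds <- c(0, mids, max(dists) + 1)
  out <- list(); seen <- character(0)
  for (th in thresholds) {
    g <- cutree(hc, h = th)
    key <- paste(match(g, unique(g)), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- list(threshold = th, grouping = g,
                                    n_groups = length(unique(g)))
  }
  out
}

# Gap statistic of the merge turning `grouping` into `coarser`: over the
# union of the merged groups, min cross-subgroup distance minus max
# within-subgroup distance (0 when the subgroups have no within pairs).
merge_gap <- function(D, sub_of) {
  ids <- names(sub_of)
  sub <- D[ids, ids, drop = FALSE]
  same <- outer(sub_of, sub_of, "==")
  ut <- upper.tri(sub)
  within <- sub[ut & same]
  min(sub[ut & !same]) - if (length(within)) max(within) else 0
}

# permutation p-value for the merge from `grouping` to `coarser`; NULL
# coarser (already the coarsest candidate) merges everything into one group.
merge_panmixia_p <- function(D, grouping, coarser, n_permutations) {
  g <- grouping[rownames(D)]
  if (is.null(coarser)) {
    merged_ids <- rownames(D)
  } else {
    cg <- coarser[rownames(D)]
    tab <- table(g, cg)
    merged_parents <- colnames(tab)[colSums(tab > 0) >= 2L]
    if (!length(merged_parents)) return(1)
    merged_ids <- rownames(D)[cg %in% merged_parents]
  }
  sub_of <- g[merged_ids]
  if (length(unique(sub_of)) < 2L) return(1)
  w_obs <- merge_gap(D, sub_of)
  exceed <- 0L
  for (p in seq_len(n_permutations)) {
    perm <- setNames(sample(sub_of), names(sub_of))
    if (merge_gap(D, perm) >= w_obs) exceed <- exceed + 1L
  }
  (1 + exceed) / (n_permutations + 1)
}

# gap width of a grouping on D: min between-group distance minus max
# within-group distance (requires >= 2 groups and >= 1 within pair).
gap_width <- function(D, grouping) {
  g <- grouping[rownames(D)]
  same <- outer(g, g, "==")
  ut <- upper.tri(D)
  within <- D[ut & same]
  between <- D[ut & !same]
  if (!length(between)) return(NA_real_)
  min(between) - if (length(within)) max(within) else 0
}

#' Score candidate partitions (ASAP-style)
#'
#' Each candidate with 2 <= n_groups <= n-1 gets a barcode-gap width
#' w = min between-group distance - max within-group distance (on its own
#' grouping), and a panmixia probability for the merge that turns this
#' candidate into the next coarser one: over the samples of the merged
#' groups, p is the Monte-Carlo probability that a random relabelling
#' (sub-group sizes preserved) yields a merge gap at least as large as
#' observed. A merge of two tight subgroups of one real cluster looks
#' panmictic (large p); the merge that finally unites two genuinely isolated
#' clusters does not (p near its minimum); merges of singletons are
#' untestable and get p = 1. Candidates are ranked by descending w and by
#' ascending p (ties share the mean rank); the asap score is the average of
#' the two ranks, lower is better.
#'
#' This scorer is a surrogate for the published ASAP web service: it keeps
#' the interface (nested candidates, a gap-width rank and a panmixia-
#' probability rank averaged into one score) but replaces the coalescent-
#' based panmixia probability with a seeded permutation test on the merge
#' gap width.
#'
#' @param ladder Output of [build_partition_ladder()].
#' @param D The distance matrix the ladder was built from.
#' @param n_permutations Permutations for the panmixia test (default 999;
#'   fewer than 99 draws a warning, fewer than 1 is an error).
#' @param seed Integer seed.
#' @return Data-frame-like list of candidates sorted by ascending
#'   `asap_score`, each with `threshold`, `grouping`, `n_groups`, `w`,
#'   `panmixia_p`, `rank_w`, `rank_p`, `asap_score`. Empty (with a message)
#'   if no non-trivial candidate exists.
#' @export
score_partitions <- function(ladder, D, n_permutations = 999L, seed = 1L) {
  if (n_permutations < 1L) stop_ctx("n_permutations must be >= 1", class = "config_error")
  if (n_permutations < 99L) warning("n_permutations < 99: panmixia p-values are coarse")
  n <- nrow(D)
  ladder <- ladder[order(-vapply(ladder, `[[`, integer(1), "n_groups"))]
  keep <- vapply(ladder, function(c) c$n_groups >= 2L && c$n_groups <= n - 1L,
                 logical(1))
  cand <- ladder[keep]
  if (!length(cand)) {
    message("no non-trivial candidate partitions (degenerate distance structure)")
    return(list())
  }
  set.seed(seed)
  ids <- rownames(D)
  for (i in seq_along(cand)) {
    idx <- which(keep)[i]
    coarser <- if (idx < length(ladder)) ladder[[idx + 1L]]$grouping else NULL
    cand[[i]]$w <- gap_width(D, cand[[i]]$grouping)
    cand[[i]]$panmixia_p <- merge_panmixia_p(D, cand[[i]]$grouping, coarser,
                                             n_permutations)
  }
  w <- vapply(cand, `[[`, numeric(1), "w")
  p <- vapply(cand, `[[`, numeric(1), "panmixia_p")
  rank_w <- rank(-w)          # descending w: widest gap ranks first
  rank_p <- rank(p)           # ascending p
  for (i in seq_along(cand)) {
    cand[[i]]$rank_w <- rank_w[i]
    cand[[i]]$rank_p <- rank_p[i]
    cand[[i]]$asap_score <- (rank_w[i] + rank_p[i]) / 2
  }
  cand[order(vapply(cand, `[[`, numeric(1), "asap_score"))]
}

#' Per-taxon verdicts from the best ASAP partition
#'
#' A taxon succeeds when some group's member set equals exactly the taxon's
#' sample set (all its individuals in one OTU containing nothing else).
#'
#' @param best A candidate from [score_partitions()] (needs `grouping`).
#' @param metadata Data.frame with `sample_id` and `taxon`.
#' @return Named character vector taxon -> `"success"`/`"failure"`.
#' @export
asap_taxon_verdicts <- function(best, metadata) {
  g <- best$grouping
  groups <- split(names(g), g)
  taxa <- unique(metadata$taxon)
  out <- setNames(rep("failure", length(taxa)), taxa)
  for (tx in taxa) {
    samples <- metadata$sample_id[metadata$taxon == tx]
    if (any(vapply(groups, function(members) setequal(members, samples), logical(1))))
      out[tx] <- "success"
  }
  out
}

#' Ranked-candidate table for export
#'
#' @param scored Output of [score_partitions()].
#' @param top Keep at most this many candidates (default 10).
#' @return Data.frame with `n_groups`, `threshold`, `w`, `panmixia_p`,
#'   `rank_w`, `rank_p`, `asap_score`, `group_sizes`.
#' @export
asap_candidate_table <- function(scored, top = 10L) {
  scored <- scored[seq_len(min(top, length(scored)))]
  do.call(rbind, lapply(scored, function(c)
    data.frame(n_groups = c$n_groups, threshold = c$threshold, w = c$w,
               panmixia_p = c$panmixia_p, rank_w = c$rank_w, rank_p = c$rank_p,
               asap_score = c$asap_score,
               group_sizes = paste(sort(table(c$grouping), decreasing = TRUE),
                                   collapse = "+"),
               stringsAsFactors = FALSE)))
}
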