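#' Collapse aligned sequences into haplotypes
#'
#' Two samples share a haplotype when their sequences are identical at every
#' column where both carry an unambiguous base (missing-tolerant matching:
#' N/gap is compatible with any base). Compatibility is closed transitively
#' by union-find, so chains of mutually compatible sequences form one
#' haplotype. The representative is the first member's sequence.
#'
#' @param x A `concat_dataset` or `region_alignment`.
#' @param sample_subset Optional character vector of sample ids.
#' @return A `haplotype_set`: list with `haplotypes` (list of id ->
#'   `sequence`, `multiplicity`, `members`) and `sample_map` (named vector
#'   sample -> haplotype id).
#' @export
collapse_haplotypes <- function(x, sample_subset = NULL) {
  aln <- if (inherits(x, "concat_dataset")) x$alignment else x
  mat <- aln$seq
  if (!is.null(sample_subset)) mat <- mat[sample_subset, , drop = FALSE]
  n <- nrow(mat)
  if (n < 1L) stop_ctx("need at least 1 sample", class = "config_error")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  unamb <- matrix(is_unambiguous(mat), n, ncol(mat))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ok <- unamb[i, ] & unamb[j, ]
      if (!any(mat[i, ok] != mat[j, ok])) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), match(roots, unique(roots)))
  ids <- sprintf("H%d", seq_along(groups))
  haplos <- setNames(lapply(seq_along(groups), function(k) {
    members <- rownames(mat)[groups[[k]]]
    list(sequence = paste(mat[groups[[k]][1L], ], collapse = ""),
         multiplicity = length(members), members = members)
  }), ids)
  sample_map <- setNames(rep(ids, lengths(groups)),
                         rownames(mat)[unlist(groups)])
  structure(list(haplotypes = haplos,
                 sample_map = sample_map[rownames(mat)]),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("Haplotype set: ", length(x$haplotypes), " haplotypes over ",
      length(x$sample_map), " samples\n", sep = "")
  invisible(x)
}

# Hamming distance over mutually unambiguous columns, on character vectors.
hamming_dist <- function(a, b) {
  ok <- is_unambiguous(a) & is_unambiguous(b)
  sum(a[ok] != b[ok])
}

# pairwise Hamming matrix over a list of character-vector sequences
hamming_matrix <- function(seqs) {
  n <- length(seqs)
  D <- matrix(0, n, n)
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- hamming_dist(seqs[[i]], seqs[[j]])
  D
}

# Minimum spanning network over a distance matrix: the union of all minimum
# spanning trees, plus (epsilon > 0) edges within epsilon of the connection
# threshold. Edge (i,j) belongs iff d_ij <= minimax(i,j) + epsilon, where
# minimax is the single-linkage cophenetic (largest step on the best path).
msn_edges <- function(D, epsilon = 0) {
  n <- nrow(D)
  if (n == 2L) return(matrix(c(1L, 2L), 1L, 2L))
  hc <- hclust(as.dist(D), method = "single")
  mm <- as.matrix(stats::cophenetic(hc))
  which(upper.tri(D) & D <= mm + epsilon + 1e-12, arr.ind = TRUE)
}

# per-site majority median of three sequences; NULL when some varying site
# lacks a majority (three distinct states, or a tie among unambiguous
# states). Missing characters are ignored; all-missing sites give N.
majority_median <- function(a, b, c) {
  L <- length(a)
  out <- character(L)
  for (s in seq_len(L)) {
    states <- c(a[s], b[s], c[s])
    states <- states[is_unambiguous(states)]
    if (!length(states)) { out[s] <- "N"; next }
    tab <- table(states)
    if (max(tab) >= 2L) { out[s] <- names(tab)[which.max(tab)]; next }
    if (length(tab) == 1L) { out[s] <- names(tab); next }
    return(NULL)
  }
  out
}

#' Median-joining haplotype network
#'
#' Builds a Bandelt-style median-joining network: (1) pairwise Hamming
#' distances over mutually unambiguous columns; (2) the minimum spanning
#' network (union of all minimum spanning trees, widened by `epsilon`);
#' (3) iterative addition of per-site-majority median vectors of connected
#' triplets when novel and cost-reducing; (4) pruning of median vectors with
#' degree <= 2. The quasi-median step is restricted to per-site majorities —
#' triplets with a three-state site contribute no median.
#'
#' @param haplotypes A `haplotype_set` (needs >= 2 haplotypes).
#' @param epsilon Non-negative tolerance widening the spanning network
#'   (default 0, the usual default).
#' @param max_rounds Safety cap on median-addition rounds.
#' @return An `igraph` graph; vertex attributes `name`, `type`
#'   (`"observed"`/`"median"`), `multiplicity`, `samples`
#'   (comma-joined); edge attribute `weight` (mutation count).
#' @export
median_joining_network <- function(haplotypes, epsilon = 0, max_rounds = 20L) {
  stopifnot(inherits(haplotypes, "haplotype_set"))
  hap <- haplotypes$haplotypes
  if (length(hap) < 2L) stop_ctx("need at least 2 haplotypes", class = "config_error")
  seqs <- lapply(hap, function(h) strsplit(h$sequence, "")[[1L]])
  names(seqs) <- names(hap)
  n_obs <- length(seqs)
  med_i <- 0L

  for (round in seq_len(max_rounds)) {
    D <- hamming_matrix(seqs)
    ed <- msn_edges(D, epsilon)
    adj <- lapply(seq_along(seqs), function(i)
      sort(unique(c(ed[ed[, 1L] == i, 2L], ed[ed[, 2L] == i, 1L]))))
    new_meds <- list()
    for (v in seq_along(seqs)) {
      nb <- adj[[v]]
      if (length(nb) < 2L) next
      for (pair in utils::combn(nb, 2L, simplify = FALSE)) {
        u <- pair[1L]; w <- pair[2L]
        m <- majority_median(seqs[[u]], seqs[[v]], seqs[[w]])
        if (is.null(m)) next
        ms <- paste(m, collapse = "")
        if (ms %in% vapply(seqs, paste, character(1), collapse = "") ||
            ms %in% vapply(new_meds, paste, character(1), collapse = "")) next
        cost_new <- hamming_dist(seqs[[u]], m) + hamming_dist(seqs[[v]], m) +
          hamming_dist(seqs[[w]], m)
        cost_old <- D[u, v] + D[v, w]
        if (cost_new < cost_old) new_meds[[length(new_meds) + 1L]] <- m
      }
    }
    if (!length(new_meds)) break
    for (m in new_meds) {
      med_i <- med_i + 1L
      seqs[[sprintf("MV%d", med_i)]] <- m
    }
  }

  # prune median vectors of degree <= 2, recomputing the network each pass
  repeat {
    D <- hamming_matrix(seqs)
    ed <- msn_edges(D, epsilon)
    deg <- tabulate(c(ed[, 1L], ed[, 2L]), nbins = length(seqs))
    is_med <- seq_along(seqs) > n_obs
    drop <- which(is_med & deg <= 2L)
    if (!length(drop)) break
    seqs <- seqs[-drop]
  }

  g <- igraph::graph_from_edgelist(
    cbind(names(seqs)[ed[, 1L]], names(seqs)[ed[, 2L]]), directed = FALSE)
  igraph::E(g)$weight <- D[ed]
  vn <- igraph::V(g)$name
  igraph::V(g)$type <- ifelse(startsWith(vn, "MV"), "median", "observed")
  igraph::V(g)$multiplicity <- vapply(vn, function(v)
    if (startsWith(v, "MV")) 0L else hap[[v]]$multiplicity, integer(1))
  igraph::V(g)$samples <- vapply(vn, function(v)
    if (startsWith(v, "MV")) "" else paste(hap[[v]]$members, collapse = ","),
    character(1))
  if (igraph::components(g)$no != 1L || length(vn) != length(seqs))
    stop_ctx("internal error: median-joining network is disconnected",
             class = "internal_error")
  g
}

#' Node composition table for network colouring
#'
#' @param haplotypes A `haplotype_set`.
#' @param metadata Data.frame with `sample_id`, `taxon`, `population`.
#' @return Data.frame: haplotype, multiplicity, taxa, populations.
#' @export
haplotype_composition <- function(haplotypes, metadata) {
  do.call(rbind, lapply(names(haplotypes$haplotypes), function(h) {
    members <- haplotypes$haplotypes[[h]]$members
    md <- metadata[metadata$sample_id %in% members, ]
    data.frame(haplotype = h, multiplicity = length(members),
               taxa = paste(sort(unique(md$taxon)), collapse = ","),
               populations = paste(sort(unique(md$population)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

#' Write a haplotype network as GML and an edge-list TSV
#'
#' @param g Network from [median_joining_network()].
#' @param gml_path,tsv_path Output paths (NULL to skip either).
#' @export
write_network <- function(g, gml_path = NULL, tsv_path = NULL) {
  if (!is.null(gml_path)) igraph::write_graph(g, gml_path, format = "gml")
  if (!is.null(tsv_path)) {
    el <- igraph::as_edgelist(g)
    df <- data.frame(from = el[, 1L], to = el[, 2L],
                     mutations = igraph::E(g)$weight)
    write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(g)
}
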