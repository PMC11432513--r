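#' Neighbor-joining tree from a K2P distance matrix
#'
#' Standard Saitou–Nei agglomeration (via \code{ape::nj}), followed by a
#' clean-up pass: negative branch lengths are clamped to 0 and the negative
#' excess is moved onto the adjacent branch (the parent branch of the node,
#' or a sibling branch at the root), preserving path lengths approximately.
#'
#' @param D Symmetric distance matrix with labels; masked (NA) pairs are not
#'   allowed.
#' @return An object of class `phylo`.
#' @export
nj_tree <- function(D) {
  if (any(is.na(D)))
    stop_ctx("distance matrix contains masked pairs; NJ needs complete distances",
             class = "distance_error")
  if (nrow(D) < 3L) stop_ctx("NJ needs at least 3 labels", class = "config_error")
  tr <- ape::nj(as.dist(D))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    excess <- tr$edge.length[e]   # negative
    tr$edge.length[e] <- 0
    node <- tr$edge[e, 1L]        # parent end of the negative edge
    adj <- setdiff(which(tr$edge[, 1L] == node | tr$edge[, 2L] == node), e)
    if (length(adj))
      tr$edge.length[adj[1L]] <- max(0, tr$edge.length[adj[1L]] + excess)
  }
  tr
}

# Canonical bipartition keys for every internal edge of an unrooted tree:
# the leaf set on the side NOT containing the reference leaf (the first
# label alphabetically), as a sorted "|"-joined string. Returns a data.frame
# with edge index, key and side size; trivial splits (side < 2) included
# with is_informative = FALSE.
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1L]
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    desc[[par]] <- c(desc[[par]], desc[[child]])
  }
  edges <- seq_len(nrow(tree$edge))
  keys <- character(length(edges)); sizes <- integer(length(edges))
  keys_child <- character(length(edges))
  for (e in edges) {
    child_side <- desc[[tree$edge[e, 2L]]]
    keys_child[e] <- paste(sort(child_side), collapse = "|")
    side <- child_side
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    keys[e] <- paste(sort(side), collapse = "|")
    sizes[e] <- length(side)
  }
  data.frame(edge = edges, key = keys, key_child = keys_child, size = sizes,
             is_informative = sizes >= 2L & sizes <= ntip - 2L,
             stringsAsFactors = FALSE)
}

#' Bootstrap supports for an NJ (or other distance) tree
#'
#' Resamples alignment columns with replacement, recomputes the K2P matrix
#' and tree per replicate, and annotates each internal edge of the full-data
#' tree with the percentage of retained replicates containing its
#' bipartition. Replicates producing a saturated (masked) pair are dropped
#' with a message; if more than 10\% are dropped, an error is raised.
#'
#' @param x A `concat_dataset` or `region_alignment`.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param tree_builder Function distance-matrix -> `phylo` (default
#'   [nj_tree()]).
#' @param sample_subset Optional sample ids.
#' @return A `phylo` with `node.label` holding supports (in [0, 100]) for
#'   internal nodes (root label empty).
#' @export
bootstrap_supports <- function(x, B = 1000L, seed = 1L,
                               tree_builder = nj_tree, sample_subset = NULL) {
  if (B < 1L) stop_ctx("B must be >= 1", class = "config_error")
  aln <- if (inherits(x, "concat_dataset")) x$alignment else x
  mat <- aln$seq
  if (!is.null(sample_subset)) mat <- mat[sample_subset, , drop = FALSE]
  base_aln <- region_alignment(mat, region = "boot", compartment = aln$compartment)
  D0 <- k2p_pairwise(base_aln)
  tree <- tree_builder(D0)
  bp <- tree_bipartitions(tree)
  counts <- setNames(rep(0L, nrow(bp)), bp$key)
  set.seed(seed)
  kept <- 0L; dropped <- 0L
  L <- ncol(mat)
  for (b in seq_len(B)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- region_alignment(mat[, cols, drop = FALSE], region = "rep",
                                compartment = aln$compartment)
    Db <- withCallingHandlers(
      tryCatch(k2p_pairwise(rep_aln), distance_error = function(e) NULL),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(Db) || any(is.na(Db))) { dropped <- dropped + 1L; next }
    kept <- kept + 1L
    keys_b <- unique(tree_bipartitions(tree_builder(Db))$key)
    hit <- bp$key %in% keys_b
    counts[hit] <- counts[hit] + 1L
  }
  if (dropped > 0L) message(dropped, " bootstrap replicate(s) dropped (saturation)")
  if (dropped > 0.1 * B)
    stop_ctx("more than 10% of bootstrap replicates dropped", class = "bootstrap_error")
  support <- 100 * counts / kept
  ntip <- length(tree$tip.label)
  node_lab <- rep("", tree$Nnode)
  for (e in which(tree$edge[, 2L] > ntip)) {
    node_lab[tree$edge[e, 2L] - ntip] <-
      formatC(support[[bp$key[e]]], format = "g")
  }
  tree$node.label <- node_lab
  attr(tree, "replicates_kept") <- kept
  tree
}

#' Read / write a support-annotated newick tree
#'
#' The default dialect stores bootstrap supports as internal node labels
#' (`(a,b)95:0.1`). The `branch` dialect stores them as bracketed comments
#' after the branch length (`(a,b):0.1[95]`).
#'
#' @param path File path.
#' @param dialect `"node"` or `"branch"`.
#' @return A `phylo` with numeric-coercible `node.label` supports.
#' @export
read_support_tree <- function(path, dialect = c("node", "branch")) {
  dialect <- match.arg(dialect)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (dialect == "branch") {
    # move [support] comments onto node labels: ")\:len[95]" -> ")95:len"
    txt <- gsub("\\)(:[0-9eE.+-]+)\\[([0-9.]+)\\]", ")\\2\\1", txt)
    txt <- gsub("\\[[^]]*\\]", "", txt)
  }
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop_ctx("unreadable newick: ", path, class = "format_error")
  tree
}

#' @rdname read_support_tree
#' @param tree A `phylo` with `node.label` supports.
#' @export
write_support_tree <- function(tree, path, dialect = c("node", "branch")) {
  dialect <- match.arg(dialect)
  if (dialect == "node") {
    ape::write.tree(tree, file = path)
  } else {
    txt <- ape::write.tree(tree)
    # ")label:len" -> "):len[label]"
    txt <- gsub("\\)([0-9.]+):([0-9eE.+-]+)", "):\\2[\\1]", txt)
    writeLines(txt, path)
  }
  invisible(path)
}

# numeric support of each edge of `tree` from its node labels (NA where
# absent); an edge's support is the label of its child node when internal.
edge_supports <- function(tree) {
  ntip <- length(tree$tip.label)
  sup <- rep(NA_real_, nrow(tree$edge))
  if (is.null(tree$node.label)) return(sup)
  lab <- suppressWarnings(as.numeric(tree$node.label))
  internal <- tree$edge[, 2L] > ntip
  sup[internal] <- lab[tree$edge[internal, 2L] - ntip]
  sup
}

#' Tree-based delimitation criterion for one taxon
#'
#' A taxon is successfully delimited when some internal edge of the tree
#' induces a bipartition with one side exactly equal to the taxon's samples
#' AND that edge's bootstrap support strictly exceeds `support_threshold`.
#' Monophyly is assessed on unrooted bipartitions, avoiding any rooting
#' assumption.
#'
#' @param tree A `phylo` whose tips are sample ids, with supports in
#'   `node.label`.
#' @param metadata Data.frame with `sample_id` and `taxon`.
#' @param taxon Taxon name to assess.
#' @param support_threshold Support must strictly exceed this (default 50).
#' @return List with `verdict` (`"success"`, `"failure"` or
#'   `"not_assessable"`), `monophyletic`, `support` (best support of a
#'   matching edge, NA if none) and `smallest_containing_clade` size.
#' @export
taxon_monophyly <- function(tree, metadata, taxon, support_threshold = 50) {
  samples <- metadata$sample_id[metadata$taxon == taxon]
  miss <- setdiff(samples, tree$tip.label)
  if (length(miss))
    stop_ctx("taxon '", taxon, "' sample(s) not in tree: ",
             paste(miss, collapse = ", "), class = "config_error")
  if (length(samples) < 2L)
    return(list(verdict = "not_assessable", monophyletic = NA,
                support = NA_real_, smallest_containing_clade = 1L))
  ref <- sort(tree$tip.label)[1L]
  target <- if (ref %in% samples) {
    paste(sort(setdiff(tree$tip.label, samples)), collapse = "|")
  } else {
    paste(sort(samples), collapse = "|")
  }
  bp <- tree_bipartitions(tree)
  sup <- edge_supports(tree)
  hit <- which(bp$key == target)
  if (length(hit)) {
    # A 2-child root duplicates one unrooted bipartition on two edges whose
    # labels can disagree; the support evidencing the taxon's monophyly is
    # the label of its own clade edge (child side == the taxon's samples),
    # falling back to the mirror edge only when that label is absent.
    key_samples <- paste(sort(samples), collapse = "|")
    own <- hit[bp$key_child[hit] == key_samples]
    best <- if (length(own) && any(!is.na(sup[own]))) {
      max(sup[own], na.rm = TRUE)
    } else {
      suppressWarnings(max(sup[hit], na.rm = TRUE))
    }
    if (!is.finite(best)) best <- NA_real_
    ok <- !is.na(best) && best > support_threshold
    return(list(verdict = if (ok) "success" else "failure",
                monophyletic = TRUE, support = best,
                smallest_containing_clade = length(samples)))
  }
  # smallest clade (bipartition side) containing all of the taxon's samples
  ntip <- length(tree$tip.label)
  sizes <- ntip
  for (e in seq_len(nrow(bp))) {
    side <- strsplit(bp$key[e], "|", fixed = TRUE)[[1L]]
    for (s in list(side, setdiff(tree$tip.label, side))) {
      if (all(samples %in% s)) sizes <- min(sizes, length(s))
    }
  }
  list(verdict = "failure", monophyletic = FALSE, support = NA_real_,
       smallest_containing_clade = sizes)
}
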