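#' Kimura 2-parameter distance between two aligned sequences
#'
#' Computes d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q)), where P and Q are
#' the proportions of transition and transversion differences over
#' pairwise-complete sites. Sites where either base is a gap, N or IUPAC
#' ambiguity code are excluded (pairwise deletion).
#'
#' @param a,b Character vectors of single characters, or single strings, of
#'   equal length.
#' @return Non-negative distance (substitutions/site).
#' @export
k2p_distance <- function(a, b) {
  if (length(a) == 1L && nchar(a) > 1L) a <- strsplit(a, "")[[1L]]
  if (length(b) == 1L && nchar(b) > 1L) b <- strsplit(b, "")[[1L]]
  a <- toupper(a); b <- toupper(b)
  if (length(a) != length(b))
    stop_ctx("sequences must have equal length", class = "alignment_error")
  ok <- is_unambiguous(a) & is_unambiguous(b)
  n <- sum(ok)
  if (n == 0L) stop_ctx("no pairwise-complete sites", class = "distance_error")
  k2p_from_PQ(p_q_counts(a[ok], b[ok]) / n)
}

# transition / transversion difference counts over unambiguous site pairs
p_q_counts <- function(a, b) {
  diff <- a != b
  if (!any(diff)) return(c(P = 0, Q = 0))
  pur_a <- a %in% PURINES
  pur_b <- b %in% PURINES
  ts <- diff & (pur_a == pur_b)   # same chemical class, different base
  c(P = sum(ts), Q = sum(diff & !ts))
}

k2p_from_PQ <- function(pq) {
  P <- pq[["P"]]; Q <- pq[["Q"]]
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop_ctx("K2P saturation: distance undefined (P=", signif(P, 4),
             ", Q=", signif(Q, 4), ")", class = "saturation_error")
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise K2P distance matrix
#'
#' All unordered sample pairs are computed under pairwise deletion.
#' Saturated pairs (where the K2P logarithm is undefined) are masked as NA
#' with a warning rather than clamped; downstream analyses must treat masked
#' pairs as unavailable.
#'
#' @param x A `concat_dataset` or `region_alignment`.
#' @param sample_subset Optional character vector of sample ids.
#' @return A symmetric numeric matrix with zero diagonal, labelled by
#'   sample id, with attribute `n_masked` (count of masked pairs).
#' @export
k2p_pairwise <- function(x, sample_subset = NULL) {
  aln <- if (inherits(x, "concat_dataset")) x$alignment else x
  mat <- aln$seq
  if (!is.null(sample_subset)) mat <- mat[sample_subset, , drop = FALSE]
  n <- nrow(mat)
  if (n < 2L) stop_ctx("need at least 2 samples", class = "config_error")
  ids <- rownames(mat)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  ok_mat <- matrix(is_unambiguous(mat), n, ncol(mat))
  masked <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- ok_mat[i, ] & ok_mat[j, ]
      nn <- sum(ok)
      if (nn == 0L)
        stop_ctx("sample pair ", ids[i], " / ", ids[j],
                 " has zero comparable sites", class = "distance_error")
      d <- tryCatch(k2p_from_PQ(p_q_counts(mat[i, ok], mat[j, ok]) / nn),
                    saturation_error = function(e) NA_real_)
      if (is.na(d)) masked <- masked + 1L
      D[i, j] <- D[j, i] <- d
    }
  }
  if (masked > 0L)
    warning(masked, " saturated pair(s) masked as NA in K2P matrix")
  attr(D, "n_masked") <- masked
  D
}

#' Population-level K2P divergence with column bootstrap
#'
#' The between-population mean is the average K2P distance over all
#' cross-population sample pairs (within-population means over within pairs);
#' standard errors come from resampling alignment columns with replacement.
#'
#' @param x A `concat_dataset` or `region_alignment`.
#' @param metadata Data.frame with `sample_id` and `population`.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return List with `mean` (symmetric population matrix; diagonal =
#'   within-population mean, NA for single-sample populations) and `se`
#'   (same shape, bootstrap SEs).
#' @export
population_divergence <- function(x, metadata, B = 1000L, seed = 1L) {
  if (B < 1L) stop_ctx("B must be >= 1", class = "config_error")
  aln <- if (inherits(x, "concat_dataset")) x$alignment else x
  mat <- aln$seq[metadata$sample_id, , drop = FALSE]
  n <- nrow(mat); L <- ncol(mat)
  pops <- unique(metadata$population)
  pop_of <- setNames(metadata$population, metadata$sample_id)

  pairs <- combn(rownames(mat), 2L)
  np <- ncol(pairs)
  # per-pair, per-column indicator matrices: valid site, transition diff,
  # transversion diff — so bootstrap means are weighted matrix products
  VALID <- TS <- TV <- matrix(FALSE, np, L)
  unamb <- matrix(is_unambiguous(mat), n, L, dimnames = list(rownames(mat), NULL))
  pur <- matrix(mat %in% PURINES, n, L)
  rownames(pur) <- rownames(mat)
  for (k in seq_len(np)) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    ok <- unamb[i, ] & unamb[j, ]
    df <- ok & (mat[i, ] != mat[j, ])
    ts <- df & (pur[i, ] == pur[j, ])
    VALID[k, ] <- ok; TS[k, ] <- ts; TV[k, ] <- df & !ts
  }

  pair_pop <- rbind(pop_of[pairs[1L, ]], pop_of[pairs[2L, ]])
  mean_of <- function(w) {
    nv <- as.numeric(VALID %*% w)
    P <- as.numeric(TS %*% w) / nv
    Q <- as.numeric(TV %*% w) / nv
    w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
    d <- ifelse(w1 > 0 & w2 > 0, -0.5 * log(w1 * sqrt(pmax(w2, 0))), NA_real_)
    M <- matrix(NA_real_, length(pops), length(pops), dimnames = list(pops, pops))
    for (a in seq_along(pops)) for (b in seq_len(a)) {
      sel <- (pair_pop[1L, ] == pops[a] & pair_pop[2L, ] == pops[b]) |
             (pair_pop[1L, ] == pops[b] & pair_pop[2L, ] == pops[a])
      if (any(sel)) M[a, b] <- M[b, a] <- mean(d[sel])
    }
    M
  }

  obs <- mean_of(rep(1, L))
  set.seed(seed)
  boots <- array(NA_real_, c(length(pops), length(pops), B))
  for (b in seq_len(B)) {
    w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
    boots[, , b] <- mean_of(w)
  }
  se <- apply(boots, c(1, 2), sd)
  dimnames(se) <- dimnames(obs)
  list(mean = obs, se = se, B = B)
}

#' Write a square labelled distance matrix as TSV
#'
#' @param D Numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_distance_tsv <- function(D, path) {
  df <- data.frame(sample = rownames(D), D, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Combined lower/upper-triangle population-divergence table
#'
#' Renders a heat-map-style table where the lower triangle holds distances
#' from one data set (e.g. divergence hotspot regions) and the upper triangle
#' distances from another (e.g. plastid intergenic regions).
#'
#' @param lower,upper Symmetric population matrices with identical dimnames.
#' @return Matrix with mixed triangles (diagonal NA).
#' @export
combine_triangles <- function(lower, upper) {
  stopifnot(identical(dimnames(lower), dimnames(upper)))
  M <- matrix(NA_real_, nrow(lower), ncol(lower), dimnames = dimnames(lower))
  M[lower.tri(M)] <- lower[lower.tri(lower)]
  M[upper.tri(M)] <- upper[upper.tri(upper)]
  M
}
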