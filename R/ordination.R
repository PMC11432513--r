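#' Principal coordinate analysis of a distance matrix
#'
#' Classical (Gower) scaling via double-centering of -D^2/2 and
#' eigendecomposition (\code{stats::cmdscale}). Coordinates are eigenvectors
#' scaled by the square root of their (positive) eigenvalues; axes with
#' non-positive eigenvalues are dropped and reported. No Lingoes/Cailliez
#' correction is applied; the magnitude of negative eigenvalues is returned
#' so distortion can be judged. The sign of each axis is fixed by forcing
#' its largest-magnitude loading positive.
#'
#' @param D Symmetric distance matrix (no masked pairs, >= 3 samples).
#' @param k Number of axes requested (default 2); truncated with a warning
#'   if fewer positive eigenvalues exist.
#' @return A `pcoa_result`: list with `coordinates` (samples x axes, centered),
#'   `eigenvalues` (all, descending), `pct_variance` (per positive axis, of
#'   the positive-eigenvalue total), `negative_eigenvalues`.
#' @export
pcoa_k2p <- function(D, k = 2L) {
  if (any(is.na(D))) stop_ctx("masked pairs in distance matrix", class = "distance_error")
  n <- nrow(D)
  if (n < 3L) stop_ctx("PCoA needs at least 3 samples", class = "config_error")
  full <- suppressWarnings(cmdscale(as.dist(D), k = n - 1L, eig = TRUE))
  eig <- full$eig
  n_pos <- sum(eig > 1e-12)
  if (n_pos == 0L) {
    coords <- matrix(0, n, k, dimnames = list(rownames(D), paste0("Axis", seq_len(k))))
    return(structure(list(coordinates = coords, eigenvalues = eig,
                          pct_variance = rep(0, k),
                          negative_eigenvalues = eig[eig < 0]),
                     class = "pcoa_result"))
  }
  if (k > n_pos) {
    warning("k = ", k, " exceeds the number of positive eigenvalues (",
            n_pos, "); truncating")
    k <- n_pos
  }
  coords <- full$points[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive on each axis
  for (a in seq_len(k)) {
    i <- which.max(abs(coords[, a]))
    if (coords[i, a] < 0) coords[, a] <- -coords[, a]
  }
  colnames(coords) <- paste0("Axis", seq_len(k))
  rownames(coords) <- rownames(D)
  structure(list(coordinates = coords, eigenvalues = eig,
                 pct_variance = 100 * eig[seq_len(k)] / sum(eig[eig > 0]),
                 negative_eigenvalues = eig[eig < 0]),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA: ", nrow(x$coordinates), " samples, ", ncol(x$coordinates),
      " axes (", paste(sprintf("%.1f%%", x$pct_variance), collapse = ", "),
      " of positive-eigenvalue variance)\n", sep = "")
  if (length(x$negative_eigenvalues))
    cat("  negative eigenvalues down to ", min(x$negative_eigenvalues), "\n", sep = "")
  invisible(x)
}

#' Write PCoA coordinates joined with sample metadata
#'
#' @param res A `pcoa_result`.
#' @param metadata Data.frame with `sample_id`, `taxon`, `population`.
#' @param path Output TSV path.
#' @export
write_pcoa_tsv <- function(res, metadata, path) {
  df <- data.frame(sample_id = rownames(res$coordinates), res$coordinates)
  df <- merge(df, metadata, by = "sample_id", sort = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
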