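#' Construct a region alignment
#'
#' A region alignment holds one aligned genetic region (plastid gene, plastid
#' spacer, mitochondrial gene or nrDNA part) over a common sample set, as a
#' character matrix of single upper-case characters (rows = samples,
#' columns = alignment sites).
#'
#' @param seqs Character matrix (rows named by sample) or a named character
#'   vector of equal-length sequence strings.
#' @param region Region name.
#' @param compartment One of `"plastid_gene"`, `"plastid_spacer"`,
#'   `"mito_gene"`, `"nrDNA_part"`.
#' @return An object of class `region_alignment`.
#' @export
region_alignment <- function(seqs, region = "region",
                             compartment = c("plastid_gene", "plastid_spacer",
                                             "mito_gene", "nrDNA_part")) {
  compartment <- match.arg(compartment)
  if (is.character(seqs) && !is.matrix(seqs)) {
    if (is.null(names(seqs))) stop_ctx("sequences must be named by sample", class = "format_error")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L)
      stop_ctx("unequal sequence lengths in region '", region, "'", class = "alignment_error")
    mat <- do.call(rbind, strsplit(seqs, ""))
    rownames(mat) <- names(seqs)
    seqs <- mat
  }
  if (!is.matrix(seqs) || is.null(rownames(seqs)))
    stop_ctx("seqs must be a matrix with sample rownames", class = "format_error")
  if (anyDuplicated(rownames(seqs)))
    stop_ctx("duplicate sample ids in region '", region, "'", class = "format_error")
  mat <- toupper(seqs)
  mat[mat == "U"] <- "T"
  structure(list(region = region, compartment = compartment, seq = mat),
            class = "region_alignment")
}

#' @export
print.region_alignment <- function(x, ...) {
  cat("Region alignment '", x$region, "' (", x$compartment, "): ",
      nrow(x$seq), " samples x ", ncol(x$seq), " sites\n", sep = "")
  invisible(x)
}

aln_samples <- function(x) rownames(x$seq)
aln_length <- function(x) ncol(x$seq)

#' Read an aligned FASTA file
#'
#' Reads a multi-FASTA file of equal-length sequences. Bases are upper-cased
#' and U is mapped to T. Ragged lengths, duplicate headers and empty files
#' are rejected.
#'
#' @param path Path to a FASTA file.
#' @inheritParams region_alignment
#' @return A `region_alignment`.
#' @export
read_fasta_alignment <- function(path, region = NULL,
                                 compartment = "plastid_gene") {
  if (!file.exists(path)) stop_ctx("file not found: ", path, class = "format_error")
  seqs <- tryCatch(seqinr::read.fasta(path, seqtype = "DNA", as.string = FALSE,
                                      forceDNAtolower = FALSE),
                   error = function(e)
                     stop_ctx("empty or malformed FASTA file: ", path,
                              class = "format_error"))
  if (length(seqs) == 0L) stop_ctx("empty FASTA file: ", path, class = "format_error")
  if (anyDuplicated(names(seqs)))
    stop_ctx("duplicate FASTA headers in ", path, class = "format_error")
  lens <- lengths(seqs)
  if (length(unique(lens)) > 1L)
    stop_ctx("unequal sequence lengths in ", path, " (", paste(unique(lens), collapse = ", "), ")",
             class = "alignment_error")
  mat <- do.call(rbind, lapply(seqs, as.character))
  rownames(mat) <- names(seqs)
  region_alignment(mat,
                   region = region %||% sub("\\.(fa|fasta|fas)$", "", basename(path)),
                   compartment = compartment)
}

#' Write a region alignment (or concatenated data set) to FASTA
#'
#' @param x A `region_alignment` or `concat_dataset`.
#' @param path Output path.
#' @export
write_fasta_alignment <- function(x, path) {
  if (inherits(x, "concat_dataset")) x <- x$alignment
  stopifnot(inherits(x, "region_alignment"))
  dna <- ape::as.DNAbin(x$seq)
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects a TSV with columns `sample_id`, `taxon`, `population`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the three columns as character.
#' @export
read_sample_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "taxon", "population")
  if (!all(need %in% names(md)))
    stop_ctx("metadata must have columns sample_id, taxon, population", class = "format_error")
  if (anyDuplicated(md$sample_id))
    stop_ctx("duplicate sample_id in metadata", class = "format_error")
  md[need]
}

#' Concatenate region alignments into a supermatrix
#'
#' Columns are appended in the given region order; the partition map records
#' the 0-based half-open column span of every region. The sample order of the
#' first region is used throughout.
#'
#' @param regions List of `region_alignment` objects.
#' @param code Data-set code (conventionally one of A–G).
#' @param pad_missing If `TRUE`, samples missing from a region are filled with
#'   N over that region's span instead of raising an error.
#' @return A `concat_dataset`: list with `code`, `alignment`
#'   (a `region_alignment`) and `partition_map`
#'   (data.frame `region`, `start`, `end`).
#' @export
concatenate_regions <- function(regions, code = "X", pad_missing = FALSE) {
  stopifnot(length(regions) >= 1L)
  all_samples <- aln_samples(regions[[1L]])
  union_samples <- unique(unlist(lapply(regions, aln_samples)))
  if (!pad_missing) {
    for (r in regions) {
      miss <- setdiff(union_samples, aln_samples(r))
      if (length(miss))
        stop_ctx("sample(s) ", paste(miss, collapse = ", "),
                 " missing from region '", r$region, "'", class = "missing_sample_error")
    }
  } else {
    all_samples <- union_samples
  }
  lens <- vapply(regions, aln_length, integer(1))
  ends <- cumsum(lens)
  starts <- c(0L, ends[-length(ends)])
  total <- sum(lens)
  mat <- matrix("N", nrow = length(all_samples), ncol = total,
                dimnames = list(all_samples, NULL))
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    present <- intersect(all_samples, aln_samples(r))
    mat[present, (starts[i] + 1L):ends[i]] <- r$seq[present, , drop = FALSE]
  }
  pm <- data.frame(region = vapply(regions, function(r) r$region, character(1)),
                   start = starts, end = ends, stringsAsFactors = FALSE)
  structure(list(code = code,
                 alignment = region_alignment(mat, region = paste0("set_", code),
                                              compartment = regions[[1L]]$compartment),
                 partition_map = pm),
            class = "concat_dataset")
}

#' @export
print.concat_dataset <- function(x, ...) {
  cat("Concatenated data set ", x$code, ": ",
      nrow(x$alignment$seq), " samples x ", ncol(x$alignment$seq), " sites, ",
      nrow(x$partition_map), " regions\n", sep = "")
  invisible(x)
}

#' Slice one region back out of a concatenated data set
#'
#' @param ds A `concat_dataset`.
#' @param region Region name present in the partition map.
#' @return A `region_alignment` holding that region's columns.
#' @export
get_region <- function(ds, region) {
  pm <- ds$partition_map
  i <- match(region, pm$region)
  if (is.na(i)) stop_ctx("region '", region, "' not in partition map", class = "format_error")
  region_alignment(ds$alignment$seq[, (pm$start[i] + 1L):pm$end[i], drop = FALSE],
                   region = region, compartment = ds$alignment$compartment)
}

NRDNA_PARTS <- c("18S", "ITS1", "5.8S", "ITS2", "26S")

#' Assemble the ITS data set (ITS1–5.8S–ITS2)
#'
#' From the five nrDNA cistron parts (18S, ITS1, 5.8S, ITS2, 26S), builds the
#' ITS supermatrix (set E) from ITS1, 5.8S and ITS2 only, in that order.
#'
#' @param parts Named list of `region_alignment`s; names (or region fields)
#'   must include ITS1, 5.8S and ITS2.
#' @return A `concat_dataset` with code `"E"`.
#' @export
extract_its <- function(parts) {
  sel <- find_parts(parts, c("ITS1", "5.8S", "ITS2"))
  concatenate_regions(sel, code = "E")
}

#' Assemble the full nrDNA cistron data set (18S–ITS1–5.8S–ITS2–26S)
#'
#' @inheritParams extract_its
#' @return A `concat_dataset` with code `"D"`.
#' @export
nrdna_cistron <- function(parts) {
  sel <- find_parts(parts, NRDNA_PARTS)
  concatenate_regions(sel, code = "D")
}

find_parts <- function(parts, wanted) {
  nm <- names(parts) %||% vapply(parts, function(p) p$region, character(1))
  if (is.null(names(parts))) names(parts) <- nm
  miss <- setdiff(wanted, nm)
  if (length(miss))
    stop_ctx("missing nrDNA part(s): ", paste(miss, collapse = ", "), class = "format_error")
  for (w in wanted) {
    if (aln_length(parts[[w]]) == 0L)
      stop_ctx("nrDNA part '", w, "' is empty", class = "format_error")
  }
  parts[wanted]
}

#' Default data-set definitions (codes A–G)
#'
#' Maps each data-set code to the region names it concatenates, following the
#' standard seven-set design: (A) plastid coding genes, (B) mitochondrial
#' coding genes, (C) plastid intergenic spacers, (D) the full nrDNA cistron,
#' (E) ITS (ITS1–5.8S–ITS2), (F) the core barcodes matK + rbcL, and
#' (G) divergence hotspot regions (rps1, rps2, rps14, ycf3-psaA, trnE-clpP).
#'
#' @param region_plan Data.frame with columns `region` and `compartment`
#'   (as produced by [default_region_plan()]).
#' @return Named list code -> character vector of region names.
#' @export
default_dataset_definitions <- function(region_plan) {
  stopifnot(all(c("region", "compartment") %in% names(region_plan)))
  list(
    A = region_plan$region[region_plan$compartment == "plastid_gene"],
    B = region_plan$region[region_plan$compartment == "mito_gene"],
    C = region_plan$region[region_plan$compartment == "plastid_spacer"],
    D = NRDNA_PARTS,
    E = c("ITS1", "5.8S", "ITS2"),
    F = c("matK", "rbcL"),
    G = c("rps1", "rps2", "rps14", "ycf3-psaA", "trnE-clpP")
  )
}

#' Build the concatenated data sets from region alignments
#'
#' @param regions Named list of `region_alignment`s (names = region names).
#' @param definitions Named list code -> region-name vector; see
#'   [default_dataset_definitions()].
#' @param pad_missing Passed to [concatenate_regions()].
#' @return Named list of `concat_dataset`s.
#' @export
build_datasets <- function(regions, definitions, pad_missing = FALSE) {
  out <- lapply(names(definitions), function(code) {
    wanted <- definitions[[code]]
    miss <- setdiff(wanted, names(regions))
    if (length(miss))
      stop_ctx("data set ", code, ": missing region(s) ",
               paste(miss, collapse = ", "), class = "format_error")
    concatenate_regions(regions[wanted], code = code, pad_missing = pad_missing)
  })
  setNames(out, names(definitions))
}
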