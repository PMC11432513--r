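test_that("FASTA alignments read back with normalisation and validation", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">s1", "acgtacgtACGT", ">s2", "ACGTACGTACGT", ">s3", "acgu-cgtNcgt"), f)
  r <- read_fasta_alignment(f, region = "x")
  expect_s3_class(r, "region_alignment")
  expect_equal(nrow(r$seq), 3L)
  expect_equal(ncol(r$seq), 12L)
  expect_identical(paste(r$seq["s1", ], collapse = ""), "ACGTACGTACGT")
  # U mapped to T, case folded, gaps and N preserved
  expect_identical(paste(r$seq["s3", ], collapse = ""), "ACGT-CGTNCGT")

  ragged <- tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGTACGTACGT", ">s2", "ACGTACGTACG"), ragged)
  expect_error(read_fasta_alignment(ragged), class = "alignment_error")

  dup <- tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGT", ">s1", "ACGT"), dup)
  expect_error(read_fasta_alignment(dup), class = "format_error")

  empty <- tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta_alignment(empty), class = "format_error")
})

test_that("write-then-read round-trips a concatenated data set", {
  aln <- make_aln(c("ACGTAC-TNA", "ACGAACGTTA", "ACGTACGTAA"))
  ds <- concatenate_regions(list(aln), code = "X")
  f <- tempfile(fileext = ".fasta")
  write_fasta_alignment(ds, f)
  back <- read_fasta_alignment(f)
  expect_identical(back$seq, ds$alignment$seq)
})

test_that("concatenation builds correct spans and handles missing samples", {
  r1 <- make_aln(c("ACGT", "ACGA", "ACGG"), region = "r1")
  r2 <- make_aln(c("TTTTTT", "TTTTTA", "TTTTTC"), region = "r2")
  ds <- concatenate_regions(list(r1, r2), code = "A")
  expect_equal(ncol(ds$alignment$seq), 10L)
  expect_equal(ds$partition_map$start, c(0L, 4L))
  expect_equal(ds$partition_map$end, c(4L, 10L))
  # partition-map slicing reconstructs the original regions
  expect_identical(get_region(ds, "r1")$seq, r1$seq)
  expect_identical(get_region(ds, "r2")$seq, r2$seq)

  r2_missing <- make_aln(c("TTTTTT", "TTTTTA"), region = "r2",
                         samples = c("s1", "s2"))
  expect_error(concatenate_regions(list(r1, r2_missing), code = "A"),
               class = "missing_sample_error")
  padded <- concatenate_regions(list(r1, r2_missing), code = "A",
                                pad_missing = TRUE)
  expect_identical(paste(padded$alignment$seq["s3", 5:10], collapse = ""),
                   "NNNNNN")
  expect_identical(paste(padded$alignment$seq["s3", 1:4], collapse = ""), "ACGG")
})

test_that("concatenated total length equals the sum of region lengths", {
  set.seed(42)
  lens <- sample(5:40, 12)
  regions <- lapply(seq_along(lens), function(i) {
    mat <- matrix(sample(c("A", "C", "G", "T"), 4 * lens[i], replace = TRUE),
                  4, lens[i], dimnames = list(sprintf("s%d", 1:4), NULL))
    region_alignment(mat, region = sprintf("r%d", i))
  })
  ds <- concatenate_regions(regions, code = "A")
  expect_equal(ncol(ds$alignment$seq), sum(lens))
  expect_true(all(diff(c(0L, ds$partition_map$end)) == lens))
  expect_equal(ds$partition_map$start[-1], ds$partition_map$end[-length(lens)])
})

test_that("nrDNA assembly: ITS is ITS1-5.8S-ITS2; the cistron is all five parts", {
  lens <- c("18S" = 1812L, "ITS1" = 2482L, "5.8S" = 158L, "ITS2" = 241L,
            "26S" = 3155L)
  parts <- lapply(names(lens), function(p) {
    mat <- matrix("A", 2, lens[[p]], dimnames = list(c("s1", "s2"), NULL))
    region_alignment(mat, region = p, compartment = "nrDNA_part")
  })
  names(parts) <- names(lens)
  E <- extract_its(parts)
  expect_equal(ncol(E$alignment$seq), 2881L)
  expect_equal(E$partition_map$region, c("ITS1", "5.8S", "ITS2"))
  D <- nrdna_cistron(parts)
  expect_equal(ncol(D$alignment$seq), 7848L)
  expect_equal(D$partition_map$region, c("18S", "ITS1", "5.8S", "ITS2", "26S"))

  expect_error(extract_its(parts[c("18S", "ITS1", "5.8S")]),
               class = "format_error", regexp = "ITS2")
  empty <- parts
  empty$ITS2 <- region_alignment(matrix(character(0), 2, 0,
                                        dimnames = list(c("s1", "s2"), NULL)),
                                 region = "ITS2", compartment = "nrDNA_part")
  expect_error(extract_its(empty), class = "format_error")
})

test_that("default data-set definitions cover A-G with the hotspot regions in G", {
  defs <- default_dataset_definitions(default_region_plan())
  expect_setequal(names(defs), LETTERS[1:7])
  expect_equal(defs$G, c("rps1", "rps2", "rps14", "ycf3-psaA", "trnE-clpP"))
  expect_equal(defs$E, c("ITS1", "5.8S", "ITS2"))
  expect_length(defs$A, 57L)
  expect_length(defs$B, 15L)
  expect_length(defs$C, 18L)
})
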