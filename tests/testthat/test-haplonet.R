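test_that("haplotype collapse: identity, distinctness, missing-tolerant merging", {
  h <- collapse_haplotypes(make_aln(rep("ACGTACGT", 4)))
  expect_length(h$haplotypes, 1L)
  expect_equal(h$haplotypes$H1$multiplicity, 4L)

  h2 <- collapse_haplotypes(make_aln(c("AAA", "AAT")))
  expect_length(h2$haplotypes, 2L)

  h3 <- collapse_haplotypes(make_aln(c("AAA", "AAN")))
  expect_length(h3$haplotypes, 1L)
  expect_equal(h3$haplotypes$H1$members, c("s1", "s2"))

  # multiplicities always sum to the sample count; members are disjoint
  set.seed(91)
  for (i in 1:10) {
    aln <- random_aln(10, 6, missing = 0.2)
    hs <- collapse_haplotypes(aln)
    expect_equal(sum(vapply(hs$haplotypes, `[[`, integer(1), "multiplicity")),
                 10L)
    members <- unlist(lapply(hs$haplotypes, `[[`, "members"))
    expect_false(anyDuplicated(members) > 0)
  }
})

test_that("median-joining: chain, cycle and star toy cases", {
  # chain A-B-C with unit edges, no medians
  g <- median_joining_network(collapse_haplotypes(make_aln(c("AAA", "AAT", "ATT"))))
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 2L)
  expect_equal(sort(unname(igraph::degree(g))), c(1, 1, 2))
  expect_true(all(igraph::E(g)$weight == 1))

  # 4-cycle of unit edges: candidate medians coincide with observed nodes
  g2 <- median_joining_network(collapse_haplotypes(make_aln(c("AA", "AT", "TA", "TT"))))
  expect_equal(igraph::vcount(g2), 4L)
  expect_equal(igraph::ecount(g2), 4L)
  expect_true(all(igraph::degree(g2) == 2))
  expect_true(all(igraph::E(g2)$weight == 1))

  # star: center plus 4 single-mutation satellites
  star <- make_aln(c("AAAA", "TAAA", "ACAA", "AAGA", "AAAC"))
  g3 <- median_joining_network(collapse_haplotypes(star))
  expect_equal(igraph::vcount(g3), 5L)
  expect_equal(igraph::ecount(g3), 4L)
  deg <- igraph::degree(g3)
  expect_equal(unname(deg[igraph::V(g3)$samples == "s1"]), 4)
})

test_that("a true median vector is inferred and kept at degree 3", {
  # three haplotypes pairwise distance 2; their majority median AAA links them
  g <- median_joining_network(collapse_haplotypes(make_aln(c("TAA", "ATA", "AAT"))))
  expect_equal(igraph::vcount(g), 4L)
  types <- igraph::V(g)$type
  expect_equal(sum(types == "median"), 1L)
  mv <- which(types == "median")
  expect_equal(unname(igraph::degree(g)[mv]), 3)
  expect_true(all(igraph::E(g)$weight == 1))
})

test_that("every observed haplotype is a node of a connected network", {
  set.seed(111)
  for (i in 1:15) {
    ds <- simulate_dataset(two_taxon_config(300L, 0.05, theta = 0.01,
                                            seed = 200 + i))
    cfg <- ds$config
    aln <- ds$regions$r1
    hs <- collapse_haplotypes(aln)
    if (length(hs$haplotypes) < 2L) next
    g <- median_joining_network(hs)
    expect_true(all(names(hs$haplotypes) %in% igraph::V(g)$name))
    expect_equal(igraph::components(g)$no, 1L)
    expect_true(all(igraph::E(g)$weight >= 1))
    # medians only persist with degree >= 3
    med <- igraph::V(g)$type == "median"
    if (any(med)) expect_true(all(igraph::degree(g)[med] >= 3))
  }
})

test_that("the spanning-network step matches an exhaustive minimax oracle", {
  # independent minimax-path oracle (Floyd-Warshall on the bottleneck
  # semiring): MSN edge iff direct distance <= minimax path distance
  minimax_oracle <- function(D) {
    mm <- D
    n <- nrow(D)
    for (k in 1:n) for (i in 1:n) for (j in 1:n)
      mm[i, j] <- min(mm[i, j], max(mm[i, k], mm[k, j]))
    mm
  }
  set.seed(121)
  for (i in 1:20) {
    aln <- random_aln(6, 30)
    hs <- collapse_haplotypes(aln)
    if (length(hs$haplotypes) < 3L) next
    g <- median_joining_network(hs)
    seqs <- lapply(hs$haplotypes, function(h) strsplit(h$sequence, "")[[1]])
    D <- barcodelim:::hamming_matrix(seqs)
    rownames(D) <- colnames(D) <- names(hs$haplotypes)
    mm <- minimax_oracle(D)
    oracle_edges <- which(upper.tri(D) & D <= mm + 1e-12, arr.ind = TRUE)
    oracle_keys <- apply(oracle_edges, 1, function(e)
      paste(sort(rownames(D)[e]), collapse = "-"))
    el <- igraph::as_edgelist(g)
    obs_edge <- !apply(el, 1, function(e) any(startsWith(e, "MV")))
    got_keys <- apply(el[obs_edge, , drop = FALSE], 1, function(e)
      paste(sort(e), collapse = "-"))
    if (!any(igraph::V(g)$type == "median")) {
      # without medians, the network IS the observed-haplotype MSN
      expect_setequal(got_keys, oracle_keys)
      # and its weight is bounded by the full MSN weight (union of MSTs)
      expect_lte(sum(igraph::E(g)$weight), sum(D[upper.tri(D) & D <= mm + 1e-12]))
    } else {
      # observed-observed edges that survive must still be MSN edges of the
      # observed-only oracle (medians only ever shorten connections)
      expect_true(all(got_keys %in% oracle_keys))
    }
  }
})

test_that("population-private organellar lineages give population-private haplotypes", {
  cfg <- simulation_config(
    species_tree = "(t1:0.01,t2:0.01);",
    populations_per_taxon = c(t1 = 3L, t2 = 3L),
    samples_per_population = 3L,
    region_plan = data.frame(region = "mt1", compartment = "mito_gene",
                             length = 800L, rate_multiplier = 3),
    within_population_theta = 0, population_divergence = 2e-3,
    hybrid_spec = NULL, seed = 77L)
  ds <- simulate_dataset(cfg)
  hs <- collapse_haplotypes(ds$regions$mt1)
  comp <- haplotype_composition(hs, ds$metadata)
  # each haplotype is confined to one population
  expect_false(any(grepl(",", comp$populations)))
})

test_that("network export writes GML and an edge list", {
  hs <- collapse_haplotypes(make_aln(c("AAA", "AAT", "ATT")))
  g <- median_joining_network(hs)
  gml <- tempfile(fileext = ".gml"); tsv <- tempfile(fileext = ".tsv")
  write_network(g, gml, tsv)
  expect_true(file.exists(gml))
  edges <- read.delim(tsv)
  expect_equal(nrow(edges), 2L)
  expect_equal(sort(edges$mutations), c(1L, 1L))
})
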