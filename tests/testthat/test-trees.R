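test_that("NJ on 3 taxa gives the closed-form branch lengths", {
  D <- matrix(c(0, 3, 5,
                3, 0, 6,
                5, 6, 0), 3, 3, dimnames = list(c("a", "b", "c"),
                                                c("a", "b", "c")))
  tr <- nj_tree(D)
  # b_a = (d_ab + d_ac - d_bc)/2 = 1, b_b = 2, b_c = 4
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["a"]], 1)
  expect_equal(lens[["b"]], 2)
  expect_equal(lens[["c"]], 4)
})

test_that("NJ recovers the additive quartet with its internal edge", {
  # unrooted quartet ab|cd: a:1, b:2, internal:1, c:3, d:4
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- D["b", "a"] <- 3
  D["a", "c"] <- D["c", "a"] <- 5
  D["a", "d"] <- D["d", "a"] <- 6
  D["b", "c"] <- D["c", "b"] <- 6
  D["b", "d"] <- D["d", "b"] <- 7
  D["c", "d"] <- D["d", "c"] <- 7
  tr <- nj_tree(D)
  # topology: the informative bipartition must be ab|cd
  bp <- barcodelim:::tree_bipartitions(tr)
  keys <- bp$key[bp$is_informative]
  expect_true("c|d" %in% keys || "a|b" %in% keys)
  # path lengths reproduce the additive matrix exactly
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
               tolerance = 1e-10)
})

test_that("NJ is exact on random additive matrices", {
  set.seed(55)
  for (case in 1:200) {
    n <- sample(8:12, 1)
    true <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    D <- ape::cophenetic.phylo(true)
    tr <- nj_tree(D[true$tip.label, true$tip.label])
    expect_equal(ape::dist.topo(ape::unroot(true), tr), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(tr)[true$tip.label, true$tip.label],
                 D, tolerance = 1e-8)
  }
})

test_that("equal distances produce a zero-length internal edge", {
  D <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  tr <- nj_tree(D)
  ntip <- 4L
  internal <- tr$edge[, 2] > ntip
  expect_true(all(tr$edge.length >= 0))
  expect_equal(sum(tr$edge.length[internal]), 0)
})

test_that("NJ refuses masked pairs", {
  D <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(D) <- 0; D[1, 2] <- D[2, 1] <- NA
  expect_error(nj_tree(D), class = "distance_error")
})

test_that("bootstrap supports: B=1 is all-or-nothing and seeds are reproducible", {
  ds <- simulate_dataset(small_config(seed = 17L))
  dsets <- build_datasets(ds$regions,
                          default_dataset_definitions(ds$config$region_plan))
  t1 <- bootstrap_supports(dsets$G, B = 1, seed = 2)
  sup <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
  t2 <- bootstrap_supports(dsets$G, B = 30, seed = 9)
  t3 <- bootstrap_supports(dsets$G, B = 30, seed = 9)
  expect_identical(t2$node.label, t3$node.label)
})

test_that("clearly separated clades get high support", {
  cfg <- two_taxon_config(2000L, 0.05, theta = 0.001, seed = 41L)
  cfg$populations_per_taxon <- c(t1 = 1L, t2 = 1L)
  cfg$samples_per_population <- c(t1 = 4L, t2 = 4L)
  ds <- simulate_dataset(cfg)
  tr <- bootstrap_supports(ds$regions$r1, B = 200, seed = 3)
  r <- taxon_monophyly(tr, ds$metadata, "t1")
  expect_equal(r$verdict, "success")
  expect_gte(r$support, 95)
})

test_that("monophyly criterion follows the strict >50 support rule", {
  md <- make_md(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  f <- tempfile()
  writeLines("((a1:1,a2:1)90:1,(b1:1,b2:1)90:1);", f)
  tr <- read_support_tree(f)
  expect_equal(taxon_monophyly(tr, md, "A")$verdict, "success")
  expect_equal(taxon_monophyly(tr, md, "B")$support, 90)

  writeLines("((a1:1,b1:1)80:1,(a2:1,b2:1)80:1);", f)
  tr <- read_support_tree(f)
  r <- taxon_monophyly(tr, md, "A")
  expect_equal(r$verdict, "failure")
  expect_false(r$monophyletic)
  # smallest bipartition side containing both A samples is a 3-leaf side
  expect_equal(r$smallest_containing_clade, 3L)

  # clade present but support only 34: fails the strict rule
  writeLines("((a1:1,a2:1)34:1,(b1:1,b2:1)90:1);", f)
  tr <- read_support_tree(f)
  r <- taxon_monophyly(tr, md, "A")
  expect_equal(r$verdict, "failure")
  expect_true(r$monophyletic)
  expect_equal(r$support, 34)
  # exactly at the threshold is also a failure; strictly above succeeds
  writeLines("((a1:1,a2:1)50:1,(b1:1,b2:1)51:1);", f)
  tr <- read_support_tree(f)
  expect_equal(taxon_monophyly(tr, md, "A")$verdict, "failure")
  expect_equal(taxon_monophyly(tr, md, "B")$verdict, "success")

  md1 <- make_md(c(a1 = "A", b1 = "B", b2 = "B", c1 = "C"))
  writeLines("((a1:1,b1:1)60:1,(b2:1,c1:1)60:1);", f)
  tr <- read_support_tree(f)
  expect_equal(taxon_monophyly(tr, md1, "A")$verdict, "not_assessable")
})

test_that("newick round-trips preserve supports and verdicts in both dialects", {
  ds <- simulate_dataset(small_config(seed = 29L))
  dsets <- build_datasets(ds$regions,
                          default_dataset_definitions(ds$config$region_plan))
  tr <- bootstrap_supports(dsets$G, B = 50, seed = 4)
  md <- ds$metadata
  for (dialect in c("node", "branch")) {
    f <- tempfile(fileext = ".nwk")
    write_support_tree(tr, f, dialect = dialect)
    back <- read_support_tree(f, dialect = dialect)
    for (tx in unique(md$taxon)) {
      expect_equal(taxon_monophyly(back, md, tx)$verdict,
                   taxon_monophyly(tr, md, tx)$verdict)
      expect_equal(taxon_monophyly(back, md, tx)$support,
                   taxon_monophyly(tr, md, tx)$support)
    }
  }
})
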