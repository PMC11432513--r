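test_that("zero divergence yields identical sequences everywhere", {
  cfg <- simulation_config(
    species_tree = "(t1:0,t2:0);",
    populations_per_taxon = c(t1 = 2L, t2 = 2L),
    samples_per_population = 2L,
    region_plan = data.frame(region = c("r1", "r2"),
                             compartment = c("plastid_gene", "mito_gene"),
                             length = c(50L, 30L), rate_multiplier = 1),
    within_population_theta = 0, population_divergence = 0,
    hybrid_spec = NULL, seed = 3L)
  ds <- simulate_dataset(cfg)
  for (r in ds$regions) {
    expect_equal(nrow(unique(r$seq)), 1L)
  }
  expect_equal(nrow(ds$truth$event_log), 0L)
})

test_that("identical seed and config give byte-identical output", {
  d1 <- simulate_dataset(small_config(seed = 11L))
  d2 <- simulate_dataset(small_config(seed = 11L))
  expect_identical(lapply(d1$regions, `[[`, "seq"),
                   lapply(d2$regions, `[[`, "seq"))
  expect_identical(d1$truth$event_log, d2$truth$event_log)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta_alignment(d1$regions[[1]], f1)
  write_fasta_alignment(d2$regions[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))
  d3 <- simulate_dataset(small_config(seed = 12L))
  expect_false(identical(d1$regions[[1]]$seq, d3$regions[[1]]$seq))
})

test_that("K2P distance estimates recover the simulated divergence", {
  # two taxa, 10 kb, true inter-taxon path 0.01: the mean K2P estimate over
  # 20 seeds must sit within 3 Monte-Carlo SEs of the truth
  est <- vapply(1:20, function(s) {
    ds <- simulate_dataset(two_taxon_config(10000L, 0.01, seed = s))
    k2p_distance(ds$regions$r1$seq[1, ], ds$regions$r1$seq[2, ])
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.01), 3 * se + 1e-12)
})

test_that("event log records the transition bias implied by kappa", {
  ds <- simulate_dataset(two_taxon_config(20000L, 0.05, seed = 9L, kappa = 8))
  ev <- ds$truth$event_log
  n_ts <- sum(ev$type == "transition")
  # kappa = 8 -> transition fraction 8/10; reject the even split
  bt <- binom.test(n_ts, nrow(ev), p = 0.5, alternative = "greater")
  expect_lt(bt$p.value, 0.05)
  expect_gt(n_ts, nrow(ev) - n_ts)
  # and the event types are consistent with the base changes
  pur <- c("A", "G")
  is_ts <- (ev$from %in% pur) == (ev$to %in% pur)
  expect_identical(ifelse(is_ts, "transition", "transversion"), ev$type)
})

test_that("hybrid samples take each compartment from the designated parent", {
  cfg <- small_config(seed = 21L)
  ds <- simulate_dataset(cfg)
  md <- ds$metadata
  hyb <- md$sample_id[md$taxon == "rhaetica"]
  syl <- md$sample_id[md$taxon == "sylvestris"]
  mug <- md$sample_id[md$taxon == "mugo"]
  dsets <- build_datasets(ds$regions,
                          default_dataset_definitions(cfg$region_plan))
  # plastid compartment from sylvestris: hybrid-sylvestris distances small
  DA <- k2p_pairwise(dsets$A)
  expect_lt(mean(DA[hyb, syl]), mean(DA[hyb, mug]))
  # mito compartment from mugo: the ordering flips
  DB <- k2p_pairwise(dsets$B)
  expect_lt(mean(DB[hyb, mug]), mean(DB[hyb, syl]))
})

test_that("organellar regions carry exactly one haplotype per sample", {
  ds <- simulate_dataset(small_config(seed = 4L))
  for (r in ds$regions) {
    expect_equal(nrow(r$seq), nrow(ds$metadata))
    expect_true(all(r$seq %in% c("A", "C", "G", "T")))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(species_tree = "not a tree"),
               class = "config_error")
  expect_error(simulation_config(species_tree = "(a:1,b:1,c:1,d:1);",
                                 populations_per_taxon = c(a = 1L),
                                 hybrid_spec = NULL),
               class = "config_error")
  expect_error(
    simulation_config(hybrid_spec = list(hybrid_taxon = "rhaetica",
                                         parent_A = "nosuch", parent_B = "mugo",
                                         origin = default_hybrid_spec()$origin)),
    class = "config_error")
  plan <- default_region_plan(); plan$length[1] <- 0L
  expect_error(simulation_config(region_plan = plan), class = "config_error")
  plan <- default_region_plan(); plan$rate_multiplier[1] <- -1
  expect_error(simulation_config(region_plan = plan), class = "config_error")
})

test_that("missingness masks roughly the requested fraction of sites to N", {
  cfg <- two_taxon_config(5000L, 0.01, seed = 2L)
  cfg$missingness <- 0.1
  ds <- simulate_dataset(cfg)
  frac <- mean(ds$regions$r1$seq == "N")
  expect_gt(frac, 0.07); expect_lt(frac, 0.13)
})

test_that("written synthetic datasets round-trip through the readers", {
  ds <- simulate_dataset(small_config(seed = 6L))
  dir <- tempfile(); write_synthetic_dataset(ds, dir)
  r <- read_fasta_alignment(file.path(dir, "matK.fasta"), region = "matK")
  expect_identical(r$seq, ds$regions$matK$seq)
  md <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(md$sample_id, ds$metadata$sample_id)
  expect_equal(md$taxon, ds$metadata$taxon)
  expect_equal(md$population, ds$metadata$population)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_setequal(unlist(truth$hotspot_regions), ds$truth$hotspot_regions)
})
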