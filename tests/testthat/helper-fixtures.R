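# Build a region_alignment from a character vector of sequence strings,
# auto-naming samples s1, s2, ...
make_aln <- function(seqs, region = "r", compartment = "plastid_gene",
                     samples = sprintf("s%d", seq_along(seqs))) {
  region_alignment(setNames(seqs, samples), region = region,
                   compartment = compartment)
}

# random alignment of given size over A/C/G/T with optional missing fraction
random_aln <- function(n, L, missing = 0) {
  mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  if (missing > 0) mat[runif(n * L) < missing] <- sample(c("N", "-"), 1)
  rownames(mat) <- sprintf("s%d", seq_len(n))
  region_alignment(mat, region = "rnd")
}

# metadata table for samples named <taxon><i>
make_md <- function(taxa_of, pops_of = NULL) {
  data.frame(sample_id = names(taxa_of), taxon = unname(taxa_of),
             population = unname(pops_of %||% taxa_of),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-taxon simulation config used by parameter-recovery tests
two_taxon_config <- function(L, depth, theta = 0, seed = 1L, kappa = 2,
                             multiplier = 1) {
  simulation_config(
    species_tree = sprintf("(t1:%g,t2:%g);", depth / 2, depth / 2),
    populations_per_taxon = c(t1 = 1L, t2 = 1L),
    samples_per_population = 1L,
    region_plan = data.frame(region = "r1", compartment = "plastid_gene",
                             length = as.integer(L),
                             rate_multiplier = multiplier),
    kappa = kappa,
    within_population_theta = theta, population_divergence = 0,
    hybrid_spec = NULL, seed = seed)
}

# planted two-cluster distance matrix: intra around `intra`, inter around
# `inter`, multiplicative jitter
planted_matrix <- function(n1, n2, intra = 0.002, inter = 0.02, jitter = 0) {
  labels <- c(sprintf("a%d", 1:n1), sprintf("b%d", 1:n2))
  n <- n1 + n2
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    same <- (i <= n1) == (j <= n1)
    d <- if (same) intra else inter
    if (jitter > 0) d <- d * (1 + runif(1, -jitter, jitter))
    D[i, j] <- D[j, i] <- d
  }
  D
}

# small multi-region config (fast) for pipeline-level tests
small_config <- function(seed = 1L, hotspot_mult = 12) {
  plan <- rbind(
    data.frame(region = c("matK", "rbcL", "rps1", "rps2", "rps14",
                          sprintf("pcg%02d", 1:5)),
               compartment = "plastid_gene",
               length = c(80L, 80L, 68L, 68L, 68L, rep(80L, 5)),
               rate_multiplier = c(1, 1, hotspot_mult, hotspot_mult,
                                   hotspot_mult, rep(1, 5))),
    data.frame(region = c("ycf3-psaA", "trnE-clpP", "igs01", "igs02"),
               compartment = "plastid_spacer",
               length = c(68L, 68L, 44L, 44L),
               rate_multiplier = c(hotspot_mult, hotspot_mult, 2, 2)),
    data.frame(region = sprintf("mtg%02d", 1:3), compartment = "mito_gene",
               length = 60L, rate_multiplier = 3),
    data.frame(region = c("18S", "ITS1", "5.8S", "ITS2", "26S"),
               compartment = "nrDNA_part",
               length = c(90L, 124L, 16L, 24L, 158L), rate_multiplier = 0.8))
  simulation_config(
    populations_per_taxon = c(mugo = 2L, uncinata = 2L, uliginosa = 2L,
                              rotundata = 2L, rhaetica = 1L, sylvestris = 1L),
    samples_per_population = c(mugo = 2L, uncinata = 2L, uliginosa = 2L,
                               rotundata = 2L, rhaetica = 2L, sylvestris = 2L),
    region_plan = plan, seed = seed)
}
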