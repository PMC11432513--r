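#' Default species tree for the synthetic pine study
#'
#' Five-leaf rooted binary tree over the four dwarf-pine complex members plus
#' the outgroup-like *P. sylvestris*; branch lengths are expected
#' substitutions per site at rate multiplier 1. The hybrid taxon (rhaetica)
#' is not a tree leaf: its compartments are copied from parent lineages at
#' simulation time.
#'
#' @return A newick string.
#' @export
default_species_tree <- function() {
  paste0("(((mugo:0.004,(uliginosa:0.0025,rotundata:0.0025):0.002):0.002,",
         "uncinata:0.006):0.01,sylvestris:0.016);")
}

#' Default region plan (scaled-down genome-skim inventory)
#'
#' Mirrors the region counts of a conifer genome-skimming inventory — 57
#' plastid coding genes (including matK, rbcL and the hotspot genes rps1,
#' rps2, rps14), 18 plastid intergenic spacers (including the hotspot
#' spacers ycf3-psaA and trnE-clpP), 15 mitochondrial coding genes, and the
#' five nrDNA cistron parts (18S, ITS1, 5.8S, ITS2, 26S) — at roughly one
#' tenth of full length. Hotspot regions are kept at 68 bp (rather than a
#' strict 1/10 of their full-length total) so per-region percent-variable
#' estimates remain statistically stable; nrDNA part lengths are proportional
#' to the real cistron (1812, 2482, 158, 241, 3155 bp).
#'
#' Rate multipliers encode the observed compartment ranking (hotspots >>
#' mitochondrial > spacers > plastid genes > nrDNA); hotspot regions run at
#' 12x the baseline, at least ten times the plan's median multiplier.
#'
#' @return A data.frame with columns `region`, `compartment`, `length`,
#'   `rate_multiplier`.
#' @export
default_region_plan <- function() {
  pcg <- data.frame(
    region = c("matK", "rbcL", "rps1", "rps2", "rps14",
               sprintf("pcg%02d", 1:52)),
    compartment = "plastid_gene",
    length = c(154L, 144L, 68L, 68L, 68L, rep(80L, 52)),
    rate_multiplier = c(1, 1, 12, 12, 12, rep(1, 52)))
  igs <- data.frame(
    region = c("ycf3-psaA", "trnE-clpP", sprintf("igs%02d", 1:16)),
    compartment = "plastid_spacer",
    length = c(68L, 68L, rep(44L, 16)),
    rate_multiplier = c(12, 12, rep(2, 16)))
  mtg <- data.frame(
    region = sprintf("mtg%02d", 1:15),
    compartment = "mito_gene",
    length = 56L,
    rate_multiplier = 3)
  nr <- data.frame(
    region = c("18S", "ITS1", "5.8S", "ITS2", "26S"),
    compartment = "nrDNA_part",
    length = c(181L, 248L, 16L, 24L, 316L),
    rate_multiplier = 0.8)
  rbind(pcg, igs, mtg, nr)
}

#' Build a simulation configuration
#'
#' @param species_tree Newick string; rooted binary tree, branch lengths in
#'   expected substitutions per site at rate multiplier 1.
#' @param populations_per_taxon Named integer vector, taxon -> number of
#'   populations. May include the hybrid taxon.
#' @param samples_per_population Single positive integer, or a named vector
#'   per taxon.
#' @param region_plan Data.frame with columns `region`, `compartment`,
#'   `length`, `rate_multiplier`.
#' @param kappa Transition/transversion rate ratio of the K2P (K80) model.
#' @param within_population_theta Expected intra-population pairwise
#'   diversity (substitutions/site at multiplier 1).
#' @param population_divergence Expected substitutions/site (at multiplier 1)
#'   on each population's private branch.
#' @param hybrid_spec Optional list with `hybrid_taxon`, `parent_A`,
#'   `parent_B` and `origin` (named character, compartment -> parent taxon).
#' @param missingness Fraction of sites per sample masked to N (default 0).
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @return A `simulation_config` list, validated.
#' @export
simulation_config <- function(species_tree = default_species_tree(),
                              populations_per_taxon = c(mugo = 3L, uncinata = 3L,
                                                        uliginosa = 3L, rotundata = 4L,
                                                        rhaetica = 1L, sylvestris = 1L),
                              samples_per_population = c(mugo = 2L, uncinata = 2L,
                                                         uliginosa = 2L, rotundata = 2L,
                                                         rhaetica = 3L, sylvestris = 3L),
                              region_plan = default_region_plan(),
                              kappa = 2.0,
                              within_population_theta = 5e-4,
                              population_divergence = 1e-3,
                              hybrid_spec = default_hybrid_spec(),
                              missingness = 0,
                              seed = 1L) {
  tree <- tryCatch(ape::read.tree(text = species_tree),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop_ctx("unreadable newick species tree", class = "config_error")
  if (is.null(tree$edge.length))
    stop_ctx("species tree must have branch lengths", class = "config_error")
  if (!ape::is.binary(tree))
    stop_ctx("species tree must be binary", class = "config_error")
  stopifnot(is.data.frame(region_plan),
            all(c("region", "compartment", "length", "rate_multiplier") %in%
                  names(region_plan)))
  if (any(region_plan$length < 1L))
    stop_ctx("every region length must be >= 1", class = "config_error")
  if (any(region_plan$rate_multiplier < 0))
    stop_ctx("every rate_multiplier must be >= 0", class = "config_error")
  if (anyDuplicated(region_plan$region))
    stop_ctx("duplicate region names in region plan", class = "config_error")
  if (is.null(names(populations_per_taxon)))
    stop_ctx("populations_per_taxon must be named by taxon", class = "config_error")
  if (any(populations_per_taxon < 1L))
    stop_ctx("populations_per_taxon must be positive", class = "config_error")
  if (length(samples_per_population) == 1L && is.null(names(samples_per_population)))
    samples_per_population <- setNames(rep(samples_per_population,
                                           length(populations_per_taxon)),
                                       names(populations_per_taxon))
  if (any(samples_per_population < 1L))
    stop_ctx("samples_per_population must be positive", class = "config_error")
  hybrid <- if (!is.null(hybrid_spec)) hybrid_spec$hybrid_taxon else character(0)
  non_hybrid <- setdiff(names(populations_per_taxon), hybrid)
  miss <- setdiff(non_hybrid, tree$tip.label)
  if (length(miss))
    stop_ctx("taxa absent from species tree: ", paste(miss, collapse = ", "),
             class = "config_error")
  if (!is.null(hybrid_spec)) {
    for (p in c(hybrid_spec$parent_A, hybrid_spec$parent_B))
      if (!p %in% tree$tip.label)
        stop_ctx("hybrid parent '", p, "' is not a leaf of the species tree",
                 class = "config_error")
    comps <- unique(region_plan$compartment)
    bad <- setdiff(comps, names(hybrid_spec$origin))
    if (length(bad))
      stop_ctx("hybrid_spec$origin missing compartment(s): ",
               paste(bad, collapse = ", "), class = "config_error")
    if (!all(hybrid_spec$origin %in% c(hybrid_spec$parent_A, hybrid_spec$parent_B)))
      stop_ctx("hybrid_spec$origin values must be parent_A or parent_B",
               class = "config_error")
  }
  stopifnot(kappa > 0, within_population_theta >= 0, population_divergence >= 0,
            missingness >= 0, missingness < 1)
  structure(list(species_tree = species_tree, tree = tree,
                 populations_per_taxon = populations_per_taxon,
                 samples_per_population = samples_per_population,
                 region_plan = region_plan, kappa = kappa,
                 within_population_theta = within_population_theta,
                 population_divergence = population_divergence,
                 hybrid_spec = hybrid_spec, missingness = missingness,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default hybrid specification (fixed-mosaic hybrid)
#'
#' The hybrid taxon inherits whole compartments from its parents: plastid
#' compartments from sylvestris (paternal plastid transmission in pines),
#' the mitochondrial compartment from mugo (maternal), and the nrDNA from
#' sylvestris. No per-site recombination is modelled.
#'
#' @export
default_hybrid_spec <- function() {
  list(hybrid_taxon = "rhaetica", parent_A = "sylvestris", parent_B = "mugo",
       origin = c(plastid_gene = "sylvestris", plastid_spacer = "sylvestris",
                  mito_gene = "mugo", nrDNA_part = "sylvestris"))
}

BASES <- c("A", "C", "G", "T")
# K2P partners: transition target per base; transversion targets per base.
TS_TARGET <- c(A = "G", C = "T", G = "A", T = "C")
TV_TARGETS <- list(A = c("C", "T"), C = c("A", "G"),
                   G = c("C", "T"), T = c("A", "G"))

# Evolve `seq` (character vector of bases) for expected `d` substitutions per
# site under K2P with ts/tv ratio kappa, as an exact Markov jump process:
# events per site ~ Poisson(d), each event a transition with probability
# kappa/(kappa+2), else one of the two transversions. Events are appended to
# the environment `log_env` with the lineage label.
k2p_evolve <- function(seq, d, kappa, lineage, log_env) {
  L <- length(seq)
  if (d <= 0 || L == 0L) return(seq)
  n_ev <- stats::rpois(L, d)
  hit <- which(n_ev > 0L)
  p_ts <- kappa / (kappa + 2)
  for (s in hit) {
    for (k in seq_len(n_ev[s])) {
      from <- seq[s]
      if (stats::runif(1) < p_ts) {
        to <- TS_TARGET[[from]]
        type <- "transition"
      } else {
        to <- sample(TV_TARGETS[[from]], 1L)
        type <- "transversion"
      }
      seq[s] <- to
      log_env$events[[length(log_env$events) + 1L]] <-
        list(lineage = lineage, site = s, from = from, to = to, type = type)
    }
  }
  seq
}

#' Simulate a multi-compartment, multi-region aligned data set
#'
#' Evolves each region along the species tree under the K2P (K80) model with
#' region-specific rate multipliers, adds population-private divergence and
#' tip-level intra-population variation, and builds the hybrid taxon as a
#' fixed compartment mosaic of its two parents. Organellar compartments carry
#' exactly one haplotype per sample (haploid sequences, no heterozygosity).
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_dataset`: list with `regions` (named list of
#'   [region_alignment()]s), `metadata` (sample_id/taxon/population),
#'   `truth` (true taxon partition, planted hotspot regions, per-region
#'   rate multipliers, substitution event log) and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tree <- config$tree
  plan <- config$region_plan
  hyb <- config$hybrid_spec

  # sample table
  md <- do.call(rbind, lapply(names(config$populations_per_taxon), function(tx) {
    npop <- config$populations_per_taxon[[tx]]
    spp <- config$samples_per_population[[tx]]
    do.call(rbind, lapply(seq_len(npop), function(p) {
      pop <- sprintf("%s_p%d", tx, p)
      data.frame(sample_id = sprintf("%s_s%d", pop, seq_len(spp)),
                 taxon = tx, population = pop, stringsAsFactors = FALSE)
    }))
  }))

  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  edge_order <- ape::reorder.phylo(tree, "cladewise")$edge
  edge_len <- ape::reorder.phylo(tree, "cladewise")$edge.length

  log_env <- new.env()
  log_env$events <- list()

  regions <- vector("list", nrow(plan))
  names(regions) <- plan$region
  for (i in seq_len(nrow(plan))) {
    L <- plan$length[i]
    m <- plan$rate_multiplier[i]
    rname <- plan$region[i]
    node_seq <- vector("list", ntip + tree$Nnode)
    node_seq[[root]] <- sample(BASES, L, replace = TRUE)
    for (e in seq_len(nrow(edge_order))) {
      par <- edge_order[e, 1L]; child <- edge_order[e, 2L]
      node_seq[[child]] <- k2p_evolve(node_seq[[par]], edge_len[e] * m,
                                      config$kappa,
                                      sprintf("%s/edge%d", rname, e), log_env)
    }
    tip_seq <- setNames(node_seq[seq_len(ntip)], tree$tip.label)
    if (!is.null(hyb))
      tip_seq[[hyb$hybrid_taxon]] <- tip_seq[[hyb$origin[[plan$compartment[i]]]]]

    seqs <- matrix("N", nrow = nrow(md), ncol = L,
                   dimnames = list(md$sample_id, NULL))
    for (tx in unique(md$taxon)) {
      for (pop in unique(md$population[md$taxon == tx])) {
        pop_seq <- k2p_evolve(tip_seq[[tx]], config$population_divergence * m,
                              config$kappa, sprintf("%s/%s", rname, pop), log_env)
        for (sid in md$sample_id[md$population == pop]) {
          s <- k2p_evolve(pop_seq, config$within_population_theta / 2 * m,
                          config$kappa, sprintf("%s/%s", rname, sid), log_env)
          if (config$missingness > 0) {
            mask <- stats::runif(L) < config$missingness
            s[mask] <- "N"
          }
          seqs[sid, ] <- s
        }
      }
    }
    regions[[i]] <- region_alignment(seqs, region = rname,
                                     compartment = plan$compartment[i])
  }

  events <- if (length(log_env$events)) {
    do.call(rbind, lapply(log_env$events, function(ev)
      data.frame(lineage = ev$lineage, site = ev$site, from = ev$from,
                 to = ev$to, type = ev$type, stringsAsFactors = FALSE)))
  } else {
    data.frame(lineage = character(0), site = integer(0), from = character(0),
               to = character(0), type = character(0))
  }

  med_mult <- stats::median(plan$rate_multiplier)
  truth <- list(
    taxon_partition = split(md$sample_id, md$taxon),
    hotspot_regions = plan$region[plan$rate_multiplier >= 10 * med_mult],
    rate_multipliers = setNames(plan$rate_multiplier, plan$region),
    event_log = events)

  structure(list(regions = regions, metadata = md, truth = truth,
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset: ", nrow(x$metadata), " samples, ",
      length(x$regions), " regions, ",
      length(unique(x$metadata$taxon)), " taxa (seed ", x$config$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic data set to disk
#'
#' Emits one FASTA per region, a metadata TSV (`sample_id`, `taxon`,
#' `population`), a truth-record JSON and the configuration as YAML.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in ds$regions)
    write_fasta_alignment(r, file.path(dir, paste0(r$region, ".fasta")))
  write.table(ds$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- ds$truth
  truth$event_log <- NULL  # tabular log omitted from JSON; kept in-memory
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  cfg <- ds$config
  yaml::write_yaml(list(species_tree = cfg$species_tree,
                        populations_per_taxon = as.list(cfg$populations_per_taxon),
                        samples_per_population = as.list(cfg$samples_per_population),
                        kappa = cfg$kappa,
                        within_population_theta = cfg$within_population_theta,
                        population_divergence = cfg$population_divergence,
                        missingness = cfg$missingness,
                        seed = cfg$seed),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}
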