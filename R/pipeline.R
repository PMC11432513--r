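#' Build a pipeline configuration
#'
#' @param input Either `"synthetic"` (default) or a list with `regions_dir`
#'   (directory of per-region FASTA files named `<region>.fasta`),
#'   `metadata` (TSV path) and `region_plan` (data.frame or TSV path with
#'   `region`, `compartment` columns).
#' @param simulation A [simulation_config()] used when `input` is synthetic.
#' @param dataset_definitions Named list code -> region names; default
#'   [default_dataset_definitions()] on the region plan in use.
#' @param support_threshold Tree-criterion support threshold (strict >).
#' @param bootstrap_B Bootstrap replicates for tree supports.
#' @param popdiv_B Bootstrap replicates for population divergence.
#' @param n_permutations Permutations for the ASAP panmixia test.
#' @param epsilon Median-joining network tolerance.
#' @param k_axes PCoA axes.
#' @param out_dir Output directory.
#' @param seed Master seed; propagated to every stochastic stage.
#' @param external_trees Optional named list (code -> newick path) of
#'   externally computed support-annotated trees used for the tree criterion
#'   instead of the built-in NJ bootstrap.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = "synthetic",
                            simulation = NULL,
                            dataset_definitions = NULL,
                            support_threshold = 50,
                            bootstrap_B = 200L,
                            popdiv_B = 1000L,
                            n_permutations = 999L,
                            epsilon = 0,
                            k_axes = 2L,
                            out_dir = "results",
                            seed = 1L,
                            external_trees = NULL) {
  if (identical(input, "synthetic") && is.null(simulation))
    simulation <- simulation_config(seed = seed)
  structure(list(input = input, simulation = simulation,
                 dataset_definitions = dataset_definitions,
                 support_threshold = support_threshold,
                 bootstrap_B = as.integer(bootstrap_B),
                 popdiv_B = as.integer(popdiv_B),
                 n_permutations = as.integer(n_permutations),
                 epsilon = epsilon, k_axes = as.integer(k_axes),
                 out_dir = out_dir, seed = as.integer(seed),
                 external_trees = external_trees),
            class = "pipeline_config")
}

load_pipeline_inputs <- function(config) {
  if (identical(config$input, "synthetic")) {
    ds <- simulate_dataset(config$simulation)
    list(regions = ds$regions, metadata = ds$metadata,
         region_plan = config$simulation$region_plan, truth = ds$truth)
  } else {
    inp <- config$input
    plan <- inp$region_plan
    if (is.character(plan)) plan <- read.delim(plan, stringsAsFactors = FALSE)
    regions <- setNames(lapply(seq_len(nrow(plan)), function(i)
      read_fasta_alignment(file.path(inp$regions_dir,
                                     paste0(plan$region[i], ".fasta")),
                           region = plan$region[i],
                           compartment = plan$compartment[i])),
      plan$region)
    list(regions = regions, metadata = read_sample_metadata(inp$metadata),
         region_plan = plan, truth = NULL)
  }
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full barcode-evaluation pipeline
#'
#' Orchestrates, for synthetic or user-supplied data: data-set construction
#' (codes A–G), the variability report and ranking, divergence-hotspot
#' detection, K2P distance matrices, the three delimitation methods
#' (NJ-bootstrap monophyly, barcoding gap, ASAP surrogate), the
#' discrimination summary, median-joining haplotype networks for the
#' organellar sets, PCoA, and the population-divergence table. All tables
#' are written as TSV under `config$out_dir`; the configuration and seed are
#' serialized alongside for provenance.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every in-memory result
#'   (`datasets`, `variability`, `ranking`, `hotspots`, `distances`,
#'   `trees`, `delimitation`, `discrimination`, `asap`, `networks`, `pcoa`,
#'   `popdiv`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  inputs <- run_stage("load", load_pipeline_inputs(config))
  regions <- inputs$regions
  metadata <- inputs$metadata
  defs <- config$dataset_definitions %||%
    default_dataset_definitions(inputs$region_plan)
  datasets <- run_stage("concatenate", build_datasets(regions, defs))

  vt <- run_stage("variability", variability_table(datasets))
  write.table(vt, file.path(out, "variability.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ranking <- rank_datasets(vt)
  writeLines(paste(ranking, collapse = " > "),
             file.path(out, "ranking.txt"))

  region_var <- run_stage("hotspots", per_region_variability(regions))
  hs <- detect_hotspots(region_var)
  write.table(data.frame(region = names(region_var), pct_variable = region_var,
                         flagged = names(region_var) %in% hs$flagged),
              file.path(out, "hotspots.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  distances <- run_stage("distances",
                         lapply(datasets, k2p_pairwise))
  for (code in names(distances))
    write_distance_tsv(distances[[code]],
                       file.path(out, sprintf("k2p_%s.tsv", code)))

  results <- list(); trees <- list(); asap_best <- list()
  for (code in names(datasets)) {
    tree <- run_stage(paste0("tree_", code), {
      if (!is.null(config$external_trees) && code %in% names(config$external_trees)) {
        read_support_tree(config$external_trees[[code]])
      } else {
        bootstrap_supports(datasets[[code]], B = config$bootstrap_B,
                           seed = config$seed + match(code, names(datasets)))
      }
    })
    trees[[code]] <- tree
    write_support_tree(tree, file.path(out, sprintf("tree_%s.nwk", code)))
    results[[paste0(code, "_tree")]] <-
      delimit_taxa("tree", code, metadata, tree = tree,
                   support_threshold = config$support_threshold)
    results[[paste0(code, "_distance")]] <-
      delimit_taxa("distance", code, metadata, D = distances[[code]])
    scored <- run_stage(paste0("asap_", code), {
      ladder <- build_partition_ladder(distances[[code]])
      score_partitions(ladder, distances[[code]],
                       n_permutations = config$n_permutations,
                       seed = config$seed + 100L + match(code, names(datasets)))
    })
    if (length(scored)) {
      asap_best[[code]] <- scored[[1L]]
      write.table(asap_candidate_table(scored),
                  file.path(out, sprintf("asap_candidates_%s.tsv", code)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      results[[paste0(code, "_asap")]] <-
        delimit_taxa("asap", code, metadata, partition = scored[[1L]])
    } else {
      results[[paste0(code, "_asap")]] <-
        data.frame(code = code, method = "asap", taxon = unique(metadata$taxon),
                   verdict = "failure", support = NA_real_,
                   max_intra = NA_real_, min_inter = NA_real_,
                   stringsAsFactors = FALSE)
    }
  }

  disc <- run_stage("discrimination",
                    summarize_discrimination(do.call(rbind, results)))
  write.table(disc, file.path(out, "discrimination.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_discrimination_tsv(disc, file.path(out, "discrimination_table.tsv"))

  networks <- list()
  for (code in intersect(c("A", "B"), names(datasets))) {
    networks[[code]] <- run_stage(paste0("network_", code), {
      hs_set <- collapse_haplotypes(datasets[[code]])
      if (length(hs_set$haplotypes) >= 2L) {
        g <- median_joining_network(hs_set, epsilon = config$epsilon)
        write_network(g, gml_path = file.path(out, sprintf("network_%s.gml", code)),
                      tsv_path = file.path(out, sprintf("network_%s_edges.tsv", code)))
        write.table(haplotype_composition(hs_set, metadata),
                    file.path(out, sprintf("haplotypes_%s.tsv", code)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        list(haplotypes = hs_set, graph = g)
      } else {
        list(haplotypes = hs_set, graph = NULL)
      }
    })
  }

  pcoa_code <- if ("G" %in% names(datasets)) "G" else names(datasets)[1L]
  pc <- run_stage("pcoa", pcoa_k2p(distances[[pcoa_code]], k = config$k_axes))
  write_pcoa_tsv(pc, metadata, file.path(out, "pcoa.tsv"))

  popdiv <- list()
  for (code in intersect(c("C", "G"), names(datasets))) {
    popdiv[[code]] <- run_stage(paste0("popdiv_", code),
      population_divergence(datasets[[code]], metadata,
                            B = config$popdiv_B, seed = config$seed))
    write_distance_tsv(popdiv[[code]]$mean,
                       file.path(out, sprintf("popdiv_%s_mean.tsv", code)))
    write_distance_tsv(popdiv[[code]]$se,
                       file.path(out, sprintf("popdiv_%s_se.tsv", code)))
  }
  if (all(c("C", "G") %in% names(popdiv)))
    write_distance_tsv(combine_triangles(lower = popdiv$G$mean,
                                         upper = popdiv$C$mean),
                       file.path(out, "popdiv_heatmap.tsv"))

  yaml::write_yaml(list(seed = config$seed,
                        support_threshold = config$support_threshold,
                        bootstrap_B = config$bootstrap_B,
                        popdiv_B = config$popdiv_B,
                        n_permutations = config$n_permutations,
                        epsilon = config$epsilon, k_axes = config$k_axes,
                        input = if (identical(config$input, "synthetic"))
                          "synthetic" else "user"),
                   file.path(out, "config_used.yaml"))

  invisible(list(datasets = datasets, metadata = metadata,
                 variability = vt, ranking = ranking, hotspots = hs,
                 distances = distances, trees = trees,
                 delimitation = do.call(rbind, results),
                 discrimination = disc, asap = asap_best,
                 networks = networks, pcoa = pc, popdiv = popdiv,
                 truth = inputs$truth))
}
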