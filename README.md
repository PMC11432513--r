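# barcodelim

Multilocus DNA-barcode evaluation and species delimitation for closely
related plant taxa, modelled on genome-skimming studies of dwarf mountain
pines (*Pinus mugo* complex, *P. sylvestris*, and their stabilized hybrid).

Taxa this young are near-identical at classical barcodes, but genome
skimming yields dozens of aligned plastid, mitochondrial and nrDNA regions
per sample. `barcodelim` asks, quantitatively: *which concatenation of
regions discriminates the taxa, under which criterion?* It builds the seven
standard data sets —

| code | contents |
|------|----------|
| A | concatenated plastid coding genes |
| B | concatenated mitochondrial coding genes |
| C | plastid intergenic spacers |
| D | full nrDNA cistron (18S–ITS1–5.8S–ITS2–26S) |
| E | ITS (ITS1–5.8S–ITS2) |
| F | core barcodes *matK* + *rbcL* |
| G | divergence hotspot regions (*rps1*, *rps2*, *rps14*, *ycf3-psaA*, *trnE-clpP*) |

— and evaluates them with three delimitation criteria plus supporting
analyses:

* **Variability reports**: variable and parsimony-informative site counts
  and percentages per data set; ranking; divergence-hotspot screen with
  threshold *T* = mean + 2·SD of per-region percent variable sites.
* **K2P distances**: *d* = −½·ln((1−2P−Q)·√(1−2Q)) with pairwise deletion,
  saturation masking, and population-level means with column-bootstrap
  standard errors.
* **Tree criterion**: a taxon succeeds when it forms a monophyletic group
  (an unrooted bipartition) with bootstrap support strictly above 50.
  Built-in NJ + column bootstrap, or any external support-annotated newick.
* **Barcoding gap**: success when the minimum interspecific distance
  strictly exceeds the maximum intraspecific distance.
* **ASAP-style partitioning**: nested single-linkage candidate partitions
  scored by barcode-gap width and a permutation panmixia probability,
  averaged ranks, lower score = better (a documented surrogate for the
  ASAP web service).
* **Median-joining haplotype networks**, **PCoA**, and Table-style
  discrimination summaries (*k*/*n* with percentages).

A multi-compartment sequence simulator (`simulate_dataset()`) generates
32-sample, 6-taxon, 95-region synthetic studies — with per-region rate
heterogeneity, planted hotspots, population structure, haploid organelles
and a fixed-mosaic hybrid — so the whole pipeline runs and is tested
without any external data. See `vignettes/barcode-evaluation.Rmd` for the
model and every numerical design choice.

## Worked example

```r
library(barcodelim)

cfg <- simulation_config(seed = 42)        # the default synthetic study
ds  <- simulate_dataset(cfg)
sets <- build_datasets(ds$regions, default_dataset_definitions(cfg$region_plan))

variability_table(sets)
#>   code length n_variable n_parsimony_informative pct_variable pct_parsimony_informative
#> A    A   4662        407                     361        8.730                     7.743
#> B    B    840        150                     131       17.857                    15.595
#> C    C    840        143                     132       17.024                    15.714
#> D    D    785         42                      37        5.350                     4.713
#> E    E    288         16                      15        5.556                     5.208
#> F    F    298         21                      21        7.047                     7.047
#> G    G    340        183                     163       53.824                    47.941
```

The hotspot set G is by far the most variable per site, the mitochondrial
set B leads the full-length sets, and the nrDNA sets D/E trail — the
ordering the simulator's rate multipliers encode. The hotspot screen
recovers exactly the five planted regions:

```r
hs <- detect_hotspots(per_region_variability(ds))
hs$threshold
#> [1] 34.46284
hs$flagged
#> [1] "rps1"      "rps2"      "rps14"     "ycf3-psaA" "trnE-clpP"
```

Delimitation on the hotspot set, distance criterion:

```r
D <- k2p_pairwise(sets$G)
barcoding_gap_test(D, ds$metadata, "uncinata")
#> $verdict   : "success"
#> $max_intra : 0.0426      # largest within-taxon K2P distance
#> $min_inter : 0.131       # smallest distance to any other taxon

summarize_discrimination(delimit_taxa("distance", "G", ds$metadata, D = D))
#>   code   method n_success n_taxa rate          cell
#> 1    G distance         6      6  100 6/6 (100.00%)
```

Under the default (deliberately divergent) synthetic conditions all six
taxa show a barcoding gap on set G; lowering the simulated divergence or
raising intra-population diversity erodes this, which is exactly the
regime the criteria are meant to probe.

The numbered drivers under `analysis/` run the full study end to end
(simulation → variability → distances/trees → delimitation → networks →
ordination), printing what each stage finds and writing all tables under
`results/`. `run_pipeline(pipeline_config(...))` does the same in one
call, on synthetic or user-supplied data (per-region FASTA + metadata
TSV).

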