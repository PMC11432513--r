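---
title: "Evaluating multilocus barcodes and species delimitation in closely related conifers"
author: "barcodelim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating multilocus barcodes and species delimitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodelim)
```

## The problem

Closely related plant taxa — the dwarf mountain pines (*Pinus mugo* complex)
are the motivating case — are often near-identical at the classical plant
barcodes. Genome skimming recovers the high-copy genome fractions
(plastome, mitogenome, nrDNA cistron) and so yields dozens of aligned
regions per sample. The question this package addresses is: *which
combination of regions, if any, can discriminate such taxa, and under which
delimitation criterion?*

The workflow evaluates seven concatenated data sets built from the skimmed
regions — (A) plastid coding genes, (B) mitochondrial coding genes,
(C) plastid intergenic spacers, (D) the full nrDNA cistron
(18S–ITS1–5.8S–ITS2–26S), (E) ITS only, (F) the core barcodes
*matK* + *rbcL*, and (G) divergence hotspot regions — under three
delimitation criteria, and complements them with haplotype networks,
principal coordinates, and population-level divergence tables.

## The synthetic study

Real genome-skim accessions are not bundled with the package; instead
`simulate_dataset()` generates data with the statistical structure the
analysis assumes, so that every downstream stage is testable and every
reported number is recomputable from a seed.

**Model.** Each region evolves independently along a species tree under the
Kimura two-parameter (K80) model, simulated as an exact Markov jump
process: the number of substitution events per site on a branch of expected
length $d$ (in substitutions/site, after multiplying by the region's rate
multiplier) is Poisson($d$); each event is a transition with probability
$\kappa/(\kappa+2)$ and otherwise one of the two transversions, with
$\kappa = 2$ by default, matching the ts/tv ratio conventionally used for
these data. Every event is logged (site, from, to, type), which is what
makes the transition/transversion machinery directly testable rather than
only observable through distance estimates.

**Population structure.** Below the species tips, each population receives
a private branch (`population_divergence`, default $10^{-3}$
substitutions/site at multiplier 1) and each sample receives tip-level
noise at rate `within_population_theta`/2 (default $\theta = 5\times
10^{-4}$, so the expected intra-population pairwise diversity is
$\theta$). Neither magnitude is published for the real material; both are
configuration fields, not constants. The defaults make populations
distinguishable on organellar data (a few private substitutions per
population on the mitochondrial set) while keeping intra-taxon divergence
an order of magnitude below inter-taxon divergence.

**Compartments and the hybrid.** Organellar compartments are haploid: one
haplotype per sample, no heterozygosity representation. The hybrid taxon
(rhaetica) is a *fixed mosaic*: each whole compartment is copied from a
designated parent lineage — plastid and nrDNA from sylvestris (plastids are
paternally transmitted in pines), mitochondria from mugo — with no per-site
recombination. This reproduces the diagnostic signature of a stabilized
hybrid: it clusters with different parents depending on the compartment
analysed.

**Default scale.** The default region plan mirrors the genome-skim
inventory at roughly one tenth of full length: 57 plastid genes (including
*matK*, *rbcL* and the hotspot genes *rps1*, *rps2*, *rps14*), 18 spacers
(including *ycf3-psaA* and *trnE-clpP*), 15 mitochondrial genes, and the
five nrDNA parts with lengths proportional to the real cistron (1812,
2482, 158, 241, 3155 bp). Two deliberate departures from a literal 1/10
scaling, both fixed by an up-front power calculation rather than tuned
afterwards:

* **Divergence scale.** Branch lengths are set so that a baseline (1×)
  region shows a few percent variable sites across the 32-sample study. At
  the real pines' divergence (0.1–2% variable sites on full-length sets), a
  tenth-length region would often carry *zero* variable sites and nothing
  downstream would be estimable. The synthetic study is therefore "a more
  divergent pine complex", preserving the *ranking* structure
  (hotspots ≫ mitochondrial > spacers > plastid genes > nrDNA) rather than
  the absolute values.
* **Hotspot region length floor.** Hotspot regions are kept at 68 bp
  (≥ 60 bp) instead of ~20 bp. The hotspot screen flags regions above
  mean + 2 SD of percent variable sites; with 5 planted outliers among 95
  regions the threshold sits roughly halfway between baseline and hotspot
  variability, so a region needs enough sites for its observed percentage
  to concentrate around its expectation. A binomial calculation puts the
  per-region recovery probability near 1 at 68 bp but only ~0.9 at 20 bp,
  which would fail the intended ≥95% recovery across seeded runs.

What the generator does **not** emulate: alignment error and indels (gaps
appear only via the optional `missingness` mask), rate variation among
sites within a region, base-composition bias, heteroplasmy, and coalescent
gene-tree discordance (populations and samples hang below species tips; no
incomplete lineage sorting). Passing tests therefore demonstrate the
correctness of the estimators and criteria under a clean K80 world, not
robustness to real-data artefacts.

## Variability and the hotspot screen

Site classification uses unambiguous bases (A/C/G/T) only; gaps, N and
IUPAC codes count as missing, following the common desktop-software
convention. A column is *parsimony informative* if at least two states
each occur in at least two sequences; *variable* if it has at least two
states; *indeterminate* if fewer than two unambiguous characters remain.
Percentages are rendered half-up at 3 decimals, the rounding used by the
printed tables this output mirrors; discrimination rates use half-up at 2
decimals. Ranking ties are broken alphabetically by data-set code (a
documented, arbitrary but deterministic rule).

The hotspot threshold is $T = \bar{x} + 2s$ with $s$ the *sample* standard
deviation ($n-1$ denominator; screens of this kind are usually described
only as "mean plus two standard deviations", and the sample version is the
conservative choice for a threshold estimated from the observed regions). The inequality is strict, so a
zero-variance profile flags nothing. By default the screen runs jointly
over all compartments; note that a mean+2SD screen has an expected ~2%
upper-tail false-positive rate among background regions, so occasional
single extra flags are inherent to the threshold, not a defect.

## Distances

The K2P distance is
$d = -\tfrac{1}{2}\ln\!\big((1-2P-Q)\sqrt{1-2Q}\big)$
with $P$ and $Q$ the transition and transversion difference proportions
over pairwise-complete sites (pairwise deletion; a complete-deletion mode
is not provided because no analysis here needs it, but the site mask is
applied per pair). When $1-2P-Q \le 0$ or $1-2Q \le 0$ the distance is
undefined (saturation); such pairs are **masked as NA with a warning**, not
clamped, and every downstream consumer that needs them fails loudly. On
all default synthetic data sets the masked-pair count is zero.

Population-level divergence averages K2P over all cross-population sample
pairs; uncertainty comes from resampling alignment columns with
replacement (default $B = 1000$), consistent with distance-on-alignment
semantics (resampling samples would change the pair set, not the
distance's sampling noise).

## Trees and the monophyly criterion

Maximum-likelihood tree search is deliberately out of scope: the
tree-based criterion accepts any support-annotated newick (supports as
internal node labels by default; a bracketed branch-label dialect is also
read). The built-in desk-scale path is neighbour joining on the K2P matrix
with column-bootstrap supports — a documented substitute for an external
ML tree, adequate because the criterion consumes only bipartitions and
supports. Negative NJ branch lengths are clamped to zero with the excess
moved to the adjacent branch. Bootstrap replicates that produce a
saturated pair are dropped and logged; more than 10% dropped is an error.

A taxon is delimited when some internal edge induces a bipartition with one
side exactly equal to the taxon's samples *and* the edge's support strictly
exceeds 50 ("exceeding" reads as strict). Monophyly is assessed on
unrooted bipartitions, avoiding rooting assumptions. One subtlety: a
rooted binary newick duplicates one unrooted bipartition on the two root
edges, whose labels can disagree; the support used is the one on the
taxon's own clade edge, falling back to the mirror edge only when that
label is absent.

## The barcoding gap

The distance criterion succeeds when the minimum interspecific distance of
a taxon strictly exceeds its maximum intraspecific distance — pairwise
extremes, not group means, per the criterion's wording. Singleton taxa are
`not_assessable` (intraspecific distance undefined), and the summary
counts them as failures so the denominator stays fixed at the taxon count,
matching the $k/6$ arithmetic of the printed summaries.

## The ASAP surrogate

The published ASAP web service is not reimplemented; the package provides a
surrogate that preserves its interface: a nested ladder of candidate
partitions from hierarchical clustering, two ranked components per
candidate, and an averaged-rank score where lower is better. Single
linkage builds the ladder (threshold-connectivity matches the "assemble"
semantics; average linkage is available by flag), cut at every midpoint
between consecutive distinct pairwise distances plus 0 and ∞, with
duplicate groupings removed.

Each candidate with $2 \le$ groups $\le n-1$ gets

* $w$ = min between-group distance − max within-group distance (the
  barcode-gap width of its own grouping), ranked descending;
* a panmixia probability, ranked ascending.

The coalescent-based panmixia probability of the original is replaced by a
seeded permutation test, and — a deliberate design choice — the test is
attached to the **merge** that turns the candidate into the next coarser
one: over the samples of the merged groups, $p$ is the Monte-Carlo
probability that a random relabelling (sub-group sizes preserved) gives a
merge gap at least as large as observed. Conditioning on the candidate's
own grouping instead would let oversplit candidates win systematically:
single linkage hand-picks the tightest subsets, so no permutation can beat
their observed gap and they would receive the minimal $p$. The merge
formulation captures what panmixia means here — merging two fragments of
one real cluster looks panmictic (large $p$), merging two genuinely
isolated clusters does not — and singleton merges are untestable, getting
$p = 1$, which correctly deprioritises the all-but-singleton end of the
ladder. With this scorer the planted two-cluster matrix is recovered as
the best candidate in 100/100 seeded runs at the default settings.

A taxon succeeds under ASAP when some group of the best partition equals
exactly the taxon's sample set. Exact reproduction of the web service's
partitions or scores on real data is a non-goal.

## Haplotype networks

Samples share a haplotype when their sequences agree at every column where
both are unambiguous (missing-tolerant matching, closed transitively by
union-find; the exact masking behaviour of popular desktop tools is
undocumented, so the permissive rule is stated and tested rather than
guessed). The median-joining network follows the classical scheme:
Hamming distances over mutually unambiguous columns; a minimum spanning
network equal to the union of all minimum spanning trees (edge $uv$ kept
iff $d_{uv} \le$ the minimax path weight $+\ \varepsilon$, default
$\varepsilon = 0$); iterative addition of median vectors of connected
triplets when novel and cost-reducing; pruning of median vectors with
degree ≤ 2. The quasi-median step is restricted to per-site majorities —
a triplet with a three-state site contributes no median — a documented
simplification of the full procedure that leaves the classical toy cases
(chain, cycle, star, single Steiner point) exact.

## Ordination

PCoA is classical Gower scaling: double-centre $-D^2/2$, eigendecompose,
scale eigenvectors by $\sqrt{\lambda}$. No Lingoes/Cailliez correction is
applied by default (the workflow this mirrors names none); negative
eigenvalues are reported so distortion can be judged, and their axes are
dropped, truncating `k` with a warning when necessary. Axis signs are
fixed by forcing the largest-magnitude loading positive, making output
deterministic across platforms.

## Determinism and problem sizes

Every stochastic stage takes an explicit seed, and the pipeline
(`run_pipeline()`) derives per-stage seeds from one master seed; reruns are
byte-identical. The test suite exercises: 1000 random alignments against a
brute-force site classifier; 200 random additive matrices for exact NJ
recovery; 100 seeded planted-cluster runs for the ASAP surrogate; 50
default-scale simulations for hotspot recovery; 50 kb two-taxon alignments
for K2P parameter recovery (absolute error well under 0.002 at true
divergence 0.01); and 32-sample, 95-region synthetic studies for the
end-to-end pipeline. These sizes keep the whole suite in the low minutes
on a single core while leaving each check statistically meaningful.

## Known limitations

* The NJ + bootstrap path is a substitute for ML tree inference; supports
  are not comparable to ML bootstrap values, only to each other.
* The ASAP surrogate ranks partitions sensibly but its scores are not
  comparable to the web service's.
* The simulator's clean K80 world (no indels, no rate heterogeneity among
  sites, no gene-tree discordance) means real-data robustness is untested
  by design.
* The hotspot screen assumes outlier regions are a small fraction of the
  inventory; with many elevated regions the mean+2SD threshold loses power
  (this is a property of the screen, faithfully reproduced).
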