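---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery in `oscimhc`, the
assumptions behind it, the tunable parameters with their defaults, what
the synthetic-data generator does and does not emulate, and the design
choices made where the methodology left genuine freedom. It states no
empirical result that the test suite does not itself compute.

## 1. Allele filtering

Clone-derived MHC repertoires mix true alleles with PCR and sequencing
artifacts. A sequence is kept as a putatively functional allele only if
it (a) contains no in-frame stop codon, (b) contains no partial-codon
gap, and (c) differs from every other retained allele at **at least 3
nucleotide positions** (`min_nt_diff = 3`).

Choices the rule itself does not pin down:

- *"Disrupted reading frame"* is read minimally: a codon containing one
  or two gap characters disrupts the frame; a whole-codon gap is a clean
  codon deletion and is tolerated.
- The 3-difference rule is applied by **single-linkage clustering** of
  the pairwise Hamming distances (columns with a gap or `N` in either
  sequence are ignored), keeping the first cluster member in input
  order. Single linkage is the conservative closure of "differs by fewer
  than 3 sites from something already kept", and first-in-input-order
  makes the representative deterministic. An alternative reading —
  comparing each sequence to one chosen reference — is not implemented.
- No filter for mosaic/chimeric sequences is implemented: no operational
  criterion for them exists in the source methodology.

## 2. Diversity statistics

`S` counts columns with two or more distinct non-gap, non-`N` bases.
`k` is the mean count of differing columns over all unordered pairs,
with pairwise deletion; `pi` is computed **per pair over compared sites
and then averaged**, not as `k/L`. On gap-free data the two definitions
agree exactly (`pi == k / L` is asserted as a test invariant); they
diverge only when gaps make compared-site counts differ between pairs.

## 3. Partitioned dN/dS (modified Nei–Gojobori + Jukes–Cantor)

**Site counting.** Each codon position contributes one site, divided
between synonymous and nonsynonymous according to the weighted fates of
its three single-base mutants: a transition mutant has weight `R`, each
transversion mutant weight 1/2, so `R = 0.5` reproduces the classic
unweighted NG86 counting (each mutant weight 1/3). Mutants that create
stop codons are excluded and the remaining weights renormalized, so
`syn + nonsyn = 3` for every codon. `R` is a free parameter
(default 0.5) because the transition/transversion ratio actually used in
the original MEGA analysis is not recorded; the dN/dS ratio is fairly
insensitive to it, but absolute dN and dS are not.

**Difference counting.** For codons differing at *d* positions, all
*d*! mutational pathways are enumerated; pathways passing through stop
codons are excluded and the synonymous/nonsynonymous step labels of the
remainder are averaged with equal weight. If every pathway is blocked by
a stop (possible but rare), the count falls back to including blocked
pathways and flags the result.

**Aggregation.** Per sequence pair, proportions
`p = differences / sites` (site counts averaged over the two sequences;
codons containing gaps, `N` or stops deleted pairwise) are corrected as
`d = -(3/4) log(1 - 4p/3)` **per pair and then averaged** — the
mean-of-pairwise convention, not correction of the averaged proportion.
`p >= 0.75` (saturation) makes that pair's estimate undefined; such
pairs are dropped from the mean. ω is the ratio of the averaged dN to
the averaged dS and is reported as `NA` when dS = 0 — common for the
14-codon PBR partition within a single species' shallow repertoire.

**Uncertainty.** Standard errors come from bootstrap resampling of codon
columns *within* each partition (default 1000 replicates, seeded).

**PBR partition.** Exon-3 codons {5,7,8,9,23,25,38,60,61,62,65,66,68,73}
map to alignment codons through `frame_offset` (default 4: the amplicon
misses the first four, conserved, exon codons, so exon codon 5 is
alignment codon 1). The offset is exposed because the numbering frame is
a convention, not a property of the alignment.

## 4. Distances, neighbor joining, tree utilities

Distances are closed-form K2P or TN93, the latter with a gamma
rate-variation correction at shape `alpha = 0.78` (the model selected
for the original data; `alpha = Inf` recovers plain TN93). Base
frequencies for TN93 are estimated per pair over the compared sites;
saturated pairs (non-positive log arguments) are flagged `Inf`. Both
forms are cross-checked against `ape::dist.dna` in the tests.

Neighbor joining is the classic Saitou–Nei agglomeration with
Studier–Keppler updates, written here (rather than delegated to
`ape::nj`) to fix two contracts: ties in the Q matrix are broken by the
lowest (row, column) index pair in the current matrix order, and
negative branch-length estimates are clamped to zero. `ape::nj` serves
as an independent cross-check in the tests, and exactness on additive
matrices is an acceptance property. Bootstrap support resamples
alignment columns, rebuilds trees, and counts bipartition recovery;
replicates with saturated distances are dropped and counted.

**Ultrametricization** substitutes a mean-path-length recursion for
penalized-likelihood rate smoothing (not implemented): bottom-up, each
node's height is the mean over children of (child height + branch),
parents are lifted to their tallest child so no edge is negative, and
heights are rescaled so the total depth equals the mean original
root-to-tip distance. Consequence: chronogram-dependent quantities
(absolute AIC values of the clade models) are **not** comparable with
published values; the clade-model machinery is validated instead by
oracle equivalence, parameter recovery and model-selection calibration.

**Random topologies** for the permutation null are uniform over unrooted
binary labeled topologies, generated by sequential random edge addition.
The original null used MacClade's random trees, whose distribution is
not documented; uniform is the natural default and is stated here as an
assumption.

## 5. Fitch parsimony and the species-clustering test

The parsimony length of the species-designation character is computed
with the Hartigan counting rule (at each node, changes increase by the
number of children minus the maximal state-count), which is exact on
multifurcations and therefore handles the trifurcating root of an
unrooted NJ tree without rerooting. It is fuzz-tested against a
brute-force Sankoff dynamic program with unit costs.

The permutation test compares the observed steps with `fitch_length` on
`n_rand` random topologies carrying the same tip states (default 1000),
with `p = (1 + #{null <= observed}) / (n_rand + 1)`. Randomizing the
topology (not the labels) is the faithful null; label shuffling on the
fixed topology is also available (`null = "labels"`). Type-I behavior of
the topology null is calibrated in the acceptance suite.

## 6. GC content and Welch tests

GC is computed per sequence at each codon position over non-gap,
non-`N` bases. The unit of analysis for the clade comparison is the
**individual sequence** (not species means): the published degrees of
freedom (~223 for ~225 sequences) identify that choice. The outgroup is
excluded; songbirds are group *a*, so the sign of *t* follows
`mean(songbirds) - mean(non-passerines)`; two-sided p-values from the
*t* distribution with Welch–Satterthwaite degrees of freedom.

## 7. Brownian-motion clade models

Four models cross shared/different clade means with shared/different
Brownian rates; parameter counts are 2, 3, 3, 4 and comparison is by
`AIC = 2k - 2 lnL` (ML variance estimates, not REML). The tree root must
be the clade split (outgroup removed first), which makes the tip
covariance block-diagonal — the "censored" reading of the clade test.

Design choices:

- **Clade A's stem carries clade A's rate** and contributes shared
  variance to all its tips. This is what makes the stem-halving
  sensitivity analysis operative: halving the stem halves the shared
  variance available to absorb a clade-mean difference, so the
  different-means model gains support — the qualitative effect the
  sensitivity analysis is designed to expose.
- Because stem scaling necessarily breaks global ultrametricity, the
  ultrametricity precondition is enforced **within each clade** (each
  clade's tips equidistant from the root, tolerance `1e-6 ×` depth) —
  exactly the invariant the block-diagonal likelihood needs.
- Fitting: means are profiled out by GLS, σ² has a closed-form ML
  estimate, and the single free rate ratio is optimized on a log scale
  over `[1e-4, 1e4]` (`optimize`, tolerance `1e-10` on log-r, i.e. well
  below `1e-8` relative lnL). For the two-rate models σ² is reported on
  the clade-B scale with `sigma2_a = sigma2 × rel_rate_a` alongside,
  since "the" Brownian variance of a two-rate model is otherwise
  ambiguous.
- Tied tips (zero-length edges in estimated trees) make the covariance
  exactly singular; the Cholesky adds a diagonal ridge of `1e-10 ×` the
  mean diagonal, grown only as far as needed, before failing.

## 8. The synthetic-data generator

The generator emulates the statistical structure the analysis assumes:

- **Tree**: a root splitting two clades, coalescent species trees inside
  each, shallow coalescent allele subtrees (default 3–13 alleles per
  songbird species, 1–3 for database-derived non-passerines) replacing
  species tips, and one outgroup lineage. Ultrametric by construction.
  Defaults: 16 songbird species, 17 non-passerine species, 88 codons,
  root-to-tip depth 0.35 proposals/site with 30% in the clade stems.
- **Sequences**: a stop-free root sequence with third-position GC at the
  clade-A target; Poisson numbers of mutation proposals per edge; a
  proposal picks a uniform site and a replacement base with transition
  weight κ (default 2) and, at third positions, a GC bias; proposals
  creating stops are rejected; nonsynonymous proposals are accepted with
  probability `min(1, ω)` of the codon's partition and synonymous ones
  with `min(1, 1/ω)`. The symmetric synonymous thinning is a deliberate
  deviation from a pure "penalize nonsynonymous" scheme: without it,
  realized ω cannot exceed 1 and the generator could not produce the
  diversifying-selection regime (target `ω_PBR = 4`) it exists to test.
- **GC3 bias calibration**: naive replacement weights proportional to
  the target frequencies equilibrate visibly below target (≈ 0.10 low at
  κ = 2) because the per-site jump chain's stationary distribution also
  involves the total exit weights. The weights are therefore calibrated
  by solving (uniroot) for the stationary GC of the jump chain to equal
  the target exactly. Equilibration to within 0.01 of targets 0.70/0.78
  requires a deep tree (`mut_scale ≈ 20`, i.e. ~7 proposals/site
  root-to-tip); the GC3-recovery tests use that regime.
- **Traits**: Brownian motion started at each clade's mean at the root,
  with the clade-A rate applied to its edges including the stem —
  exactly the model the likelihood assumes.

What it does **not** emulate: recombination and gene conversion
(reticulate histories), codon-usage structure beyond GC3, rate variation
among sites beyond the partition ω targets, indels (simulated alignments
are gap-free), and base-composition differences at positions 1–2. A
green test therefore establishes correctness of the estimators on
tree-like, partition-structured data — not robustness to reticulation or
alignment error.

## 9. Calibration and recovery test design

- **Neutral ω calibration** uses `ω = 1` everywhere, GC bias off, and the
  site-count weight matched to the generator (`R = κ/2`: the generator
  gives the single transition weight κ against 1 per transversion, the
  counter gives it `R` against ½). The estimate is depth-dependent
  through the JC correction; across shallow and deep regimes it stays
  within the accepted [0.8, 1.25] band.
- **BM parameter recovery** is judged on the **median over five seeded
  replicate draws**: the rate-ratio estimator is unbiased but a variance
  ratio from 50+50 correlated tips has a sampling sd of ~0.29 on the log
  scale, so a single draw sits at the 1.5× bound roughly one time in
  seven; the median isolates estimator bias from draw noise. The
  recovery tree uses a short stem (5% of depth): with a long shared stem
  the clade mean is unidentifiable to better than a few trait units
  regardless of tip count, which would test the tree, not the estimator.
- **Pipeline smoke tests** feed the known simulated tree to the BM stage:
  a finite-data NJ tree need not recover reciprocal monophyly of the two
  clades (trans-species polymorphism makes this common in practice), and
  the clade models are undefined without it. With empirical data the NJ
  tree is used when it does separate the clades; `run_full_analysis`
  errors informatively otherwise and accepts `bm_tree` as an override.

## 10. Known limitations

- Absolute AIC/lnL values depend on the ultrametricization and are not
  comparable across branch-length substitutes (Section 4).
- The dN/dS counter reports pairwise-deletion, pathway-averaged
  estimates; it is not an ML codon model and has no site-specific ω
  output (PAML-style models are out of scope).
- The permutation null assumes exchangeability of topologies without
  taxonomic constraints.
- `filter_putative_alleles` assumes its input is one individual/species'
  repertoire; passing a mixed-species alignment merges across species.
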