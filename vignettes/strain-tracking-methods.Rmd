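---
title: "Window-based SNV similarity strain tracking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based SNV similarity strain tracking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsstrack)
```

## The problem

Longitudinal shotgun metagenomes of the human gut can be compared at the
level of *strains*: the dominant within-species genotype of a microbe in one
sample, summarized by its single-nucleotide-variant (SNV) pattern against a
species reference genome. For a pair of samples from the same individual the
question is whether the dominant strain of a species *persisted* (the same
genotype, up to a little within-host evolution and sequencing noise) or went
*extinct and was replaced* by an unrelated strain. Because an individual's
strain complement is close to a fingerprint, a well-chosen genome-wide
similarity score separates these two situations cleanly.

`wsstrack` implements that analysis end to end: reading per-species variant
calls and depth tracks, scoring sample pairs, calibrating per-species
decision cutoffs, classifying persistence versus replacement, and
cross-checking the calls with a neighbor-joining tree. It deliberately
starts *after* read processing: trimming, host-read removal, alignment and
variant calling are consumed as their standard outputs (FASTA, `samtools
depth` TSV, multi-sample VCF), not re-implemented.

## The WSS score

For two samples $a, b$ mapped to the same species reference of length $L$,
the reference is tiled into non-overlapping windows of $w$ bp (default
$w = 1000$; the last window may be shorter). Within a window the comparison
set is the union of the two samples' variant positions, minus positions
where either sample has no call *and* per-base depth below $d_{site}$
(default 5) — there its state is unknowable. At each retained position a
sample's state is its called allele index, or $0$ (reference observed) when
it has no call but adequate depth. The window similarity is the fraction of
retained positions with equal states, and

$$\mathrm{WSS}(a,b) \;=\; \frac{1}{|W|}\sum_{k \in W} \frac{m_k}{c_k},$$

the unweighted mean over the set $W$ of windows that (i) pass the depth
filter and (ii) have $c_k > 0$ comparable positions. Scores live in
$[0, 1]$; a pair with $|W|$ below `min_windows` (default 1) has no score
(the `NS` state).

Filters, with their defaults:

* **Sample QC** — a sample is excluded when breadth of coverage (fraction of
  reference positions with depth $\ge 1$) is below 0.30 or mean depth is
  below 3.5. Both thresholds are strict (`<`), so boundary values are
  retained. Mean depth is genome-wide (zeros included) by default; a
  `depth_over_covered` flag averages over covered bases instead, since
  either reading of "mean depth" is defensible.
* **Window depth filter** — a window is excluded for a pair when, in either
  sample, strictly more than 50% of its bases have depth below 5. The filter
  is applied per pair (similarity is a pairwise quantity, so one
  low-coverage sample invalidates the window for that pair only).

Design choices worth making explicit:

* Windows whose comparison set is empty are skipped rather than scored 1.0:
  absence of evidence is not agreement, and skipping keeps the score driven
  by informative sites.
* A missing call with adequate depth is an *observed reference* state; a
  missing call with inadequate depth is *unobserved* and excluded. This
  distinction is what lets near-reference strains still produce meaningful
  agreement.
* The mean is over windows, not sites, so a variant-dense window cannot
  dominate the genome-wide score.
* The exact window size and per-window formula of the original WSS tooling
  are not restated in the source study; this package's definition is an
  explicit reconstruction, isolated in `window_similarity()` /
  `compute_wss()` so it can be swapped, and the window size is a logged
  configuration knob rather than a constant.

## Cutoff calibration

Per species, a cutoff separates the *related* score distribution
(within-individual longitudinal pairs) from the *unrelated* one
(between-individual pairs), emulating the reference-cohort (HMP-based)
calibration of the published per-species cutoffs. `calibrate_cutoff()`:

1. With fewer than `min_per_class = 5` scores in either class, no cutoff is
   assigned (`CO:NA`); such species are excluded from classification.
2. If the classes are disjoint, the cutoff is the midpoint of the gap
   between `max(unrelated)` and `min(related)`.
3. Otherwise it is the crossing of Gaussian kernel density estimates of the
   two classes (Silverman's rule-of-thumb bandwidth per class, floored at
   $10^{-4}$ so degenerate zero-variance classes stay finite), searched on a
   fixed 512-point grid between the class means; among multiple crossings
   the one closest to the midpoint of the means wins. If the densities never
   cross inside the mean interval (near-identical classes), the point of
   closest approach is used.

The procedure is deterministic, and the cutoff always lies strictly between
the class means. Published cutoffs can instead be supplied verbatim through
the species table's `cutoff` column and used without recalibration. The
original cutoff-derivation procedure is not described in the source study;
density intersection is this package's documented stand-in.

Classification is strict: a pair is **related** iff `score > cutoff`,
otherwise **unrelated** — including exact equality, since related is defined
strictly as above-cutoff. Species without a cutoff yield
`not_classifiable`, which takes precedence over a missing score; pairs with
no computable score yield `no_score`. Summaries count only
related/unrelated pairs in percentage denominators, reporting the excluded
states in a separate column, mirroring the `CO:NA` / `NS` sentinels of the
published supplementary tables.

## Neighbor-joining concordance

As an independent cross-method check (standing in for a marker-gene
StrainPhlAn comparison), `snv_distance_matrix()` computes genome-wide
p-distances — mismatched states over compared positions, with the same
comparison-set rules as the WSS but no windowing — and `build_nj_tree()`
runs standard Saitou–Nei neighbor joining. Negative branch lengths (possible
on non-additive input) are clamped to zero with the deficit moved to the
sister branch, preserving the joined pair's path length. On additive
matrices the tree reproduces the input distances exactly.

`tree_relatedness()` calls a pair related when the leaf-to-leaf path
distance is strictly below a threshold. The published criterion, a branch
-length difference below 0.001, is stated for marker-gene trees built from
model-based substitution distances; on genome-wide p-distance trees the
distance scale is entirely different, so the threshold is an exposed
parameter rather than interpretation baked into the package. In the
acceptance suite the threshold is set to $1 - \mathrm{cutoff}$: on a
single-window fixture the p-distance is exactly $1 - \mathrm{similarity}$,
so this is the natural image of the WSS cutoff on the distance scale.
p-distances rather than Maximum Composite Likelihood distances are a
documented divergence: MCL is substitution-model machinery for marker
alignments, and a monotone distance suffices for a concordance check.

## The synthetic cohort generator

Real inputs to this analysis are terabyte-scale read sets; the generator
produces the *statistical situation* the analysis assumes, at desk scale,
written out as FASTA + multi-sample VCF + depth TSVs so the whole real-data
path is exercised. One simulated world per species:

* a uniform-random reference (default 50 kb — large enough for ~50 windows,
  small enough for fast property tests);
* per-strain haplotypes: each site independently polymorphic with
  probability `snv_density` (default 0.01, a typical within-species SNV
  density against a conspecific reference), alternate base uniform over the
  three non-reference bases;
* longitudinal persistence vs replacement: with probability
  `replacement_prob` a later timepoint carries a fresh independent strain
  (truth label unrelated); otherwise each polymorphic site's state is
  resampled to a different base with probability `drift` (default 0.02,
  small relative to between-strain divergence, emulating within-host
  evolution plus residual calling noise across months-scale intervals);
* observation: per-base depth Poisson with mean `mean_depth` (default 20)
  under an independent `dropout` mask (default 0.05 of bases uncovered — the
  one parameter neither stated nor implied upstream; chosen once as a modest
  uncovered fraction typical of ~20x per-species coverage), calls emitted
  only on covered sites, and each observed state perturbed with probability
  `call_error` (default 0.005);
* haploid genotypes throughout: WSS compares dominant-strain states, so the
  diploid-style conventions of a general-purpose caller are deliberately
  not simulated.

Truth labels for non-adjacent timepoints compose along the lineage: a pair
is related iff no replacement event lies between its timepoints. Everything
is deterministic given the seed, to the byte, on disk.

What the generator does *not* emulate — and hence what a green test does not
establish — includes strain mixtures within a sample (the dominant-strain
assumption is built in), alignment artifacts and reference bias,
indels/structural variation, GC-dependent or negative-binomial-overdispersed
coverage, and cross-species read misassignment. Tests against this world
verify the *scoring and decision machinery*, not variant-caller behavior.

## Numerical and degenerate-input policy

* Thresholds follow the printed inequalities strictly: breadth `< 0.30`,
  mean depth `< 3.5`, window low-fraction `> 0.5`, related `> cutoff`,
  tree-related `< threshold`. Boundary values therefore pass filters and
  classify as unrelated, respectively.
* Coordinates are 1-based inclusive in all file formats (VCF / depth TSV
  convention) and 0-based half-open internally for window arithmetic.
* Indels and other non-SNV VCF records are skipped with a warning count;
  the analysis is SNV-only.
* Merging pooled samples (e.g. multiple pre-treatment runs) happens at the
  profile level: depths add, and each variant position takes the
  depth-weighted majority state, with ties broken by the deeper input and
  then by the lower allele index — a deterministic, depth-respecting
  consensus. Whether the original pooling happened at read or VCF level is
  unstated upstream; profile-level merging is this package's stand-in.
* NJ pair selection breaks Q-matrix ties by the first pair in row-major
  order, making tree construction deterministic under permutation of input
  taxa (up to leaf-labeled isomorphism, which is what the tests assert).

## Scaling of the test suite

The acceptance properties (oracle equivalence on 100 random pairs,
drift-monotonicity, calibration recovery on a 400-pair cohort, regime
reproduction, NJ exactness, WSS/tree concordance, byte-level round trips)
run on 20 kb genomes to keep the whole suite inside a small CPU budget; the
scores concentrate tightly enough at this size that none of the stated
margins are close to binding. Larger genomes change runtimes, not conclusions, and
`simulation_config()` exposes every knob used.

## Known limitations

* The per-window similarity formula reconstructs the published method from
  its description; if the original tooling weighted windows or sites
  differently, absolute scores would shift while the related/unrelated
  separation logic would not.
* Calibration quality depends on the supplied cohort actually containing
  same-strain and different-strain pairs; the `CO:NA` path guards small
  classes but not mislabeled ones.
* The NJ concordance check inherits the scale caveat above: with the
  default 0.001 threshold on p-distance trees nearly everything is
  unrelated; set the threshold to the distance scale of your matrix.
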