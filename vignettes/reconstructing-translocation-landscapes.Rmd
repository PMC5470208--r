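---
title: "Reconstructing translocation regulatory landscapes from 4C-seq"
author: "TADfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing translocation regulatory landscapes from 4C-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A reciprocal translocation joins two chromosomes at a breakpoint and creates a
derivative chromosome. When both breaks fall *inside* topologically
associating domains (TADs), the two truncated domains can fuse into a single
novel regulatory landscape: enhancers native to one locus become physically
and functionally available to a gene from the other. 4C-seq measures, from a
chosen viewpoint fragment (typically a promoter), the genome-wide contact
profile of that viewpoint, and is well suited to mapping such fused
landscapes — but it needs a dedicated computational chain: a restriction
fragment coordinate system, signal processing that respects derivative
coordinates and allele dosage, a peak caller that separates specific contacts
from the polymer background, restraint-based 3D models that turn several
one-viewpoint profiles into an all-vs-all "virtual Hi-C", and a boundary
caller that locates TAD borders on that matrix. TADfusion implements this
chain together with a synthetic-data generator, so that the central
qualitative property — *a fused TAD bounded by the parental outer borders,
with no boundary at the breakpoint* — can be exercised end to end against
known ground truth.

## Fragment maps

`digestGenome()` scans each chromosome for literal occurrences of the primary
recognition site (DpnII's GATC by default) and places fragment boundaries at
the first base of every occurrence, scanning with step 1 so overlapping
occurrences all cut (GATCGATC yields cuts at 0 and 4). Only palindromic sites
are accepted, so a forward-strand scan is complete; N never matches. The cut
is placed at the site start rather than the enzymatic offset: 4C fragment-end
units only need a consistent coordinate convention, and nothing downstream
depends on the intra-site offset. Each fragment is flagged *blind* if no
secondary-enzyme site (Csp6I's GTAC) starts strictly inside it, and *short*
if it is under `minLen = 40` bp; `validFragments()` removes both classes.
"Smaller than 40 bp" is read strictly, so a 40 bp fragment is retained. The
blind-fragment rule is applied in the conventional 4C direction — a
primary fragment lacking an internal secondary site is unobservable in the
circularisation step — rather than to secondary fragments.

## 4C profiles

`assignReads()` counts reads whose 5' position equals a valid fragment-end
coordinate exactly; each valid fragment contributes two ends, and a cut site
shared by two adjacent valid fragments collapses to a single end so the
coordinate vector stays strictly increasing. Reads matching no valid end are
tallied as discarded, never silently dropped. Ends within
`exclusionRadius = 2` valid fragments of the viewpoint are masked and zeroed:
self-ligation and immediate-neighbour signal is an artefact of the assay, and
although the exclusion radius is not part of the published filtering rules,
leaving the dead zone in would dominate every downstream normalisation.

Smoothing (`smoothProfile()`) is a centered running mean over
`window = 30` ends — 14 before, self, 15 after — truncated at the chromosome
edges and renormalised by the actual window size, so a constant profile stays
exactly constant everywhere. Smoothing precedes normalisation (the published
order is unstated; the two operations commute up to a scalar, and smoothing
counts first keeps the RPM step a pure scaling). `normaliseRPM()` scales the
smoothed signal to one million total; `zscoreProfile()` standardises the RPM
layer over unmasked ends with the population (n) standard deviation, with
z = 0 for a constant profile. This plain standardisation is a documented
stand-in for the more elaborate Z-score recipe referenced in the 4C
literature; its role here is a configurable significance filter, not an
inferential statistic. `sideFractions()` reports the percentage of raw counts
on either side of an anchor within a flanking window, and within a domain
interval intersected with that window — the statistic used to summarise how a
promoter's contacts distribute around it and within its TAD.

## Derivative chromosomes

A breakpoint is specified half-open: `posA` is the first base of chromosome A
*not* retained, `posB` the first base of chromosome B retained, with an
optional junction insertion (a 22 bp duplicated fragment at the junction is
the motivating real-world case). Micro-homology is resolved by assigning
ambiguous bases to chromosome A. `buildDerivative()` emits the fused sequence
and an exact segment table; `nativeToDerivative()` / `derivativeToNative()`
round-trip every retained base.

`rescaleDerivative()` doubles raw counts on the far side of the junction
(including insertion bases): in a cell carrying one derivative and intact
homologs, viewpoint-side sequence is present on two alleles while far-side
sequence is unique to the derivative, so far-side signal is at half dosage.
The factor 2 follows from that allele arithmetic; the operation is guarded
against double application, and is applied to raw counts before smoothing.
`balanceSides()` addresses the complementary display problem — reads upstream
and downstream of the breakpoint mixing different allele populations — by
scaling the two sides toward the geometric mean of their flank means, a
symmetric, order-independent convention under which the two flank means come
out exactly equal.

## Peak calling

The background model is a two-sided monotonic fit: 4C signal decays with
genomic distance from the viewpoint, so the left arm is constrained
non-decreasing toward the viewpoint and the right arm non-increasing after
it. Each arm is the least-squares isotonic fit computed by the Pool Adjacent
Violators Algorithm with unit weights (implemented in `pava()`; the test
suite checks it against both `stats::isoreg` and a brute-force search over
the monotone cone). The two arms share the viewpoint position, where the
background takes the larger arm value — the upper envelope keeps the fit
unimodal. Residuals (observed − fitted) are thresholded at
`Q3 + 1.5 × IQR`, with quartiles computed by linear interpolation between
order statistics (R's default type 7; the published convention is unstated)
over both arms jointly — one residual distribution per viewpoint region.
"Above" is strict, so all-equal residuals yield no peaks. Runs of
consecutive above-threshold ends become peaks spanning the union of their
fragments' intervals (non-degenerate BED intervals, rather than isolated end
points), and peaks separated by less than `mergeGap = 500` bp merge —
strictly less, so a 500 bp gap keeps two peaks. `restrictToDomain()` clips a
peak set to a domain, for analyses where a downstream limit is taken from a
previously determined TAD border.

## 3D modelling and virtual Hi-C

`buildRestraints()` converts per-viewpoint profiles into spatial restraints
over particles of `binSize` bp, under the assumption that 4C signal is
inversely related to spatial distance. Binned signal passing the Z-score cut
gets a harmonic restraint to the viewpoint bin with target
`d = dMax − s·(dMax − dMin)`, where `s` is the min–max normalised binned
signal: the strongest bin maps to `dMin`, the weakest retained bin to
`dMax`, and the map is monotone decreasing throughout. Because 4C signal
spans orders of magnitude, `s` is computed on `log1p`-transformed signal by
default: with the raw scale nearly every mid- and long-range bin collapses
onto `s ≈ 0`, the targets all sit at `dMax`, and insulation differences
between domains disappear from the restraints entirely. Any monotone
increasing transform preserves the inverse-proportionality contract;
`transform = identity` restores the plain affine map. Adjacent bins carry
connectivity restraints at `dMin`, all remaining pairs an excluded-volume
lower bound at `dEv = 2·dMin` (active only when violated). Defaults
`dMin = 1`, `dMax = 100` arbitrary units, force constant 1.

`optimizeModel()` minimises total squared restraint violation by gradient
descent with bold-driver step adaptation, plus annealing cycles that perturb
the best-seen state with decaying Gaussian noise. Initial coordinates are
uniform in a cube of side `dMax·n^{1/3}`. All randomness is pre-generated in
R under `set.seed(seed)`, so a model is a bit-reproducible function of
(restraints, seed), and the best-seen state is returned, so the final energy
never exceeds the initial one. The optimizer replaces a general-purpose
integrative modelling engine: the scientific contract is restraint
satisfaction, and a dedicated quadratic-penalty minimiser keeps the package
self-contained. `runEnsemble()` runs seeds `baseSeed … baseSeed+n−1` and
keeps the lowest-energy subset; the reference configuration is 200 kept of
50,000 (0.4%), the package default a desk-scale 2,000/20.

Distance restraints cannot distinguish a structure from its mirror image, so
a selected ensemble is two enantiomeric populations. `clusterMirror()`
computes pairwise RMSDs after optimal rotation-only superposition (Kabsch
with the determinant constrained positive, so reflections never superpose),
clusters by average linkage cut at two, and verifies the mirror relationship
explicitly: reflecting one cluster medoid through a coordinate plane and
re-superposing must reduce the medoid RMSD by at least half. The most
populated cluster is kept (ties: lower medoid energy). `virtualHiC()`
averages pairwise distances over the kept cluster; contact mode returns
reciprocal mean distance with the diagonal set to the maximum off-diagonal
contact, which is the input form the boundary caller expects.

## Directionality index and boundary consensus

For bin *i* with window *w* bins, `A` sums contacts to bins *i−w…i−1* and
`B` to *i+1…i+w*; `DI = sign(B−A)·((A−E)²/E + (B−E)²/E)` with
`E = (A+B)/2`, zero when `A = B`. Windows reaching past the analysed region
use the mean of the observed matrix for every out-of-range cell — the border
imputation needed because only the region of interest is available. The DI
magnitude scales with the matrix, but its sign pattern, and hence the called
boundaries, are scale invariant.

Per-window boundary detection places a boundary where DI crosses from
negative to non-negative and both flanking extrema exceed
`strength = 1` standard deviation of the track. This sign-change heuristic
deliberately replaces the hidden-Markov segmentation of the original DI
method: it is deterministic, dependency-free and adequate at these
resolutions, and is documented as a deviation. `consensusBoundaries()`
repeats the call over a ladder of expected TAD sizes
(`window = round(size/binSize)`; default ten sizes log-spaced between 2× and
50× the bin size), clusters candidate bins across iterations by single
linkage within `tolBins = 1`, and scores each cluster by the fraction of
iterations containing a member. Selection takes candidates supported by all
iterations (`minSupport = 1`), or the `topK` best-supported when the
expected number of borders is known — the treatment appropriate for virtual
Hi-C, where per-iteration calls are noisier than on deep real Hi-C.
Candidates within one window of the region ends are flagged "edge" and
excluded from selection: a border at the end of an analysed region may be an
artefact of the truncation.

## The synthetic generator

`makeGenome()` plants primary sites at geometrically spaced cuts around a
mean fragment length and a secondary site near each fragment midpoint, while
scrubbing accidental site occurrences, so digestion recovers the requested
valid-fragment count within ~10%. `makeStructure()` builds target distances
`d_ij = |i−j|^0.5 · insulation^(boundaries crossed)`, with planted loops
dividing their pair's distance by the loop strength; the square-root kernel
is an equilibrium-globule-like choice with bounded growth — any monotone
kernel would serve the pipeline's contracts. A 3D embedding (classical
scaling refined by stress minimisation) is stored alongside; the formula
matrix is the canonical truth and the embedding its best Euclidean
realisation. `simulate4C()` inverts the modelling assumption: expected
counts are `coverage · d^(−α)/Σ d^(−α)` with `α = 2` by default (so counts
fall roughly as reciprocal bin separation, the familiar 4C decay), drawn
negative-binomial with `dispersion = 0.1` — overdispersed, as 4C counts are —
and spread evenly over the valid fragment ends of each bin.
`makeFusedLandscape()` joins two landscapes at intra-TAD breaks with *no*
insulation penalty at the junction, encoding the hypothesis under test: the
breakpoint itself is not a boundary, and the fused TAD runs between the two
parental borders flanking the breaks. Breaks at existing boundaries are
rejected, since the scenario requires intra-TAD breaks.

What the generator does *not* emulate: sequencing error, PCR duplicates,
mappability and GC biases, trans contacts, partial digestion, or cell-to-cell
structural heterogeneity beyond restraint noise. Tests passing on this
generator therefore demonstrate the correctness and internal consistency of
the chain — background fitting, coordinate bookkeeping, restraint geometry,
boundary logic — not robustness to every artefact of real libraries.

## Study conditions for the end-to-end property

The fused-TAD closure check runs the full chain — fused landscape, simulated
overdispersed 4C, profiles, restraints, ensemble, virtual Hi-C, boundary
consensus — on two 40-bin parents (two TADs each, insulation 2.5, 5 kb bins)
broken at bins 30 and 5, giving a 65-bin derivative with parental borders at
bins 20 and 40 and the junction at bin 30. Conditions: 11 viewpoints every 6
bins; all observed bins restrained (`zCut = −Inf` — with the plain
standardisation used for Z-scores, a `z > 0` cut keeps only near-viewpoint
bins and leaves the model under-constrained between viewpoints, so the
significance filter is left open in simulation, where there is no
library-level noise floor to suppress); `dMax = 30` so harmonic targets are
realisable within the connectivity chain of a 65-bin region; 400 models with
the top 20 kept, 150 iterations over two annealing cycles; consensus over
window sizes of 4–12 bins with `topK = 2` (the expected border count, the
same top-two treatment the source analysis applied to its virtual Hi-C).
Success per seed requires both parental borders within ±1 bin and no
boundary at the junction bin. Other problem sizes used by the test suite and
`scripts/acceptance.R`: 2,000-fragment genomes with ten strength-4 loops for
peak recovery (20 replicates), 36-bin three-TAD matrices under 20%
multiplicative noise (50 replicates), and a 100-bin two-TAD structure with
five viewpoints and a 2,000-model ensemble for virtual-Hi-C fidelity.

## Numerical choices and limitations

Quantile convention type 7; strict inequalities at the peak threshold and
merge gap; PAVA ties pooled to exact block means; the DI denominator `E` is
never zero off the `A = B` branch; degenerate inputs (constant profiles,
all-equal residuals, identical ensembles, single-model clusters) take
defined, tested paths rather than erroring. Known limitations: the Z-score
is a plain standardisation, not a background-aware significance model; the
boundary caller's sign-change heuristic can fragment very noisy DI tracks
(mitigated by the consensus); restraint targets are affine in transformed
signal rather than calibrated physical distances, so virtual Hi-C is
interpretable in ranks, not nanometres; and the optimizer is a local method —
ensemble diversity, not per-model global optimality, is what the selection
step relies on.
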