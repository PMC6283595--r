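---
title: "Methods: quantifying bimodal TAD regulation with tadquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying bimodal TAD regulation with tadquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadquant)
```

# The problem

Gene clusters such as *HoxD* sit at the junction of two topologically
associating domains. Enhancers in the telomeric domain (T-DOM) drive an
early, proximal program; enhancers in the centromeric domain (C-DOM)
later take over for the distal program. The measurable signature of this
switch is a *reallocation of chromatin contacts*: a viewpoint inside the
cluster directs most of its contacts into T-DOM in proximal cells and
shifts a large fraction of them toward C-DOM in distal cells. `tadquant`
quantifies that signature from 4C-seq viewpoint profiles, capture Hi-C
matrices, and ChIP-seq enrichment tracks, and ships a generative model
of such a locus so the whole pipeline is testable against known truth.

All coordinates are 0-based half-open throughout (the BED convention);
1-based coordinates exist only at the GRanges boundary inside the I/O
helpers. This makes interval arithmetic (midpoints, containment,
padding) free of off-by-one corrections in every quantification.

# 4C viewpoint quantification

## Normalization and smoothing

Raw per-fragment scores are divided by the mean raw score of
non-excluded fragments whose midpoint lies within ±W of the bait
midpoint. W defaults to 1 Mb — wide enough to average over local
restriction-site density but local enough to track the viewpoint's own
visibility; 2 Mb is the conventional choice for deletion alleles whose
rearranged neighborhood makes the 1-Mb window unrepresentative.
Fragments outside the window are rescaled by the same constant, so the
window's mean normalized score is exactly 1 and profiles from libraries
of different depth are directly comparable. Normalization is idempotent
by construction.

Window membership is decided by fragment *midpoint* (any-overlap is the
other defensible reading; midpoint was chosen because it makes window
membership, domain assignment and region membership one single
convention with no double counting). The bait fragment and its two
flanking fragments are excluded by default: self-ligation and
undigested-template artifacts dominate them in real 4C libraries. A
user-supplied exclusion list replaces or extends this.

Smoothing is a running mean over up to k = 11 fragments centered on each
fragment — the window is truncated at locus ends rather than emitting
missing values, keeping every position defined and totals preserved away
from edges. Excluded fragments contribute to neither numerator nor
denominator. Smoothing exists for display and boundary-eye-balling only:
**all quantifications use the pre-smoothing normalized scores**, since a
running mean smears signal across region boundaries.

## Contact fractions

The domain contact fraction of domain *d* is the summed normalized
signal of non-excluded fragments midpoint-assigned to *d*, divided by
the same sum over the whole domain set. The set is {cdom, tdom} in the
standard design and {cdom, tdom, next_tad} for deletion alleles where
the fused neighboring TAD recruits contacts. Fractions over the set sum
to 1 whenever the denominator is positive; a zero denominator is an
error, not a silent NaN. Named regulatory regions (CS39-, CS93-,
island-III-like elements) are quantified against the *same* denominator
after symmetric ±10-kb padding, so region fractions are directly
comparable to domain fractions. The gene cluster itself can be excluded
from all sums (`exclude_cluster`), which matters when the cluster
overlaps a domain after a rearrangement.

## Paired testing

Condition differences are tested per fragment with a paired two-sided
Wilcoxon signed-rank test on the normalized scores of fragments in the
padded region. Zero differences are dropped before ranking; ties get
midranks. For n ≤ 25 pairs the null distribution is computed exactly by
dynamic-programming convolution over the doubled midranks — the same
distribution a literal 2^n sign enumeration yields (the test suite
verifies this against a brute-force enumeration for n ≤ 12), but at
polynomial cost and still exact under ties. Above 25 pairs the normal
approximation with the standard tie variance correction and a 0.5
continuity correction takes over. Tests are two-sided because no
direction is privileged a priori. Each result carries
`delta_fraction` — the region's contact fraction in condition B minus
condition A — so "reduced from 8% to 3%" statements are one call.

Degenerate inputs follow a fixed policy: all-zero differences give
statistic 0 and p = 1 with a warning; a single nonzero pair gives the
exact p = 1.

# Capture Hi-C

Pairs carry fragment-middle positions and are kept when
min(MAPQ1, MAPQ2) ≥ 30 — the threshold is inclusive (the common-practice
reading of "above 30" in alignment pipelines) and exposed as a
parameter — and both mates lie in the capture span. Binning increments
`counts[i, j]` and `counts[j, i]` per pair, the diagonal once.

## Balancing

Iterative correction: bins with raw marginal below `min_marginal`
(default 10 counts — below that, a bin's weight is noise) are masked;
per-bin biases are updated multiplicatively until the coefficient of
variation of unmasked marginals falls below 1e-5 or 200 iterations. The
scale convention sets every unmasked row sum to 1, so `balanced = W
counts W` with explicit per-bin weights. Balancing a balanced matrix
changes the weights by less than the tolerance (idempotence, tested).

## Subtraction and sub-matrix tests

Balancing determines a matrix only up to a constant, so before
subtraction each balanced matrix is scaled to unit total over its
unmasked cells. This makes the difference map antisymmetric under
operand exchange and exactly invariant to rescaling either input — the
two properties a differential map must have to be interpretable. The
union of the bad-bin masks is NA in the output. Sub-matrix differential
tests apply the signed-rank machinery to corresponding unmasked bin
values of the two scaled matrices restricted to a rows × cols rectangle.

## Boundary detection

The diamond bin-signal at bin i is the mean balanced contact between the
w bins ending at i and the w bins starting at i + 1, truncated at matrix
edges and skipping masked cells. Within a TAD the diamond is filled;
across a boundary it empties, so boundaries are minima. The default is
w = 28 at 10-kb bins; calling at 5-kb bins warns, because masked gaps
are typically too numerous at that resolution.

The caller simplifies the turning-point fit of the published diamond
algorithm to strict local minima within a ±w neighborhood, followed by a
statistical filter: a one-sided rank-sum test of the candidate's diamond
cells against the *flanking diamonds centered w bins to either side*.
The flanking diamonds have the same cell-distance composition as the
candidate's, so pure distance decay cancels out of the comparison — the
naive alternative (testing the diamond against the candidate's own
within-triangle cells) rejects everywhere under decay alone, because
diamond cells span systematically larger distances. Candidate p-values
are Bonferroni-corrected over the number of candidates so that a
boundary-free matrix stays boundary-free at the 0.05 threshold.
Candidates closer than w bins resolve to the lower signal. The reported
position is the bin start of the first bin of the downstream domain.

# ChIP quantification

Reads are extended to 300 bp from their 5′ end in their strand
direction (the typical sonicated-fragment length; extension 0 keeps raw
intervals) and counted into 25-bp bins by extended-interval overlap.
Ratio tracks scale each library to reads-per-million of its own total
first — "normalized" is read as RPM because depth invariance is exactly
the property cross-sample enrichment comparisons need; a scale-to-
smaller-library mode would serve equally and RPM is simply fixed and
documented. The pseudocount (0.5, applied on the RPM scale after
scaling) bounds every bin away from log2 singularities. Region
enrichment applies the same ratio to region read counts. 1x-depth
scaling multiplies by `effective_genome_size / (total_reads ×
read_length)`; the effective genome size is a required input and never
guessed.

Read extension widens a region's effective counting window by up to the
extension length on each side; for ≥10-kb regions this perturbs the
log2 ratio by only a few hundredths, but enrichments of sub-kilobase
regions at extension 300 should be interpreted with that dilution in
mind.

CTCF orientation is a log2-odds PWM scan against a uniform background
on both strands; the strand of the larger best score wins, with calls
inside a 1e-6 score tolerance returned as "ambiguous" (palindromic
motifs land here by construction). Positions containing N are skipped.
Reverse-strand hits are reported at their forward-strand start.

# The synthetic locus generator

The generator emulates the data *structure* of a two-TAD locus, not its
sequence biology:

* geometry (defaults): a 3-Mb locus holding a ~397-kb telomeric domain,
  a ~96-kb gene cluster, a ~285-kb centromeric domain and a ~1.1-Mb
  next TAD, with CS39/CS93-like proximal enhancers and island-III/Prox-
  like distal enhancers; the viewpoint sits inside the cluster;
* sequence: uniform-random DNA scrubbed of accidental recognition
  sites, with sites planted at log-normal spacings (sdlog 0.5) around
  the requested median fragment length (default 1.5 kb). Log-normal
  rather than exponential spacing keeps the fragment count at
  locus_length / median within ~15%, matching the way a target median
  is naturally budgeted; a rare accidental site recreated at a planted
  junction can shift the count marginally;
* 4C signal: expected counts decay as distance^-alpha (alpha = 1, the
  typical sub-Mb contact-frequency scaling) and are partitioned into
  fixed expected shares — 0.80 to the two domains, split rho : 1 - rho
  between cdom and tdom, 0.06 cluster, 0.06 next TAD, 0.08 elsewhere.
  Because the split is exact in expectation, the true two-domain cdom
  fraction *is* rho; enhancer multipliers reshape signal within a
  domain without changing its total, so they sharpen profiles without
  moving the ground truth. The two default conditions use rho = 0.26
  ("proximal", telomeric fraction 0.74) and rho = 0.51 ("distal",
  0.49) — a reallocation of 0.25, the magnitude of the
  proximal-to-distal switch the package is designed to measure. Counts
  are Poisson by default; a negative-binomial option (dispersion 0.1)
  models the over-dispersion of real 4C fragment counts;
* CHi-C: pair probabilities on a 5-kb lattice with the same decay,
  attenuated by `insulation_factor` (default 0.2) across the planted
  boundary, plus symmetric enhancer × cluster stripe blocks — the
  simplest structure that makes subtraction maps and sub-matrix tests
  meaningful. Positions are lattice-cell midpoints, mirroring the
  fragment-middle convention. A configurable fraction of pairs receives
  sub-threshold MAPQ to exercise the filter;
* ChIP: input reads uniform; ChIP reads drawn from a density of 1 over
  background and `fold` over each enriched region, so the expected
  RPM ratio over a region is its fold diluted by the global weight
  excess log2(L / Z). The default geometry keeps enriched regions
  ≲1.5% of the locus, bounding that dilution near -0.02 so a fold-4
  region reads out close to log2 4 = 2.

Every generator is seeded and byte-deterministic: the same configuration
and seed reproduce identical sequences, counts, pairs and reads; the RNG
state of the caller is restored afterwards.

What passing tests on this generator do **not** show: robustness to
mappability artifacts, PCR duplicates, restriction-site density biases,
copy-number variation, trans contacts, or the heavy tails of real
contact maps. The generator validates the estimators' arithmetic and
statistical calibration, not their behavior on pathological genomic
context.

# Problem sizes and numerical choices

The test suite validates, among others: the exact signed-rank branch
against full 2^n enumeration on 250 random paired datasets (n ≤ 12);
digestion against a regex-scan oracle on 1,060 random kilobase
sequences; fraction recovery at depth 1e5 across telomeric regimes
{0.40, 0.49, 0.70, 0.74, 0.83} over 100 seeds each (within ±0.02 in ≥
95%); the 0.25 reallocation scenario over 20 seed pairs (detected at
p < 0.01, recovered within ±0.03); planted-boundary recovery on 150-bin
matrices (contrast 4, Poisson noise, ≥50 expected near-diagonal counts)
over 100 seeds with w = 28 (within ±1 bin in ≥95%); balancing to CV <
1e-5 with idempotence; subtraction antisymmetry and scale invariance on
100 random pairs; fold-4 ChIP recovery at 2e6 reads (log2 enrichment
2.0 ± 0.1); strand antisymmetry of orientation calls on 560 random
sequences; and byte-determinism of the full demo. These sizes were
chosen as the smallest at which the binomial/Poisson error bounds make
the stated tolerances comfortable.

Numerical details worth knowing: window means use exact cumulative
sums; the exact signed-rank DP works on integer doubled midranks, so no
floating-point rank comparisons occur; ICE convergence is measured on
the marginal CV, and the 2 × 2 closed form is reproduced exactly;
subtraction compares at unit total, so values are scale-free; PWM
log-odds floor probabilities at 1e-9 to keep scores finite.

# Known limitations

* The fragment→domain midpoint convention differs by at most one
  boundary-straddling fragment from an overlap convention; at realistic
  fragment sizes this is far below the reported precision.
* The boundary caller is a deliberate simplification of the published
  diamond algorithm (strict minima + distance-matched rank-sum filter
  instead of a piecewise-linear turning-point fit); it shares inputs,
  window semantics and output conventions but can differ on shallow or
  closely spaced boundaries.
* `compare_region_signal` treats fragments as exchangeable paired
  observations; spatial autocorrelation along the profile is not
  modeled, so p-values on wide regions are anti-conservative in the
  presence of strong local correlation — the conventional caveat for
  per-fragment signed-rank testing.
* The CHi-C simulator draws positions on a lattice; sub-bin positional
  noise is not modeled.
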