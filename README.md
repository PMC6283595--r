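# tadquant

Quantification of chromatin contacts and enrichment at gene clusters
sitting on the boundary between two topologically associating domains
(TADs).

Developmental gene clusters such as *HoxD* are regulated bimodally: two
flanking TADs — a telomeric regulatory domain (T-DOM) and a centromeric
one (C-DOM) — take turns driving the cluster, and the switch between them
reallocates a sizeable fraction of a gene's chromatin contacts from one
domain to the other. `tadquant` implements the quantitative machinery
needed to measure that switch from three complementary assay types, plus
a fully seeded synthetic locus generator so that every stage can be
validated against known ground truth without any external data.

## What it computes

**4C-seq viewpoint profiles.** Per-fragment scores on a restriction
fragment map are normalized to the mean score of fragments within ±W of
the bait (W = 1 Mb by default, 2 Mb for large deletion alleles) and
smoothed with an 11-fragment running mean. The headline statistic is the
*domain contact fraction*

    frac(d) = sum of normalized signal in domain d
              -------------------------------------- ,
              sum over all domains in the domain set

with the domain set either {C-DOM, T-DOM} or, for deletion alleles,
{C-DOM, T-DOM, next TAD}; fragments are assigned to the unique domain
containing their midpoint. Differences between conditions are tested
per fragment with a paired two-sided Wilcoxon signed-rank test whose
small-sample branch (n ≤ 25) is exact over the full 2^n sign-flip null
(valid under ties), via dynamic-programming convolution.

**Capture Hi-C matrices.** Contact pairs (fragment-middle positions) are
kept when both MAPQs are ≥ 30 and both mates fall in the capture span,
binned at 5 kb, and balanced by iterative correction until the unmasked
marginals are equal (CV < 1e-5). Balanced matrices are compared by
unit-total scaling and subtraction, sub-matrix differences are tested
with the same signed-rank machinery, and TAD boundaries are called from
the diamond bin-signal (window 28 at 10-kb bins) as statistically
filtered local minima.

**ChIP-seq enrichment.** Reads extended to 300 bp from their 5′ end are
binned at 25 bp; ChIP and input tracks are scaled to reads-per-million
and compared as log2((chip + 0.5) / (input + 0.5)); region enrichments
use the same ratio on region read counts, and CTCF coverage can be
scaled to 1x genome-wide depth. CTCF site orientation is called by a
log2-odds PWM scan of both strands with an explicit ambiguity tolerance.

## Worked example

Two simulated conditions of the default synthetic locus differ only in
how the viewpoint splits its contacts between the domains (telomeric
weight 0.74 versus 0.49):

```r
library(tadquant)

cfg    <- synthetic_locus_config()
locus  <- generate_locus(cfg, seed = 1)
raw_p  <- simulate_fourc(cfg, "proximal", locus = locus, seed = 101)
raw_d  <- simulate_fourc(cfg, "distal",   locus = locus, seed = 102)
prof_p <- normalize_profile(locus$fragment_map, raw_p, cfg$bait)
prof_d <- normalize_profile(locus$fragment_map, raw_d, cfg$bait)

domain_fractions(prof_p, locus$annotation)
#> Contact fractions (cdom + tdom):
#>   cdom        26.0%
#>   tdom        74.0%
#> ...
domain_fractions(prof_d, locus$annotation)
#> Contact fractions (cdom + tdom):
#>   cdom        51.0%
#>   tdom        49.0%
#> ...
```

The proximal condition keeps 74% of its domain contacts telomeric; the
distal condition has reallocated 25% of them to the centromeric domain.
A per-fragment paired test localizes part of that loss to the CS93-like
enhancer region:

```r
compare_region_signal(prof_p, prof_d, "CS93", locus$annotation)
#> Signed-rank test, region CS93: W = 66, n = 11, p = 0.000977, delta = -0.008
```

(W is the signed-rank statistic over the 11 shared fragments in the
padded region; delta is the region's contact fraction in the second
condition minus the first.) On the capture Hi-C side, the planted
boundary at 1.42 Mb is recovered exactly:

```r
span  <- genomic_interval(cfg$chrom, 0, cfg$locus_length)
pairs <- filter_pairs(simulate_chic(cfg, "proximal", seed = 103), span)
cm    <- balance_ice(bin_pairs(pairs, span, 10000))
call_boundaries(cm, w = 28)
#>   bin_index position  bin_signal       p_value window_w
#> 1       143  1420000 0.001093394 1.516098e-268       28
```

`run_demo("out/")` chains all of the above (both conditions, 4C, CHi-C
and ChIP stages) into provenance-stamped TSV/JSON reports;
`inst/scripts/tadquant-demo.R` wraps it for the shell.

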