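---
title: "Quantifying bivalent promoters from H3-normalized ChIP data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bivalent promoters from H3-normalized ChIP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bivalr)
```

## The biological question

During mammalian sex determination, a bipotential population of gonadal
supporting cells commits to either the Sertoli (testis) or pregranulosa
(ovary) fate. Many of the genes that drive one fate or the other sit, before
commitment, in a *bivalent* chromatin state: their promoters carry both the
active H3K4me3 and the repressive H3K27me3 mark, poised for either
activation or stable silencing. Upon differentiation a bivalent promoter can
*resolve* — lose one of the two marks — or remain bivalent, keeping the
alternate fate repressed but accessible.

bivalr implements the quantitative side of this analysis: H3-normalized
promoter enrichment, four-state chromatin classification, domain calling,
state dynamics across developmental timepoints, TSS metaprofiles, and
ChIP-qPCR quantification, together with a synthetic-data generator that
carries known chromatin-state truth so every stage can be validated end to
end.

## The enrichment model

The unit of quantification is the 4 kb promoter window, `[TSS - 2000,
TSS + 2000)` in 0-based half-open coordinates (symmetric, hence
strand-independent; windows clipped at chromosome edges are kept and
flagged, and their counts are not rescaled for the lost width). For each
window and mark we count ChIP tags — each aligned read reduced to its
single 5' base, duplicates retained — and form the H3-normalized log2
enrichment

$$E_m \;=\; \log_2 \frac{c_m \cdot K/N_m + p}{c_{H3} \cdot K/N_{H3} + p},$$

where $c$ are window tag counts, $N$ library totals, $K$ a fixed reference
depth (default $10^6$, i.e. counts per million) and $p$ a pseudocount
(default 1 scaled tag). Dividing by an H3 ChIP from the same cells controls
for nucleosome occupancy and recovery, so $E_m$ measures the methylated
fraction of H3 rather than raw coverage.

Two numerical choices matter here:

* **The pseudocount is applied after depth scaling.** Scaling to a fixed
  $K$ first makes $E_m$ *exactly* invariant to duplicating every tag in
  both libraries (sequencing the same library twice as deep changes
  nothing), keeps $E_m$ finite for empty windows, and makes the
  zero-vs-zero window sit at exactly 0. Applying the pseudocount to raw
  counts before scaling would break the invariance whenever
  $c_m \neq c_{H3}$.
* **A raw-ratio mode is retained** (`norm_config(depth_scale = FALSE)`) for
  sensitivity analysis, since published "normalized to H3" values do not
  always document their depth handling.

## Chromatin states

A promoter is classified as `K4_ONLY`, `K27_ONLY`, `BIVALENT` or `NEITHER`
under one of two operational definitions:

* **Threshold mode** (`classify_threshold()`): a mark is "high" iff its
  $E_m$ is *strictly* greater than the cut (default 2.5 log2 units — the
  conventional "high enrichment" line on promoter scatterplots; a value
  exactly at the cut is not high).
* **Peak-overlap mode** (`classify_peak_overlap()`): a mark is "present"
  iff at least 1 bp of a called domain overlaps the 4 kb window (the
  bedtools default; intervals are half-open, so a domain abutting the
  window boundary does not count).

On synthetic data with well-separated emission rates the two definitions
agree on well over 90% of genes; on real data they emphasise different
things (threshold mode is quantitative and graded, peak mode is
significance-gated), which is why both are first-class and every
`state_table` records its `mode`. Replicate tables can be combined by
per-mark union or intersection (`combine_state_tables()`); per-replicate
tables are the default because published pipelines rarely state which
combination they used.

## Domain calling

`call_domains()` tiles the genome in non-overlapping windows — 5 kb for the
broad H3K27me3 domains, 1 kb for sharp H3K4me3 promoter peaks
(`default_domain_config()`) — and tests each window's tag count against a
Poisson null whose mean is the local flanking rate (tags within ±10
window-widths, excluding the window, scaled to window width), floored at
the genome-average rate so tag deserts cannot manufacture infinite folds.
Windows with Benjamini–Hochberg $q \le 0.001$ and fold $\ge 4$ over the
floored local mean are kept; significant windows within one window-width
are merged, and count, fold and p-value are recomputed over the merged
span (the reported $q$ is the minimum over merged members, so the
significance guarantee is preserved).

This is a re-implementation in spirit, not in internals, of the
histone-style peak callers commonly used for such data; it is therefore
validated by *calibration*, not by output identity: on uniform synthetic
libraries across 100 seeds the count of falsely significant windows must
not exceed the nominal per-window level (one-sided binomial test — the
discrete Poisson tail makes BH conservative under the null, so observing
fewer rejections than $\alpha n$ is the expected direction), and implanted
10-fold 5 kb domains must be recovered in ≥ 95% of seeds. Whether the H3
library should enter the calling statistic as an input control (rather
than only the enrichment normalization) is left as a possible extension;
the local-flank background already absorbs most of what an input track
would provide at desk scale.

## State dynamics

`transition_table()` cross-tabulates two state tables over an identical
gene universe (a mismatch is an error, not a silent intersection) into a
4×4 count matrix, optionally restricted to a gene set.
`resolution_fraction()` reports `100 * count / row_total` with
nearest-integer rounding alongside the raw counts; `resolved_fraction()`
is the complement of remaining in place. "Resolved to active" is
specifically `BIVALENT → K4_ONLY`. Published resolution percentages for
sex-determining gene sets are reproduced exactly by this arithmetic from
their printed count pairs (all five printed pairs are consistent with
nearest-integer rounding), which is the correct desk-scale check given
that the underlying genome-wide tag data are not redistributable.

`expression_by_state()` associates expression log-intensities with states:
per-state mean ± SEM plus pairwise two-sample t-tests. Welch's
unequal-variance test is the default even where legacy analyses used the
pooled form, because state groups have no reason to share a variance;
`var_equal = TRUE` restores the classical test. Outlying values are
retained — trimming is a plotting choice, not an inferential one.

## Metaprofiles

`metaprofile()` averages H3-normalized signal in fixed bins around TSSs
(default ±5 kb in 1 kb bins; a 20 kb preset is available). The per-gene,
per-bin IP/H3 ratio (same pseudocount and depth constants as promoter
quantification) is computed first and then averaged across genes
(*ratio-then-average*). This makes the profile of a gene universe exactly
the gene-count-weighted mean over any partition of it — the property that
makes gene-set profiles comparable — at the cost of a small convexity bias
upward when per-bin H3 counts are low. The alternative
(*average-then-ratio*, `profile_config(mode = "average_then_ratio")`) is
exposed because figure pipelines differ silently on this point. For
minus-strand genes the bin index is mirrored, which makes strand reversal
flip the profile *exactly*, not merely approximately.

## ChIP-qPCR

Native MNase ChIP is quantified as the bound/unbound ratio
$2^{CT_{unbound} - CT_{bound}}$ with the IgG control subtracted per
replicate before averaging (mean ± SEM across replicates); negative
post-subtraction values are clamped to 0 with a warning, since background
above signal means "no detectable enrichment", not negative occupancy.
Cross-linked ChIP and ChIP-re-ChIP are quantified as percent input with
the input CT first adjusted for its dilution
($CT_{input} - \log_2(1/f)$ for an input fraction $f$, e.g. 10%); the
re-ChIP no-antibody control is handled exactly like IgG. Primer efficiency
is fixed at 2 (the plain ΔCT form); efficiency correction and melt-curve
QC are out of scope.

## The synthetic-data generator

`synthetic_config()` defines the simulated study. Defaults, chosen once as
a realistic desk-scale experiment:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 400 | enough for 3-SE census/transition checks, small enough for seconds-scale runs |
| `chrom_len` | 40 Mb | one gene per 100 kb — the mammalian gene density, see below |
| `lambda_h3` | 30 tags / 4 kb window | moderate-depth MNase H3 ChIP |
| `ip_high_mult`, `ip_low_mult` | 12×, 0.5× | true depth-scaled log2 ratios ≈ +3.5 and −1, straddling the 2.5 cut |
| `background_rate` | `lambda_h3 / 4000` per bp | nucleosome density (hence H3 signal) is roughly uniform genome-wide |
| `ip_background_mult` | 0.5 | IP signal outside marked regions is depleted |
| `state_proportions` | 45/5/16/34% (K4/K27/bivalent/neither) | a realistic promoter census with a 15–17%-scale bivalent fraction |
| `transition_matrix` | bivalent row (0.68, 0.05, 0.22, 0.05) | differentiation resolves most bivalency toward the active state |
| `expression_means` | 8, 4.8, 5, 4.5 (sd 1) | active promoters ~3 sd above poised/repressed ones |

The genome scale deserves a note. Depth scaling multiplies every
enrichment ratio by $N_{H3}/N_{IP}$. An IP library concentrates its reads
in marked regions, so if promoters make up a large share of the simulated
genome, $N_{IP}$ inflates relative to $N_{H3}$ and *every* promoter's
enrichment deflates — on a toy genome where promoters are a third of all
sequence, a true 12× emission rate lands near log2 ≈ 1.6, below any
sensible "high" cut. On real mammalian data promoters are a tiny fraction
of the library and the factor is close to 1. Simulating at the real gene
density (400 genes / 40 Mb) reproduces that regime: the 12×/0.5× rates
yield log2 ratios of about +3.5/−1, which is the geometry the classifier
is meant to face.

Window counts are Poisson by default, matching the domain caller's test
statistic; a negative-binomial `overdispersion` parameter exists to
stress-test robustness. TSSs are packed with ≥ 8 kb spacing so promoter
windows never overlap (overlapping-window behaviour is covered by
dedicated small fixtures in the counting tests instead). Everything is
deterministic given `seed`.

What the generator does *not* emulate — and hence what passing tests do
not demonstrate about real data: mappability and GC structure, fragment-
length effects, replicate batch effects, copy-number variation,
carrier-chromatin artefacts, and broad-domain shapes more complex than
uniform-rate windows. The generator validates the *arithmetic and
statistics* of the pipeline, not the biology of any particular dataset.

## Problem sizes and runtime

The shipped tests and the acceptance script use: one 400-gene / 40 Mb
two-timepoint experiment (~1 M tags across six libraries, ~2 s), 100-seed
domain-caller calibration on 1 Mb / 10^4-tag libraries, 20-seed
expression-significance and depth-monotonicity sweeps, and sub-second
closed-form checks. The full suite runs in well under a minute on one
core; these sizes were chosen so the binomial 3-SE bands in the tests are
tight enough to be meaningful while keeping iteration fast.

## Known limitations

* The domain caller approximates histone-style peak calling; coordinates
  will not match any specific external tool's output exactly.
* Enrichment has no GC/mappability correction and no spike-in
  normalization; comparisons across conditions assume libraries of
  comparable composition, which the H3 ratio only partly guarantees.
* Peak-overlap classification inherits the domain caller's resolution: a
  1 kb H3K4me3 tile can make a promoter "present" from a neighbouring
  gene's peak on very dense annotations.
* qPCR quantification assumes perfect primer efficiency and subtracts IgG
  per replicate; plates lacking matched controls are rejected rather than
  imputed.

## A minimal session

```{r, eval = FALSE}
library(bivalr)

ex <- simulate_experiment(synthetic_config(seed = 7))
q1 <- quantify_promoters(ex$tags$t1$k4, ex$tags$t1$k27, ex$tags$t1$h3,
                         ex$windows)
st1 <- state_table(q1, "t1")
st1

q2 <- quantify_promoters(ex$tags$t2$k4, ex$tags$t2$k27, ex$tags$t2$h3,
                         ex$windows)
tt <- transition_table(st1, state_table(q2, "t2"))
resolution_fraction(tt)          # bivalent -> K4-only, with raw counts
```
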