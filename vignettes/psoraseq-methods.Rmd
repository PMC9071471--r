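---
title: "Methods: supercoiling landscapes, twin-domains, and the additive transcription model"
author: "PsoraSeq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: supercoiling landscapes, twin-domains, and the additive transcription model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PsoraSeq)
```

# The measurement and its estimand

Psoralen binds duplex DNA at a rate proportional to helical tension, most
strongly where DNA is underwound. A biotin-psoralen pulldown library and an
unpurified input library from the same cells are sequenced; with fragment
counts binned at 1 kb, the estimand of the pipeline is the per-bin log2
ratio of normalized pulldown to normalized input coverage — a *relative*
supercoiling signal centered on the genome average. Two properties of the
design matter for everything downstream:

* the input cancels multiplicative per-bin effects shared by both libraries,
  in particular the replication copy-number gradient (origin-proximal DNA is
  more abundant in growing cells) and mappability/sequencing bias;
* absolute supercoiling density cannot be recovered; only differences
  relative to the genome average are meaningful. The package therefore never
  reports sigma, only log2 fold-changes and z-scores.

## Track construction choices

**Binning.** Fragments are assigned to the bin containing their circular
midpoint. The assignment rule is not dictated by the measurement itself; the
midpoint is robust to the ~500 bp sonication fragment size and treats
paired-end fragments naturally. Bin `i` covers `[i*1000, (i+1)*1000)` in
0-based bp; text output is 1-based.

**Repeat imputation.** Bins overlapping unmappable repeats (for *E. coli*
MG1655, the seven rRNA operons: 35 one-kb bins) receive the mean of the
nearest 3 unmasked kb on each side, 6 kb total, and are flagged imputed.
When a flank would run into a second masked interval the search continues
outward past it, with a warning.

**Mask semantics.** A single per-bin flag marks bins that are imputed or
invalid, but the two cases behave differently downstream: imputed bins carry
finite (locally interpolated) values and participate in smoothing, windows,
consensus averaging and twin-domain regression — exactly as the imputed rRNA
bins must, since ribosomal twin-domains straddle the operon body — whereas
invalid bins (zero coverage on either side of the ratio) are `NA` and are
skipped pairwise everywhere. Normalization statistics (the relative mean,
z-score mean and sd) use unmasked bins only, so imputation cannot tilt the
genome average.

**Zero-coverage bins.** No pseudocount is added. At 0.5–3 million reads per
sample (~100–650 reads per kb) zeros are rare, and a pseudocount would bias
exactly the low-coverage bins where the log ratio is least reliable; the bin
is masked instead.

**Z-scores** use the population standard deviation (divide by n), making
standardization idempotent and matching spreadsheet conventions.

**Smoothing** is a centered circular moving average; widths given in kb are
rounded to the nearest odd bin count so the window is symmetric.

# Twin-domain quantification

Windows of ±40 kb around each transcription unit midpoint are flipped so
transcription runs left to right, mean-centered over their full range (the
mean log2 value over the window is zero), and averaged position by position
into a consensus profile with per-position standard errors.

The regression on each side uses distances 1..k kb from the midpoint,
starting at k = 10 and extending 1 kb at a time; the retained window is the
one maximizing |r|. Two details are deliberate:

* **Global scan, not first local maximum.** "Extending until the correlation
  is maximal" is implemented as a full scan over k with the global maximum
  of |r| taken (ties go to the shortest window); the scan is cheap and a
  greedy variant (`rule = "greedy"`) is provided for comparison. A unit test
  proves the scan equals an independent brute-force oracle on random
  profiles.
* **|r|, not signed r.** Upstream and downstream limbs have opposite slopes;
  using the magnitude treats both sides identically.

Amplitude is the y-intercept (log2 fold-change extrapolated to the operon
midpoint, signed: positive upstream, negative downstream) and magnitude the
x-intercept `-intercept/slope`, measured from the *midpoint* because the
consensus is anchored there. The 95% ranges are the x- and y-intercepts of
the pointwise 95% confidence band of the fitted mean line, the construction
a spreadsheet LINEST-style workflow yields. On an exactly linear profile the
residual variance is zero and the band collapses onto the point estimates;
this degenerate case is handled explicitly and tested to 1e-6.

A fit whose slope and intercept share a sign does not decay toward baseline;
it is flagged "no domain detected" and its magnitude is `NA` rather than a
negative number.

The regression begins at 1 kb from the midpoint, not 0: the midpoint bin
sits on the sign crossing between the two limbs and belongs to neither.
Consensus windows are averaged with equal weight across all operons and
replicates; a per-experiment pre-averaging option was considered and
rejected as the default because equal weighting uses the per-position
standard error transparently.

**Per-TU amplitudes** (genome-wide screening) are the enrichment 5 kb
upstream of the 5' boundary minus the enrichment 5 kb downstream of the 3'
boundary, in transcription orientation. The sign convention makes canonical
twin-domains positive; inverting a unit flips the sign, which is itself a
regression test.

# The additive transcription model

Each transcription unit contributes a signed triangle: +A at the midpoint
falling linearly to zero `negMagnitudeKb` upstream, −A falling to zero
`posMagnitudeKb` downstream, with

```
A = ampPerUnitExpression * expression / referenceExpression
```

Defaults are 0.38 (log2 fold-change at the mean ribosomal rate) and
23/25 kb, the consensus ribosomal values; the reference expression is the
mean of ribosomal-flagged units in the supplied annotation, and must be
given explicitly when no units are flagged — the amplitude scale is anchored
to ribosomal rates and silently guessing another anchor would rescale the
whole model. Between the two peaks the default shape is a linear ramp
crossing zero at the midpoint (continuous and integrable); a step variant is
provided, and the two differ only at the midpoint bin at 1-kb resolution.
Expression values above the reference are not capped: nothing in the model
prevents a hypothetical unit transcribed above the ribosomal rate from
exceeding ±0.38, and capping would silently distort exactly the most
informative units.

The genome model is the circular sum of all contributions — linear in the
TU list and exactly rotation-equivariant, both tested. For comparison with a
measured track, the model is affinely rescaled so its extrema match the
measurement's; extrema are extracted after 50-kb smoothing of both tracks
(the smoothing at which such comparisons are plotted), because raw extrema
are dominated by single-bin noise. Affine rescaling leaves all Pearson
correlations unchanged, which is also tested.

Model fitness is the genome-wide Pearson correlation per replicate,
summarized as mean ± sem, plus a sliding-window correlation (default 300-kb
circular centered window, evaluated every 1 kb) to localize where the model
succeeds; windows with fewer than 3 valid pairs are `NA`. A circle has no
edges, so no edge policy is needed.

# Replichore symmetry

The symmetry axis passes through a point displaced from oriC by the skew
angle (1 degree = genome length / 360 bp; positive = counterclockwise,
toward decreasing coordinate on the conventional map) and its antipode. The
left arm is read counterclockwise from the axis point, the right arm
clockwise, each to half the genome truncated by the smoothing half-window so
that only fully supported positions enter the Pearson correlation; masked
positions are excluded pairwise. The arms are compared out to the axis
antipode rather than to dif: the antipode is defined for every skew, whereas
dif is a property of the zero-skew axis only. The skew scan smooths once,
evaluates the correlation on a 1-degree grid (default ±90°), and breaks ties
toward the smallest absolute skew.

# Region statistics

Regions are circular intervals; a bin belongs to a region when its midpoint
falls inside, so regions tiling the genome partition the bins exactly (the
length-weighted grand mean then equals the genome mean, a tested invariant).
Replicate comparisons follow the two-step convention: F test for variance
equality, then a paired two-tailed t test across replicates with
df = n_replicates − 1. No multiple-testing correction is applied by default,
matching the reporting convention for small panels of planned comparisons; a
`correction` argument exposes `p.adjust` methods. Degenerate comparisons
(identical means across replicates) report p = 1 rather than erroring.

Enriched/depleted region calling — 100-kb smoothing, ±0.5 sd threshold,
20-kb minimum run length — is a package default, not a published recipe: the
thresholds behind published region counts are not stated anywhere we could
anchor to, so they are configurable and documented as ours. The association
test against an external binding track is one-sample against zero across
region means (df = n_regions − 1), consistent with the degrees of freedom
such analyses report; a two-sample variant between classes is provided.

# The synthetic-data generator

The generator is the package's test bed and defines its reference study
conditions: a 4,641,652 bp circular genome in 1-kb bins with oriC at
coordinate 0 and dif at the antipode; seven rrn-like 5.5-kb operons; six
pulldown/input replicate pairs of one million fragments; an ori:ter
copy-number ratio of 4 (exponential in circular distance from oriC —
adequate for testing that the ratio cancels copy number, with no multi-fork
cell-cycle model); per-bin counts Poisson; and multiplicative per-bin noise
of 0.05 on the log2 scale representing residual technical variation
(crosslinking efficiency, local pulldown bias) beyond counting noise. Noise
is placed on the log2 scale because that is the pipeline's estimand — the
enrichment estimates `s + eps` directly — and it keeps counts non-negative.

Where the conditions were open, the choices are: expressions log-normal with
meanlog 0 and sdlog 2 (bacterial transcription rates span several orders of
magnitude) with ribosomal units pinned at `exp(meanlog + 2*sdlog)` — about
fifty-fold the median unit, so rrn-like units sit at the top of the
distribution and, because they are pinned exactly at the reference
expression, the generative twin-domain amplitude equals
`ampPerUnitExpression` exactly, making recovery tests sharp. Non-ribosomal
lengths are 1 kb plus an exponential tail truncated at 6 kb, which lets
2,598 units fit on the 4.64-Mb circle with a mean inter-unit gap under 1 kb,
as in a gene-dense bacterial genome. Ribosomal units are placed at least
100 kb apart (they are dispersed on real chromosomes), so consensus windows
do not overlap neighbouring ribosomal domains; on genomes too small for
100 kb the spacing shrinks to half the circle divided by the unit count.

The generator also produces two variants: a mirror-symmetric smooth
landscape about a skewed axis (doubly 50-kb-smoothed white noise, scaled to
sd 0.3 log2 units, copied from one arm to the other) for symmetry-recovery
tests, and a transcription-shutoff variant scaling all amplitudes by a
stated factor for drug-treatment-style comparisons.

What the generator does **not** emulate: sequence-dependent psoralen
affinity, GC or mappability bias (the diagnostic for GC correlation is
provided, but no correction — none was needed for *E. coli*), topological
barriers and supercoil diffusion dynamics, RNAP occupancy excluding psoralen
from operon bodies, and read-level artifacts (duplicates, multi-mapping).
Passing the recovery tests therefore demonstrates that the estimators are
correct and well-calibrated under the stated noise model — not that real
libraries are free of the biases above.

# Problem sizes and determinism

The test suite and acceptance script run at the full 4,642-bin genome scale.
Parameter-recovery and skew-recovery properties use 100 simulated studies
each; pipeline-consistency uses 20 seeds by 5 depths from 0.1 to 10 million
reads. Every stochastic call is a pure function of an explicit integer seed;
datasets regenerate bit-identically, and the pipeline writes a manifest
(resolved parameters, input checksums, seed, package version) so a run can
be reproduced from its outputs.

# Known limitations

* Relative signal only; amplitudes are log2 fold-changes against the genome
  average, not supercoiling densities.
* The twin-domain model is phenomenological and additive; it ignores
  topoisomerase kinetics, barrier stochasticity, and interactions between
  overlapping domains.
* Magnitudes are midpoint-anchored; for long operons the distance from the
  gene edge is correspondingly shorter.
* The expanding-window regression assumes an approximately linear decay; a
  strongly convex decay would bias the x-intercept.
* The shipped MG1655 macrodomain and rRNA coordinates are approximate
  external annotation, intended as defaults to be overridden.
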