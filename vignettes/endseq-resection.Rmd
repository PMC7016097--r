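---
title: "Measuring meiotic DSB resection and SPO11-bound ends with endseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring meiotic DSB resection and SPO11-bound ends with endseqr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endseqr)
```

## The measurement model

END-seq reads begin at the ssDNA–dsDNA junction of a blunted DSB end, so
the 5′ endpoint of each read is the observation. Around a SPO11 hotspot
center the strand-separated endpoint profile decomposes into a central
peak (protein-bound SPO11 ends sequenced from the cut itself), a
read-less gap (no cell in the population resects less than the minimum
extent), and distal long-range resection endpoints with correct polarity
(right end of a DSB → top-strand read, left end → bottom-strand read).
`endseqr` treats everything as 0-based, half-open coordinates internally
(BED-native); conversions happen only at file boundaries. Duplicate reads
are kept throughout — peak calling, profiles and estimators all operate on
raw endpoint multiplicities — because bona fide END-seq endpoints from
independent cells legitimately coincide at hot positions.

## The generative model behind the simulator

`simulate_library()` emits endpoints from an explicit DSB-processing
model. Each hotspot draws a Poisson number of break events
(`events_per_hotspot`, optionally scaled by an exponential "heat");
each event is one of four species:

* **fully resected** (`p_resected`): top endpoint at `cut + R_right`,
  bottom at `cut - R_left`;
* **SPO11-RI** (`p_ri`): one end blocked by motif-bound PRDM9 between the
  cut and the MRE11 nick site, so SPO11 stays covalently attached and the
  read starts at the cut itself, with reversed polarity (a cut left of
  center yields a top-strand central read); the other end is fully
  resected;
* **unresected SPO11cc** (`p_cc`): both ends protein-bound at the cut
  (top at `cut + 1`, bottom at `cut - 1`);
* **double-cut** (`p_doublecut`): two cuts `c1 < c2` spaced uniformly on
  `dc_spacing`, bottom-strand end at `c1`, top-strand at `c2`, both
  protein-bound.

Single-cut positions are displaced from the hotspot center by
`cut_disp` (default 30 bp, jittered with sd `cut_disp_sd`, random sign),
which is what makes the aggregated SPO11-RI strand shift ≈ −2×30 = −60 nt.
Double-cut pairs are centered on the hotspot center rather than displaced:
the two cuts straddle the PRDM9 motif inside the nucleosome-depleted
region, and centering keeps the +`spacing` strand-gap signature
identifiable instead of smearing it into a bimodal mixture.

Per-side resection endpoint distances are `R = gap + L`: `gap` is normal
(`gap_mean = 600`, `gap_sd = 30` bp per side in the WT preset — the
population minimum-resection gap is empirically very uniform, and only its
total width is observable, so the per-side split is a model parameter) and
`L` is a gamma-distributed long-range extension (positive, right-skewed,
matching the 1–3 kb endpoint spread; the family is pluggable, with
lognormal as an alternative). Spike-in cells (fraction `spike_fraction`,
default 2%) each carry exactly one blunt break at a fixed locus on a
separate chromosome; background endpoints fall uniformly on both strands
at `background_rate` per bp (default 1e-5).

**WT calibration.** The WT preset fixes `E[R] = 600 + 529 = 1129` nt and
sets the gamma sd to 247 so that the expected per-hotspot maximum of 50
draws is 1845 nt; both values were computed from the distribution alone
(Monte Carlo over draws of `R`, before any estimator ran) and frozen.
The reference depth of 50 resected ends per side is the package's
standard simulation scale (2000 hotspots × ~55 events for genome-wide
statistics; smaller for unit tests).

**Category probabilities are per break event, and each break emits two
ends.** An SPO11-RI break therefore contributes one central end out of
two, so the RI share of total *signal* is `p_ri / 2`, while an SPO11cc
break is central on both ends and its signal share equals `p_cc`. The WT
preset uses `p_ri = 0.20`, `p_cc = 0.01`: 10% RI + 1% SPO11cc = 11%
central signal fraction, which is the observable the central-peak
estimator recovers.

**Enzyme conditions.** `apply_enzyme_condition()` filters endpoints by
species: ExoVII+ExoT detects everything (per-species efficiencies default
1); ExoT alone only protein-free ends; TDP2+ExoT additionally recovers
SPO11cc (TDP2 hydrolyses the phosphotyrosyl bond of the two-nucleotide
overhang) but not SPO11-RI, whose heteroduplex-capped structure resists
TDP2; MRN+CtIP pretreatment removes SPO11-bound ends with probability
0.9 before ExoVII+ExoT detection.

## Estimators and their numerical choices

All three resection estimators work per hotspot and side on binned
profile rows; the top strand measures the right side, the bottom strand
the left.

**Mean resection** is `E(x) = Σ_{i=21}^{400} x_i p_i` on 10-bp bins over
±4 kb, with `x_i` the bin midpoint distance (`10i − 5`; the paperless
choice between midpoint and edge is at most 5 bp) and `p_i` the
normalized signal share, so the estimate is scale-invariant (raw counts
and RPM give identical values). Bins 1–20 (distances < 210 bp) never
contribute; an all-zero side is `NA`, never 0.

**Minimum resection** slides a `window_bins = 5` (50 bp) window from the
long-range peak (leftmost argmax of the lightly smoothed side profile
beyond 300 bp) toward the center and applies a one-sided one-sample
t-test against μ, the mean of the bins within ±500 bp of the peak (a
reference sample, not a search range). The first window with `p ≤ 0.05`
defines the boundary (its midpoint distance). A constant window below μ
is treated as `p = 0` (an all-zero window inside the gap is the strongest
possible evidence, but has no t statistic); a window equal to μ as
`p = 1`. Window width 5 is the smallest size at which the t-test is
well-defined with a few degrees of freedom while keeping boundary
quantization at ±25 bp.

**Maximum resection** uses 20-bp bins over ±6 kb and a per-hotspot
dynamic background: the maximum bin intensity at 5–6 kb on the same side.
Scanning outward from the long-range peak, it stops at the first 5-bin
window in which more than half the bins have *strictly lower* intensity
than background, and reports the last preceding bin strictly above
background. The strict comparisons matter for sparse profiles: with a
zero background, empty bins (equal to background) do not trigger the
stop, so the scan reaches the true last endpoint, which is what makes the
estimator equal the empirical per-hotspot maximum on clean simulations.
With background endpoints present, a stray read beyond the true tail can
be counted when the 5–6 kb strip happens to be empty, which biases the
genome-wide mean of maxima upward by a few percent at the default
background rate — visible in the worked examples (≈1890 vs the calibrated
1845) and well inside the 10% recovery band.

Both sliding-window estimators are verified against exhaustive
brute-force window enumeration (exact equality over thousands of random
profiles) — the window scan is an optimization, not an approximation.

**Genotype comparison** (`compare_resection`) is a one-sample t-test on
paired per-hotspot differences against a null offset (default 10 bp, an
allowance for replicate-level technical variation), with the median
difference as effect size.

## Central-peak quantification

`central_fraction()` height-matches the ExoT-only aggregate to the
ExoVII+ExoT aggregate on the distal flanks and integrates the
zero-clipped difference. Choices made where the procedure was open:

* the flank statistic is the *maximum* over |offset| ∈ [800, 3000] bp
  (area matching is available as an option);
* per-offset negative differences are clipped at zero before integration,
  so flank sampling noise cannot create negative central mass; if the
  unclipped negative mass exceeds 10% of the total area the function
  warns of a flank-shape mismatch;
* the central window is ±200 bp (the central peak is ~400 bp wide) and is
  reported as a diagnostic of where the difference lies, not used to
  restrict the integral.

`decompose_central()` propagates two detection assumptions into bounds:
if ExoT detects SPO11cc and SPO11-RI overhangs equally, the TDP2+ExoT
fraction is all SPO11cc (`cc_high`); if ExoT captures every SPO11cc, the
implied SPO11cc break count over a reference total gives `cc_low`. The
reference total is an explicit argument (default 333) because the
published arithmetic implies a reference sample (≈ 2 breaks / 0.6%) that
is not named; the bounds satisfy
`ri_low + cc_high = ri_high + cc_low = f_full` exactly.

`polarity_shift()` locates each strand's central endpoint distribution by
the argmax of a Gaussian-smoothed (sd 5 bp) 1-bp histogram with leftmost
tie-breaking; a weighted median is offered for robustness. Negative
shifts (top left of bottom) are the SPO11-RI signature; positive shifts
the SPO11cc/double-cut signature.

## Peak calling, normalization and QC

The hotspot caller is deliberately a simple fold-enrichment scanner, not
a reimplementation of a full peak caller: pooled-strand counts in 2-kb
sliding windows (50% overlap; the window matches the ~2 kb separation of
the two resection flanks that motivates a ±1 kb strand shift in
shift-based callers) are compared with the uniform expectation
`library_size × window / genome_length`, windows above 2.5× expectation
are merged, and the summit is the leftmost argmax of the 50-bp
running-mean-smoothed signal. It has no local-lambda model and no
q-values; it is a deterministic, testable stand-in whose recovery on
simulated truth is what the test suite checks.

Spike-in normalization divides the total hotspot-window signal (±5 kb
around centers, windows unioned so overlapping hotspots are not double
counted) by the spike-locus signal and by the mixing divisor (50 for a
2% spike-in), yielding breaks per bulk cell-equivalent; being a ratio of
signals from the same library it is depth- and scale-invariant.

QC follows the ChIP-seq FRiP / strand cross-correlation conventions with
one END-seq-specific reversal: bottom-strand endpoints lie *left* of
top-strand ones, so the fragment-length correlation peak `CCfrag` is
located at *negative* shifts, and its position tracks the distance
between the two long-range resection flanks (~−2 kb in wild-type-like
simulations). `NSC = CCfrag/CCmin` requires a positive correlation
baseline; real libraries get one from shared mappability and nonspecific
coverage, which the simulator does not model (its uniform background is
independent between strands), so on synthetic data `CCmin` can be ≤ 0 and
NSC is reported `NA` with a failing flag rather than a misleading ratio.
RSC and the fragment shift are the informative synthetic-data metrics.
Thresholds default to FRiP > 1%, NSC ≥ 1.05, RSC ≥ 0.8; the NSC cutoff is
also quoted as 1.5 in some guidelines, and both are exposed in
`run_config()`.

## What the simulations do and do not show

The generator reproduces the features the estimators rely on — species
mixtures, strand conventions, the read-less gap, spike-in ratios — under
idealized conditions: no mappability structure, no PCR duplicates, no
sequence-composition bias, point endpoints with no read-length effects,
and a uniform background that is independent between strands. Passing
recovery tests therefore validates the estimators' logic and numerics,
not their robustness to alignment artifacts; on real data the blacklist,
the dynamic background and the QC module carry that weight. Problem sizes
in the test suite (150–2000 hotspots, 25–55 events per hotspot) are the
package's standard simulation scale, chosen so each estimator sees at
least ~50 observations per measured quantity.

```{r example}
sim <- simulate_library(preset("WT", n_hotspots = 300,
                               events_per_hotspot = 55,
                               heat = "constant", seed = 1))
pm <- bin_endpoints(sim$track, sim$hotspots, W = 4000, bin = 10)
rt <- resection_table(pm)
median(rt$mean_resection, na.rm = TRUE)
polarity_shift(sim$track, sim$hotspots)$shift
```

## Known limitations

* The caller is not MACS-equivalent; fold enrichments are comparable
  within a library, not across callers.
* The SPO11-RI model always blocks the motif-proximal end completely; no
  partial-block mode is offered.
* Secondary SPO11 cut positions are represented only through the cut
  displacement distribution, not as a separate species.
* `cross_correlation()` evaluates Pearson correlations on a 10-bp grid
  genome-wide; on very large genomes this is memory-bound and a coarser
  bin or restricted shift range should be used.
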