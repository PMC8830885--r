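---
title: "Methods: single-molecule m6A footprinting of heterochromatin recruitment and spread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-molecule m6A footprinting of heterochromatin recruitment and spread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirspread)
```

# The assay and the analysis problem

Fusing a nonsite-specific adenine methyltransferase (M.EcoGII) to a
chromatin protein turns every visit of that protein into a permanent mark:
accessible adenines near its binding sites acquire m6A, a modification
absent from native budding-yeast DNA. Long-read sequencing with a
modified-base caller then reports, for every adenine on every molecule, a
probability that it is methylated. In budding-yeast heterochromatin this
separates two processes that bulk assays conflate: *recruitment* —
sequence-specific nucleation of the silencing (SIR) complex at silencers,
telomeric TG repeats and X elements — and *spread*, the sequence-nonspecific
extension of the complex along nucleosomes away from those sites.

`sirspread` implements the full analysis path from per-read modified-base
calls to biological readouts: binarization, aggregation, coverage
filtering, coverage-weighted smoothing, single-read matrices, background
estimation, spread-boundary calling, response classification, differential
methylation, nucleosome-linker periodicity, spread decay-length fitting and
establishment-onset mapping. Because deposited sequencing data are outside
the package's scope, it also ships a generative occupancy model that
simulates per-read call sets with the statistical structure the analysis
assumes, so every stage is testable end to end against known truth.

# The occupancy model

Occupancy of the silencing protein at position $x$ is

$$\mathrm{occ}(x) = \mathrm{clamp}\Big(b + \sum_{s}
  p_s\, e^{-d(x,s)/\lambda} \prod_{\text{boundaries } k \text{ crossed}}
  a,\; 0, 1\Big)$$

where $b$ is background occupancy, $p_s$ the peak occupancy of recruitment
site $s$, $d(x,s)$ the distance from $x$ to the nearest edge of the site
interval (0 inside it, so methylation is flat-topped over silencers),
$\lambda$ the spread decay length in bp, and $a \in [0,1]$ a boundary
attenuation applied once per boundary element crossed on the path from the
site to $x$. Attenuation 1 makes boundaries inert; attenuation 0
annihilates spread past the element.

A molecule's chance of being methylated at an adenine is
$\mathrm{occ} \times \mathrm{acc} \times r$: accessibility
$\mathrm{acc}(x)$ is `core_accessibility` within ±73 bp of a nucleosome
dyad (the 147 bp core) and `linker_accessibility` elsewhere, reproducing
the ~165 bp periodic banding seen on single reads; $r$ is a per-visit
methylation efficiency. The factorization into independent Bernoulli draws
per adenine per read is a modeling choice — the enzyme's true processivity
and the protein's dwell-time structure are unknown — and is the main
respect in which simulated reads are *simpler* than real ones: real
single-read methylation is "spotty" with correlations along a molecule
that this model does not produce. Passing tests therefore validate the
pipeline's arithmetic and inference logic under honest noise, not the
biological realism of single-read correlation structure.

For establishment time courses each site term is scaled by the saturation
factor $t/(t+h)$ with a fast recruitment halftime (default 10 min) for the
in-interval component and a slow spread halftime (default 120 min) for the
decayed component, so recruitment sites saturate first — the ordering the
time-course analysis is designed to detect.

## Base-caller emission

The caller's per-call probabilities are modeled by their threshold
behaviour only: a truly methylated adenine lands above the binarization
threshold with probability `tpr` (default 0.9), an unmethylated one with
probability `fpr` (default 0.01); within each side of the threshold values
are drawn from truncated Beta laws (right-skewed for methylated,
left-skewed for unmethylated) so emitted probabilities are smooth,
realistic, and have *exactly* the configured threshold rates. Low-confidence
calls on truly methylated adenines are thereby "missed", mirroring the
conservative binarization of the real caller.

## Defaults and units

| parameter | default | unit | why |
|---|---|---|---|
| binarization threshold | 0.8 (strict >) | probability | the assay's published operating point |
| min coverage | 10 | emitted calls/position | the assay's aggregate-track filter |
| `enp_target` | 100 | effective parameters | the assay's smoothing flexibility per plotted window |
| adenine density | 0.3 / strand | — | AT-rich yeast genome (~62% AT) |
| read length | 15 kb (CV 0.25) | bp | gDNA sheared to 15–20 kb |
| `lambda` | 800 | bp | places "lower but significant" interior methylation between silencers 2–3 kb apart |
| peak occupancy | 0.9 (silencer/X/TG), 0.6 (promoter) | — | strong flat-topped anchors; weaker Rap1-site promoters |
| `rate` r | 0.8 | per visit | silencer methylation in the tens of percent |
| accessibility | 1 linker / 0.2 core | — | ~5× linker preference |
| background occupancy | 0.02 | — | control-sample background ~1–2% methylation |
| background k | 2 | SD | mean + 2 SD of the control |
| run length W | 300 | bp | ~2 nucleosomes; rejects core-occlusion dips |
| halftimes | 10 / 120 | min | recruitment saturates before spread |

Read placement allows truncation by either contig end, as random shearing
of a linear chromosome produces shorter terminal fragments rather than a
coverage hole: coverage is therefore uniform out to the very ends, and
telomere-proximal windows are analyzable at desk scale.
`target_coverage` is the expected read depth per position *per strand*;
both strands carry adenines independently at the same density and are
simulated as distinct sites, because m6A can occur on the A of either
strand and strand handling upstream is unspecified. Aggregation keeps
strands separate by default with a `merge_strands` pooling option; the
boundary/periodicity analyses in this package pool strands to double the
per-position coverage.

# Numerical and procedural choices

**Smoothing.** `smooth_track()` wraps `stats::loess` with `degree = 1`,
tricube kernel, observation weights equal to coverage, and the span
calibrated by `enp.target` — pinning the smoother's effective number of
parameters (default 100) rather than a bandwidth, so windows with different
adenine counts get comparable flexibility. With `surface = "direct"` the
fit at each position is exactly a per-point weighted local-linear
least-squares fit (the test suite verifies agreement to < 1e-8 against an
independent implementation); the default interpolating surface is used for
long tracks. Weights are scale-invariant: doubling every coverage changes
nothing. Smoothing is applied per analysis window, never to a whole contig,
because one enp budget describes one window's span.

**Background.** `estimate_background()` returns mean + k·SD (default k = 2)
of the *smoothed* control values. On a raw track the per-position binomial
noise (SD ≈ 1% at 100× for a 1% rate) would inflate the threshold several
fold beyond the level the control actually supports; the smoothed track
measures the spatial variation of the background level itself.

**Boundary calling.** The spread boundary is the first position, scanning
from the anchor edge, where the smoothed signal stays at or below
background for ≥ W = 300 bp. A run-length rather than derivative criterion
is robust to smoothing ripple and to the periodic core dips, whose width
(≤ 147 bp) is below W. A signal that never rises above background is
`at_anchor` (extent 0); one that never returns is `unbounded` at the window
edge. Raising the background level can only shorten the called extent.

**Response classification.** Comparing two conditions at one anchor,
`boundary_shift` is the change in spread extent and `level_ratio` the mean
smoothed-signal ratio over the shared above-background domain. The
categories (`extended` if shift > 500 bp and ratio > 1.25;
`increased_only` if only the ratio criterion holds; else `unchanged`)
formalize the three telomere response classes seen under overexpression.
The thresholds are declared configuration calibrated on the simulator —
the original classes were adjudicated visually, so no printed values exist
to inherit.

**Differential positions.** An exact (Fisher) two-proportion test per
shared position with BH correction; exact rather than normal-approximate
because coverage sits near the 10× floor.

**Periodicity.** The percent track is detrended against its smoothed trend
(auto-detrending uses ~800 bp resolution so the trend cannot absorb the
165 bp oscillation), expanded to a 1 bp grid by nearest neighbour (adenine
spacing is irregular), and autocorrelated to 400 bp. The repeat length is
the lag of the first *positive* local maximum at lags ≥ 30 bp — the lower
cut skips the few-bp shoulder that nearest-neighbour gridding induces, and
requiring a positive peak excludes ripples inside the anticorrelation
trough. The autocorrelation is lightly smoothed (11-lag running mean)
before peak finding. Significance is a ≥ 95th-percentile exceedance over a
permutation null that shuffles detrended values across positions.

**Spread fit.** `fit_spread_model()` least-squares fits
$\mathrm{bg} + A e^{-d/\lambda}$ over the directional window with
L-BFGS-B, $\lambda \in [10, 10^5]$ bp; amplitudes below 0.5% are reported
censored rather than returning a meaningless decay length.

**Onset.** A position's onset is the earliest sampled time from which it
exceeds background for ≥ 2 consecutive sampled times; never-exceeding
positions are censored, not forced. Raw (unsmoothed) tracks are the
default input so onsets are not advanced by spatial bleed from strong
neighbours.

**Determinism.** One top-level seed; every substream (adenine masks, read
placement per contig, each time point, bootstraps, permutations) derives
its seed by hashing (seed, purpose label), so adding one stage never
perturbs another's draws. Re-running a pipeline config reproduces every
output byte-identically.

# Study conditions used by the validation experiments

The test suite and the acceptance script run the pipeline on fixed
simulated experiments, at desk scale (16–30 kb contigs, 30–50× per-strand
coverage, 8 kb reads, 100 seeded replicates for rate claims):

* **Boundary recovery and overexpression.** These experiments use a
  strong-spreading configuration (λ = 4000 bp) so that the boundary
  element placed 5 kb from the anchor — and not the decay length — is what
  limits the spread, as at real telomeres where methylation reaches the
  X-element boundary. With the locus-scale default λ = 800 bp the signal
  would decay below background ~2.3 kb out and no method could localize a
  boundary at 5 kb. The overexpression contrast doubles peak occupancy
  from a half-saturated baseline (0.45 → 0.9); doubling an already
  near-saturated peak would clamp at 1 and produce no measurable level
  change.
* **Recruitment-without-spread contrast.** Wild-type (λ = 800) versus a
  spreading-deficient configuration (λ → 0, recruitment peaks intact), on
  a 30 kb contig whose anchors sit ≥ 3 kb from contig ends — read-end
  coverage decay would otherwise starve the anchor intervals below the 10×
  floor — and ≥ 10 kb apart so neighbouring spread tails do not fill the
  inter-anchor gaps. The contrast annotation carries no promoter so
  anchor-interval methylation is recruitment-only on both sides of the
  comparison.
* **Establishment ordering.** Two silencers 10 kb apart; "interior"
  positions 1.5–2.5 kb from the nearest silencer edge are genuinely
  spread-limited (early time points below background, later ones above or
  censored), so the recruitment-before-spread ordering is read from the
  onset medians.
* **Decay-length recovery.** A single isolated site, fitted to 6 kb; the
  nucleosome-repeat ripple is averaged out by the smoother and absorbed in
  the fit residual.

# Known limitations

* No along-read correlation structure (see above); no replication or
  cell-cycle dynamics — time scaling is a deterministic saturation curve.
* No sequence-level simulation: the simulator emits call tables, not
  FASTQ or signal; the base caller itself is out of scope.
* The per-read text dialect is pinned to one column set; modBAM (MM/ML)
  input is not supported.
* Format adapters for real deposited data are untested against real
  downloads; coordinates are 0-based half-open throughout.
* `classify_response` thresholds and the boundary run-length are
  operational definitions declared here, not quantities inherited from a
  printed source; conclusions that depend on them should report them.
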