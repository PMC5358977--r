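---
title: "Mapping mouse vocal repertoires: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping mouse vocal repertoires: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usvmap)
```

## The analysis in one paragraph

Mouse pups separated from the dam emit ultrasonic isolation calls, short
(5–150 ms) frequency-modulated syllables mostly between 40 and 110 kHz. A
syllable is represented here by its *frequency contour* — the uniformly
sampled trajectory of its dominant frequency. To compare the vocal output
of two genotype groups without committing to a syllable taxonomy, `usvmap`
builds a *repertoire map*: every pair of (mean-subtracted) contours is
compared by dynamic time warping, the resulting all-to-all dissimilarity
matrix is embedded into two dimensions with t-SNE, and group differences
are assessed on that map — as bootstrap significance maps of the per-group
densities, and as a genotype-blind step/non-step classification of map
regions feeding a 2×2 chi-squared test.

## Stage by stage

### Contours and acoustic measures

A contour is a sequence of `n >= 2` positive frequencies (kHz) at a fixed
hop (default 1 ms; the hop is a configurable convention, not a claim about
any particular extraction tool). Duration is `(n - 1) * hop` (fence-post
convention), bandwidth is `max(f) - min(f)` of the contour, and mean
frequency is the unweighted mean of its samples — contours carry no
amplitude, so no amplitude weighting is possible. Syllables whose
recording clipped are carried through I/O but excluded from every
analysis. Group comparisons of the simple measures use one-way ANOVA on
*per-individual means*, the individual being the unit of analysis; with 5
and 6 individuals this gives the familiar `df = (1, 9)` design.

A *step* (jump) syllable contains an abrupt frequency discontinuity. The
detector flags any adjacent-sample `|Δf| >= 10` kHz (configurable, `>=`
at the boundary). Ten kHz cleanly separates continuous sweep slopes
(about 1 kHz per 1-ms hop in this corpus) from genuine jumps, which sit
at 12 kHz and above in the synthetic templates.

### DTW dissimilarity

Contours are mean-frequency subtracted, then compared with the classic
dynamic-time-warping dynamic program: local cost `(f_a[i] - f_b[j])^2`,
symmetric unit steps (match/insert/delete), boundary-to-boundary paths, no
warping window. The reported value is a *mean* squared error: the minimum
over warping paths of path cost divided by path length. Because a direct
DP minimises the sum rather than the ratio, the ratio is minimised exactly
by Dinkelbach iteration — re-solving the DP on `cost - λ` at the ratio of
the current argmin path until the optimum reaches zero; the path set is
finite, so this terminates, in practice after two or three passes. The
test suite checks exact agreement with a brute-force enumeration of every
warping path on short contours. Normalising by optimal-path length (rather
than `max(n, m)`) keeps scores comparable across length pairs; contours
are *not* length-normalised first, since duration differences are
legitimately absorbed by warping and duration is analysed separately.

### t-SNE embedding

t-SNE runs directly on the precomputed dissimilarities. The neighbourhood
size is parameterised as the *transition entropy* `H` in bits — the
Shannon entropy of each point's transition distribution — with per-point
kernel bandwidths tuned by binary search; this is equivalent to perplexity
`2^H`, so the default `H = 5` is perplexity 32. Dissimilarities enter the
Gaussian affinity kernel linearly (they are already squared-error
quantities, in kHz²). Gradient descent uses the reference implementation's
early exaggeration (12× for the first quarter of iterations), momentum
switch and adaptive gains, and stops when the relative change of the KL
cost between checks (every 10 iterations) falls below `1e-4`.
Initialisation is classical MDS of the dissimilarities scaled to small
norm — deterministic, so a map is reproducible from (matrix, seed) alone —
with a seeded random fallback for degenerate inputs. Map axes are
arbitrary; every downstream statistic is invariant to rigid
rotation/reflection, which the tests verify (for the discrete entropy,
after the `log2(cell_area)` correction discussed below).

### Density, entropy and the bootstrap significance map

Group densities are sums of isotropic Gaussian kernels (`sigma` in map
units, default 4) evaluated on a regular grid (default 100×100 covering
the points plus a 3σ margin) and renormalised so `sum(rho) * cell_area =
1`. The kernel width should be read relative to the map extent: t-SNE
maps of a few hundred points are materially smaller than maps of many
thousands, and desk-scale analyses in the test suite use `sigma = 2`
where region resolution matters.

The pooled density is the average of the two group densities. Its entropy
is computed as the discrete cell-probability entropy
`H = -Σ p_i log2 p_i`, `p_i = rho_i * cell_area` — the grid quadrature of
the differential-entropy integral up to an additive `log2(cell_area)`;
the convention is fixed by recording the grid with every density object.

Uncertainty in each group's density due to the finite number of
vocalizations is estimated by resampling the embedded points with
replacement (`n_boot` times; 10,000 at study scale, smaller for desk
runs) and recomputing the density grid per replicate. At every cell,
univariate Gaussian mixtures with 1–3 components are fitted to the
bootstrap values and the component count chosen by AIC. AIC is
*minimised* — the standard direction for an information criterion that
penalises parameters. EM uses deterministic quantile initialisation (so
fits are reproducible), runs at most 15 iterations per fit, and
represents degenerate cells (zero variance) as point masses. Cells whose
bootstrap values never exceed `1e-9` of the group's peak density are
below the numerical support floor and are stored as point masses with a
`tiny` flag; where *both* groups are below floor the comparison returns
0.5 — densities indistinguishable from zero carry no directional
evidence.

The per-cell comparison `P_HT(x, y) = Prob(rho_HT > rho_WT)` assumes the
two groups are sampled independently and integrates the two fitted
mixtures — trapezoidal rule on a 2048-point grid spanning both mixtures'
`1e-6 … 1-1e-6` quantile envelopes, with point masses handled
analytically. Cells with `P_HT > 1 - α'` or `P_HT < α'` are flagged. The
familywise correction is Šidák's, `α' = 1 - (1 - α)^(1/m)`, with the
effective number of comparisons `m = 2^H` taken from the entropy of the
pooled map density; `m` is used as a real number without rounding.
Closed-form checks (identical models → 0.5; unit-variance Gaussians
separated by δ → `Φ(δ/√2)`) and a null-calibration experiment (two groups
from one generator; flagged fraction ≲ α, typically zero cells) pin the
behaviour.

### Step regions and the contingency test

Study-scale analyses of this kind have delineated step and non-step
territory on the map by eye; `usvmap` substitutes an automatic surrogate:
watershed
segmentation of the (negated) pooled density from its local maxima, with
the cells jointly holding the lowest 1% of mass as background. Each
region is classified *step* iff more than half of its member contours
trigger the step detector — a majority vote using only map position and
contour shape, never group identity — and every vocalization inherits its
region's class (background vocalizations are attached to the nearest
region so counts always total n). Group-by-label counts form a 2×2 table
tested by Pearson's chi-squared. The Yates continuity correction is the
default: on the recorded counts (3257/4718 step in wild types versus
2073/4295 in heterozygotes) the corrected statistic reproduces the
reference value 400.42 while the uncorrected closed form gives 401.29, which
pins down the variant; the uncorrected statistic remains available by
flag.

### Synthetic repertoires

The generator exists so that every downstream stage is testable without
recordings. It emulates pup isolation-call repertoires: four non-step
template families (flat, linear up/down sweeps, parabolic chevrons — the
parameterisations are this package's choice, made to give the map a
multimodal structure) plus step syllables built from two segments with a
discontinuity drawn from 12–40 kHz, unambiguously above the 10 kHz
detection threshold. Defaults mirror the study design: 5 wild-type and 6
heterozygous individuals, 4718 and 4295 calls, and step probabilities
0.69 and 0.48. Base frequencies are drawn from 55–90 kHz with a
per-individual random shift (SD 3 kHz, truncated at 3 SD), per-sample
Gaussian jitter (SD 0.5 kHz, truncated at 4 SD), durations 15–130 ms, and
all contours stay inside a 35–115 kHz band; colony statistics beyond step
prevalence are not part of the reference design, so these are
literature-typical values and documented as such. Template slopes are
capped so that slope plus worst-case jitter stays strictly below the step
threshold, making the step/non-step ground truth exact by construction.
Each individual has its own RNG stream seeded from a hash of its
identifier, so enlarging a design never perturbs existing individuals.

What the generator does *not* emulate: amplitude structure, harmonics and
multi-component syllables, temporal call-sequence structure, colony- and
age-dependent repertoire drift, and recording noise. Passing tests
therefore demonstrate that the pipeline recovers the structure this
generator puts in — prevalence differences carried by distinct contour
shapes — not that it resolves every distinction present in real
recordings.

### Audio front-end

The optional extraction stage is a declared simplification of spectral
contour tracers: 0.5 ms windows with 50% overlap are tapered with DPSS
sequences (NW = 3, 5 tapers, computed by the tridiagonal eigenvector
method), zero-padded to four times the window length so tones falling
between natural FFT bins are not missed, and tested per bin with the
Thomson harmonic F-statistic (df 2, 2K−2) at `p < 0.01` without
multiplicity correction. Per time step the maximal-F significant point is
traced; gaps above `max_gap` split syllables, syllables shorter than
`min_duration` are dropped, and clipping within a syllable's span flags
it. One dominant contour per time step, no harmonic merging, no manual
correction. The companion synthesizer renders a contour as a
phase-continuous FM tone using a zero-order hold on the instantaneous
frequency — a hold rather than linear interpolation, so that contour
discontinuities remain abrupt in the signal; round-trip tests
(synthesize → extract) recover contours with median error well under 2
kHz and correct step status in ≥ 95% of syllables.

## Problem sizes and tolerances used by the test suite

Desk-scale runs keep the suite fast while preserving the statistical
structure: collections of 300–1000 contours at a 3 ms hop for map-level
experiments, 100×100 grids, 200–500 bootstrap replicates, 20 replicate
seeds for the calibration and effect-recovery experiments. A study-scale
map of 9013 vocalizations is not reproducible without original
recordings; the effect-recovery experiment (step probabilities 0.69
versus 0.48, 500 calls per group) is the property-based surrogate, and
the full-size design enters the tests only as a comparison-count check.

## Known limitations

- DTW is exact but O(nm) per pair and O(n²) pairs; collections beyond a
  few thousand contours call for subsampling (the package deliberately
  ships no approximate DTW).
- The discrete entropy and hence `m = 2^H` depend on the grid resolution;
  resolution is part of the recorded configuration, not a free knob.
- Watershed region classes depend on the density kernel width relative to
  map extent; the defaults suit study-scale maps, and smaller maps warrant
  proportionally smaller `sigma`.
- The extraction front-end assumes a single dominant tonal component per
  time step and is not bit-compatible with any specific external tracer.
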