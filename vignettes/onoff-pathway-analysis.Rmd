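---
title: "Methods: quantifying ON/OFF pathway stimulation and its choroidal correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying ON/OFF pathway stimulation and its choroidal correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onoffscan)
```

## Background

The retina splits visual input into parallel ON and OFF channels: ON
ganglion cells respond to luminance increments (a bright center on a darker
surround), OFF cells to decrements. Work in animal models indicates that
selectively stimulating one channel has selective effects on eye growth,
which makes the *relative* ON/OFF stimulus strength of everyday visual
environments — in particular printed text — a quantity of interest for
myopia research. Reading dark text on a bright page turns out to be a
strongly OFF-biased stimulus, its photometric inverse an ON-biased one, and
one hour of either is accompanied by measurable, oppositely signed changes
in subfoveal choroidal thickness, a short-term biomarker of eye-growth
signaling.

`onoffscan` implements the full computational side of such a study:

1. a multi-scale center-surround scan that assigns each image position an
   ON- or OFF-stimulating label and aggregates per-scale strengths
   (`analyze_frame()`),
2. deterministic stimulus generators — polarity-controlled text,
   luminance-matched pairs, checkerboards, 1/f-noise scene surrogates
   (`render_text()`, `match_mean_luminance()`, `checkerboard()`,
   `pink_noise()`),
3. the statistics pipeline for choroidal-thickness tables plus a synthetic
   cohort simulator for parameter-recovery testing
   (`change_from_baseline()`, `paired_t_test()`, `rm_anova()`,
   `regress_thinning_on_refraction()`, `simulate_cohort()`).

## The receptive-field model

A "receptive field" here is deliberately simple: at center pixel $(x, y)$
and scale $k$, the response is

$$ r_k(x, y) = I(x, y) - \frac{1}{8}\sum_{(dx, dy)} I(x + dx, y + dy), $$

where the eight surround samples sit at offsets
$\{(\pm k, 0), (0, \pm k), (\pm k, \pm k)\}$ — a Moore neighborhood scaled
by $k$. Positive responses are ON-stimulating, negative ones
OFF-stimulating, and an exact zero counts as neither (the classification is
defined only by sign). No difference-of-Gaussians weighting or response
normalization is applied; the filter is intentionally minimal, and the
package does not attempt to model more elaborate ganglion-cell models.

All interior pixels at least `margin = max(scales)` from the frame edge are
centers, one shared grid for all scales. A 640 x 480 frame with the default
scales 1–10 is therefore scanned at $(640-20)(480-20) = 285{,}200$
positions. Responses are computed in floating point (the surround mean is
generally a non-integer multiple of 1/8) and never rounded before
aggregation.

Scale maps to spatial frequency as $sf(k) = sf_1 / k$ cyc/deg: a
center-to-surround distance of $k$ pixels is half a cycle of the best-tuned
grating. The default $sf_1 = 22.4$ cyc/deg reproduces the figures for a
640 x 480 camera with a 16 mm lens (so $k = 2$ samples 11.2 cyc/deg and
$k = 10$ samples 2.24 cyc/deg); `calibration()` also accepts a
focal-length/pixel-pitch pair and computes $sf_1 = 1/(2\,\mathrm{deg\ per\ pixel})$.

## Why the default aggregator is an energy sum

How classified responses combine into ON and OFF strengths is the one
genuinely open design point, and it matters. Two seemingly natural choices
fail:

* **Linear magnitude sums** are provably uninformative for interior
  content. If every pixel that differs from a constant background is at
  least `margin + k` from the frame edge, each such pixel enters the grid
  sum once as a center (weight $+1$) and exactly eight times as a surround
  (weight $-1/8$), so the *signed* responses sum to exactly zero and ON and
  OFF magnitude sums are identical. This "zero signed-sum" identity is
  verified exactly in the test suite.
* **Position counts** invert the expected result for thin dark strokes: a
  dark line produces few strongly negative responses on the stroke and many
  weakly positive ones in the bright halo around it, so counting positions
  yields ON dominance.

The default is therefore an energy-weighted sum,
$\mathrm{ON} = \sum_{r > 0} r^{\gamma}$,
$\mathrm{OFF} = \sum_{r < 0} |r|^{\gamma}$ with $\gamma = 2$, which weights
the sparse large-magnitude stroke responses above the dense weak halo and
reproduces both hallmark behaviors: thin dark-on-light text is
OFF-dominant at every scale, and very thick letters are less
OFF-stimulating than thin ones. `aggregator()` also exposes `sum`, `count`
and `threshold` modes so the binary-classification variants remain
selectable.

The normalized summary is the polarity index
$(\mathrm{ON} - \mathrm{OFF}) / (\mathrm{ON} + \mathrm{OFF}) \in [-1, 1]$;
it is reported as `NA` (undefined), never 0, when both strengths vanish,
e.g. on a uniform frame.

Two exact invariances follow from the filter's structure and are enforced
as bit-level tests: photometric inversion ($255 - I$) swaps ON and OFF
exactly in every mode, and adding a constant to every pixel (within
$[0, 255]$, integer offsets on integer frames) leaves every response — and
hence the whole profile — unchanged, which is why mean-brightness
differences between stimuli cannot confound the asymmetry.

## Stimulus generators

**Text.** `render_text()` uses an embedded stroke font: each glyph is a set
of axis-aligned segments on a 3 x 5 design grid, scaled to the requested
glyph height and thickened to the requested stroke width. Embedding the
font makes output bit-reproducible across platforms; no system fonts are
touched. Original-typeface glyph shapes are not reproduced — only their
contrast structure (thin strokes on a uniform field), which is what the
analysis responds to. Anti-aliasing is off: strokes are binary, matching
the analyzer's assumption of luminance-proxy pixel values. The inter-glyph
gap grows with stroke width so very thick glyphs never merge. The renderer
reports the achieved ink fraction, and with levels $(0, 255)$ a polarity
flip is an exact photometric inversion.

**Luminance matching.** The experimental stimuli were matched in *physical*
screen luminance; the package matches mean pixel value instead, justified
by the additive-offset invariance above. Matching is a pure shift about the
frame mean — a gain change would alter contrast, the very quantity under
study. A shift that would push any pixel outside $[0, 255]$ raises an error
reporting the feasible target range; pixels are never clipped silently.
(Consequence: full-contrast 0/255 text pairs cannot be mean-matched by
shifting; use moderate-contrast levels when matched pairs are needed, or
rely on the offset invariance which makes matching irrelevant to the
profile.)

**Controls.** `checkerboard()` is balanced by symmetry (the pattern equals
its own inverse after a half-period translation), giving
$|\mathrm{polarity\ index}| < 0.02$ at every scale, residual border effects
only. `pink_noise()` shapes seeded Gaussian noise to a $1/f$ amplitude
spectrum — the canonical second-order statistic of natural scenes — then
rescales to mean 128 with all values inside $[20, 235]$. Its symmetric
generative distribution makes ON and OFF balance in expectation; the
residual per-seed imbalance shrinks with frame area (at the analyzer's
native 640 x 480 it stays well under $|0.1|$ at all ten scales). These
surrogates emulate only the amplitude spectrum of natural scenes, not their
phase structure, occlusions or shadows — so balanced noise supports, but
does not prove, balance in real outdoor footage.

## Choroidal-thickness statistics

The measurement table is flat: one repeated manual read per row, keyed by
subject, eye, condition (`dark_text`, `light_text`, `blank_screen`),
timepoint (0/30/60 min), thickness in µm and optionally the eye's
spherical-equivalent refraction in diopters.

The pipeline mirrors the study design:

* `change_from_baseline()` averages repeated reads per cell first, then
  subtracts each series' own baseline.
* `condition_effects()` runs two-sided paired t-tests on the changes with
  eyes pooled as independent observations — the study's explicit analysis
  choice — alongside per-eye modes and a conservative subject-level mode
  (eyes averaged first) that is flagged in its output. No
  multiple-comparison correction is applied anywhere, matching the original
  analysis.
* `rm_anova()` is the classical one-way repeated-measures ANOVA over
  timepoint with subject-eye as the repeated unit, sphericity assumed,
  followed by paired t-tests at 30 and 60 min versus baseline. Incomplete
  series are dropped with a warning; degenerate (zero-variance) input is an
  explicit error, not a zero p-value.
* `regress_thinning_on_refraction()` fits OLS of the 60-min dark-text
  change on spherical equivalent with eyes independent, reporting slope
  (µm/D), intercept, Pearson R and its two-sided p.

## The synthetic cohort generator

`simulate_cohort()` exists so the pipeline's estimators can be tested for
parameter recovery; its defaults *are* the study conditions: 7 subjects x
2 eyes, three conditions, timepoints 0/30/60 min, 5 reads per cell,
measurement SD 7 µm (within the reported 5–10 µm repeatability), baseline
255 ± 40 µm (spanning the reported per-observer means around 250–260 µm),
refractions uniform on $[-6.25, +0.25]$ D (the recruited range), 60-min
effects $-16.13$ µm (dark text), $+9.96$ µm (light text) and 0 (blank
screen) with SDs 4.54 and 6.51 µm.

Design choices that the source material left open:

* The published effect SDs are treated as eye-level SDs (drawn
  independently per eye and condition), because the printed ±4.54/±6.51
  accompany the pooled-eyes analysis in which each eye is an observation.
* The refraction dependence of dark-text thinning uses the centered form
  $\Delta_{60} = \mu_{dark} + 1.44\,(SE - \overline{SE})$ so the pooled
  mean stays at $\mu_{dark}$ regardless of the drawn refractions. With the
  default refraction range this is numerically consistent with the
  published line ($1.44 \times (-3) - 11.8 = -16.12$).
* The 30-min change is modeled as a fixed fraction (default 0.5) of the
  60-min change. Significance at 30 min was reported without an effect
  size, so this fraction is a generator parameter, not an empirical claim.
* Diurnal choroidal drift (reported amplitudes up to 30 µm over the day)
  is off by default because measurements were time-locked to one morning
  hour; a sinusoidal drift term can be enabled via `diurnal_amplitude`.

What recovery tests show: averaged over hundreds of simulated cohorts, the
pooled-eyes change-from-baseline estimator recovers the generating 60-min
effects to well within 1 µm, and the median OLS slope recovers the
generating 1.44 µm/D to well within 0.5 µm/D (individual 14-eye cohorts
scatter substantially, as a real 7-subject study would). What they do not
show: anything about the real cohort's p-values or correlation — those
depend on the actual measurements, which require the externally hosted raw
spreadsheet; `read_choroid_csv()` ingests such a table if the user supplies
it.

## Numerical choices and problem sizes

* Ties: a response of exactly 0 contributes to neither channel.
* All aggregation happens in double precision; profile CSV output is
  serialized at 6 significant digits with `.` decimal separator for
  diffability, JSON at full precision.
* t and F statistics delegate to `stats::t.test()` / `stats::aov()`; the
  test suite checks both against independent closed-form and brute-force
  sums-of-squares oracles to 1e-10.
* The oracle-equivalence tests compare the vectorized scan against a naive
  per-position double loop on frames up to 32 x 32; property tests use
  frames from 64 x 64 up to 640 x 480 and 200–500 simulated cohorts,
  sizes at which the full suite runs in well under a minute on one CPU.

## Limitations

* The exact aggregation rule of the original analysis binary is not
  recoverable from its description; the energy-sum default is this
  package's own resolution of that gap, chosen for reproducing the
  documented qualitative behaviors, and the alternative modes are provided
  for sensitivity analysis.
* Display gamma is not modeled: pixel values are treated as luminance
  proxies throughout.
* No real-time guarantee: frames are processed offline; a 640 x 480,
  10-scale profile takes on the order of a quarter second in pure R.
* OCT acquisition, choroid segmentation and inter-observer reliability are
  outside the package's scope; the reliability figures quoted in the
  source material are documented here but not re-estimated.
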