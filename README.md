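# onoffscan

Quantifies how strongly an image stimulates the retina's ON versus OFF
pathways, and replicates the statistical pipeline of choroidal-thickness
reading experiments on real or synthetic measurement tables.

**Who it is for.** Vision scientists and myopia researchers who want to
characterize the contrast-polarity statistics of visual environments —
printed or displayed text above all — and to analyze (or power-test, via
simulation) short-term choroidal-thickness experiments in which subjects
read text of opposite polarity.

## The model

ON retinal ganglion cells respond to luminance increments, OFF cells to
decrements. At every interior position $(x, y)$ of a grayscale frame and at
each scale $k$ (default $k = 1 \dots 10$), the package computes a
center-surround response

$$ r_k(x, y) = I(x, y) \;-\; \tfrac{1}{8}\textstyle\sum I(x \pm k,\, y \pm k) $$

(the mean over the 8 surround pixels at offsets
$(\pm k, 0), (0, \pm k), (\pm k, \pm k)$). Positive responses are
ON-stimulating, negative OFF-stimulating. Per scale, strengths are
aggregated by an energy sum ($\sum r^2$ over each sign class; linear-sum,
count and threshold modes are also available) and summarized by the
polarity index $(\mathrm{ON}-\mathrm{OFF})/(\mathrm{ON}+\mathrm{OFF})$.
Scale maps to spatial frequency as $sf(k) = sf_1/k$, with the default
$sf_1 = 22.4$ cyc/deg corresponding to a 640 × 480 camera with a 16 mm
lens; a 640 × 480 frame is scanned at 285,200 positions.

The companion statistics module implements change-from-baseline summaries,
two-sided paired t-tests (eyes pooled as independent observations),
one-way repeated-measures ANOVA over timepoint with follow-up tests, OLS
regression of thinning on spherical-equivalent refraction, and a seeded
synthetic cohort generator (7 subjects × 2 eyes, conditions
dark-text/light-text/blank, timepoints 0/30/60 min, 5 repeated reads per
cell) for parameter-recovery testing.

## Worked example

```r
library(onoffscan)

frame <- render_text(text_stimulus_spec("DARK TEXT ON A BRIGHT PAGE",
                                        glyph_height = 24))
analyze_frame(frame)
#> ON/OFF profile of a 562 x 72 frame (mean luminance 246.8, margin 10, aggregator power)
#>  scale_k spatial_frequency_cpd on_strength off_strength on_count off_count polarity_index
#>        1              22.40000    23337879     45913746     2696      1297      -0.325998
#>        2              11.20000    22128820     48159141     3206      1297      -0.370338
#>        ...
#>       10               2.24000    19936259     62074491     5323      1297      -0.513814
```

Dark text on a bright background is OFF-dominant at every sampled spatial
frequency (polarity index −0.33 to −0.57 across 22.4 → 2.24 cyc/deg):
the few strongly negative responses on the letter strokes outweigh the many
weak positive ones in the surrounding halo. `analyze_frame(invert_frame(frame))`
flips every sign exactly. Checkerboards (`checkerboard()`) and 1/f-noise
scene surrogates (`pink_noise()`) come out balanced.

A synthetic reading cohort, analyzed end to end:

```r
tbl <- simulate_cohort(cohort_spec(), seed = 1)
condition_effects(change_from_baseline(tbl))
#>     condition pooling  n mean_change       sd         t            p
#>  blank_screen    eyes 14    1.301351 4.118697  1.182221 2.582912e-01
#>     dark_text    eyes 14  -16.611291 6.268221 -9.915694 1.984783e-07
#>    light_text    eyes 14   10.045762 7.982499  4.708776 4.086917e-04
```

After 60 minutes this simulated cohort shows −16.6 µm of choroidal
thinning for dark text and +10.0 µm of thickening for light text (both
highly significant by paired t on 14 pooled eyes), no change for the blank
screen; `rm_anova(tbl, "dark_text")` gives F(2, 26) = 79.9 and
`regress_thinning_on_refraction()` recovers a thinning-vs-refraction slope
of 1.63 µm/D on this draw (generating value 1.44; single 14-eye cohorts
scatter around it).

A command-line wrapper covers the same ground
(`analyze`, `generate`, `stats`, `simulate-cohort` subcommands):

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "onoffscan", package = "onoffscan"))')" \
  generate --text "ON OFF" --out stim.png
```

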