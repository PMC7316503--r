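# loopscope

Quantitative analysis of DNA loop extrusion from single-molecule
fluorescence kymographs.

## The problem

SMC complexes (condensin, cohesin) organize chromosomes by reeling DNA
into loops. In the single-molecule assay this package analyzes, a 48.5 kb
lambda-phage DNA molecule is tethered at both ends below its contour
length, stained with an intercalating dye, and imaged at 100–300 ms per
frame; a looping event appears as a bright diffraction-limited spot
growing on a dimmer line. Because the tether distance `L` is fixed, loop
growth tightens the DNA outside the loop: the relative extension

```
RE(t) = L / (CL_phys * (1 - loop_kb / 48.5))
```

rises toward 1, the worm-like-chain (Marko–Siggia) tension

```
F(x) = (kBT / P) * (1/(4 (1 - x)^2) - 1/4 + x),   P = 50 nm, kBT = 4.11 pN nm
```

climbs, and extrusion slows until it stalls. `loopscope` is aimed at
single-molecule biophysicists who want, per event: the initial extrusion
rate (kb/s), the stall force (pN), a symmetry score
`(max(a,b) − min(a,b))/(a+b)` over the DNA amounts extruded from the two
flanking regions (1 = one-sided, 0 = symmetric; slippage clipped to zero
and flagged above 2 kb), the loop displacement along the strand (static
below 0.08), and, per condition, the looping probability among strands
with sufficient slack (RE < 0.6) with exact binomial comparisons.

The pipeline: perpendicular projection → median background subtraction →
kymograph → per-frame Gaussian fit of the spot → ±2σ loop window →
intensity-to-kb conversion (regions always sum to 48.5 kb) → kinetics,
mechanics and population statistics. A built-in simulator
(`simulate_extrusion()`, `render_kymograph()`, `generate_population()`)
generates events under a tension-limited rate law
`r(F) = r0 * max(0, 1 − F/F_stall)` with full ground truth, so every
stage is testable without raw movies.

## Worked example

```r
library(loopscope)

# one metaphase-like event: a one-sided extruder at 2 kb/s that stalls at
# 0.3 pN on a strand tethered at 45% relative extension
strand   <- strand_config(end_to_end_um = 9, contour_um = 20, n_frames = 300)
extruder <- extruder_config("one_sided_left", rate_left_0 = 2,
                            stall_force_pN = 0.3, landing_position_kb = 24)
set.seed(42)
truth <- simulate_extrusion(strand, extruder)
kymo  <- render_kymograph(truth, strand)    # noisy raster + calibration
kymo
#> kymograph: 300 frames x 77 px; 0.16 um/px, 0.15 s/frame; anchors at px 11 - 67

res <- analyze_event(kymo, event_id = "demo")
res$fit
#> exponential fit: L0 = -1.06 kb, Lf = 18.56 kb, tau = 8.00 s, rate0 = 2.45 kb/s (converged)
res$summary[, c("rate0_kbps", "stall_pN", "score", "class",
                "displacement_rel", "direction_class")]
#>   rate0_kbps  stall_pN score     class displacement_rel direction_class
#> 1   2.453016 0.2786013     1 one_sided       -0.2863771 toward_boundary

initial_rate_savgol(res$trace)   # model-free onset rate, kb/s
#> [1] 1.41
wlc_force(0.85, wlc_params())    # tension at 85% relative extension
#> [1] 0.9626533
```

Reading the output: the recovered stall force (0.279 pN) sits within 7%
of the configured 0.3 pN on this noisy render; the score of exactly 1
identifies strictly one-sided reeling, and the loop, fed from its left
flank, drifts toward the nearer boundary (displacement −0.29). The two
rate estimates differ by design: the exponential fit extrapolates a
saturating curve to t = 0 (2.45 kb/s), while the Savitzky–Golay
derivative reports the actual onset slope (1.41 kb/s ≈ r0 reduced by the
baseline tension factor `1 − F(RE0)/F_stall` = 0.72). The methods
vignette (`vignettes/loop-extrusion-analysis.Rmd`) explains when each is
the right summary.

## Command line

```sh
Rscript inst/cli/loopscope.R simulate --n-events 10 --out runs/sim --seed 7
Rscript inst/cli/loopscope.R analyze  --in runs/sim --out runs/analysis
Rscript inst/cli/loopscope.R population --events runs/analysis/events.csv \
        --out runs/population.csv
```

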