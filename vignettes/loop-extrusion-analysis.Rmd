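---
title: "Quantifying DNA loop extrusion from single-molecule kymographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA loop extrusion from single-molecule kymographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopscope)
```

## The measurement

In the underlying assay, a 48.5 kb linear lambda-phage DNA molecule is
tethered at both ends to a surface at less than its contour length, stained
with an intercalating dye, and imaged at 100-300 ms per frame. A
loop-extruding factor (an SMC complex such as condensin or cohesin) lands on
the strand and reels DNA into a growing loop, which appears as a bright
diffraction-limited spot moving on a dimmer line. Because the tether
distance $L$ is fixed, every kilobase pulled into the loop shortens the DNA
available outside it and raises the tension, until extrusion stalls.

`loopscope` turns such movies (or pre-built kymographs) into per-event
physical quantities: the initial extrusion rate, the stall force, a
symmetry score distinguishing one-sided from two-sided extrusion, the
loop's displacement along the strand, and population-level looping
probabilities. Since raw movies for the original experiments are not
deposited anywhere, the package also contains a simulator that generates
kymographs with exactly the statistical structure the analysis assumes,
with full ground truth, so every stage is testable end to end.

## From movie to kymograph to regions

Each frame is summed perpendicular to the strand axis
(`project_frame()`), the background is removed by a running-median
baseline estimated outside the strand support (`subtract_background()`,
default kernel 51 px), and the per-frame profiles are stacked into a
kymograph (`build_kymograph()`). Anchors are the outermost columns whose
time-averaged intensity exceeds 20% of the strand median.

Per frame, the loop is located as the intensity maximum between the
anchors and refined by a least-squares Gaussian fit
$A\exp(-(x-\mu)^2/2\sigma^2) + c$ in a local window. The strand is then
partitioned into three regions: the loop window $[\mu - 2\sigma,
\mu + 2\sigma]$ and the two flanking regions. The loop signal is the
window sum minus the offset pass-through $c \cdot 4\sigma$ (the non-looped
DNA running underneath the spot, which is returned to the flanking regions
in equal halves), *plus* the fitted Gaussian tail mass outside the window;
that same tail mass is subtracted from the flanking sums. Two details here
are deliberate numerical choices rather than cosmetics:

* **Tail accounting.** A $\pm 2\sigma$ window holds only ~95.4% of a
  Gaussian spot. Without the tail correction the loop is systematically
  underestimated by ~5%, which would break the round-trip recovery
  requirement; with it, the three signals always sum to the total strand
  signal and a noiseless render is recovered to machine precision.
* **Fractional-pixel boundaries.** All window and region sums are
  integrated with fractional pixel coverage, so the partition is a
  continuous function of the fitted center. Integer-pixel windows would
  inject ~0.2-0.4 kb of quantization jitter into the region traces, which
  the first-ten/last-ten difference statistics would inherit.

Signals convert to DNA amounts by `kb = 48.5 * signal / total`
(`intensity_to_kb()`), so `loop + regionI + regionII = 48.5 kb` holds
exactly on every accepted frame, and the segmentation is invariant to
intensity rescaling.

Tracking (`track_trace()`) seeds each frame's search from the previous
center (a plain global argmax is available as `mode = "global"`). Frames
whose profile shows no spot above the noise floor and a 5% contrast floor
over the line level are flagged `no_loop`; Gaussian fits whose width
exceeds half the fit window, or whose partition would need a large
negative clamp, are treated as failed (such fits are invariably the
degenerate "the spot is the whole strand" solution). Isolated failures
are linearly interpolated; traces with more than 30% failed frames are
rejected.

## Mechanics: tension, stall force, contour-length calibration

The tension on the non-looped DNA follows the Marko-Siggia worm-like-chain
interpolation

$$F(x) = \frac{k_B T}{P}\left[\frac{1}{4(1-x)^2} - \frac14 + x\right],
\qquad x = \mathrm{RE}(t) = \frac{L}{CL_\mathrm{phys}\,(1 - \mathrm{loop}/48.5)}$$

with persistence length $P = 50$ nm and $k_BT = 4.11$ pN nm. Neither
constant is printed in the source study; these are the community-standard
values, and they reproduce the published correspondence between ~85%
relative extension and ~1 pN ( `wlc_force(0.85)` = 0.963 pN). The inverse
(`wlc_extension()`) is solved by bracketed root finding and is exact to
1e-9.

The **stall force** of an event is the WLC force at the relative extension
implied by the mean loop size over the last ten accepted frames
(`stall_force()`). Events whose loop window ends within 3 px of an anchor
are excluded — there the loop stopped because it ran out of DNA on one
side, not because it reached its stall tension.

Intercalating dyes lengthen DNA, so all kb-to-physical conversions use the
*effective* contour length. `effective_contour_length()` implements the
calibration: stretch the strand at a known force (1.54 pN in the reference
protocol), measure the extension, and divide by the WLC fractional
extension at that force.

## Kinetics

Loop growth is fit with the saturating exponential
$\mathrm{loop}(t) = L_f - (L_f - L_0)\,e^{-(t-t_0)/\tau}$
(`fit_exponential()`); the initial rate is $(L_f - L_0)/\tau$. The event
onset $t_0$ is the first frame whose loop size exceeds three times the
pre-event noise SD. Convergence is declared only when the relative change
of the cost function falls below 1e-8 — non-converged events are excluded
from rate statistics, mirroring the attrition reported for the original
datasets. The optimizer is a small Levenberg-Marquardt routine that
requires the relative-cost criterion on two consecutive accepted steps
(a single small step can be a damped stall far from the optimum).

A model-free alternative is the Savitzky-Golay first derivative of the
loop trace (`initial_rate_savgol()`, order 2, window 63 by default). For
trace smoothing before tension conversion the same filter is used
(`smooth_trace()`), since thermal fluctuations in the relative extension
amplify enormously through the steep WLC law.

**A caveat the simulator makes visible.** Under the simulator's
tension-limited rate law (below), loop growth is *not* exponential: it is
nearly linear while the WLC is soft and bends sharply near stall. On such
curves the exponential fit systematically overestimates the onset
derivative (by up to a factor ~2 at high stall force), while the
Savitzky-Golay derivative recovers the true onset rate to a few percent —
provided its window does not span the entire growth phase, which is why
`initial_rate_savgol()` caps its window at about half the growth phase.
The two estimators agree (within 15%) exactly when the kinetics really are
exponential, and the package's recovery tests therefore use the
model-free estimate against the generator's true onset rate. On real
data, where the functional form is unknown, both numbers are reported.

## Symmetry and displacement

For each flanking region, the DNA it contributed is the mean of its first
ten accepted time points minus the mean of its last ten
(`region_changes()`). A region that *gained* DNA (the loop slipped) is
clipped to zero contribution, with the gain recorded as slippage and
flagged when above 2 kb. The symmetry score
$(\max(a,b)-\min(a,b))/(a+b)$ is 1 for strictly one-sided and 0 for
balanced two-sided extrusion; events at or above 0.5 are classified
one-sided (two-sided is defined by "score below 0.5", so the boundary
belongs to one-sided). The published sign bookkeeping for $a$ and $b$ is
internally inconsistent (its two sentences imply opposite conventions);
defining $a, b$ as non-negative *extruded amounts* makes the printed
formula yield 1 for one-sided and 0 for symmetric events, matching the
published exemplar distributions, and that is what `loopscope` does.

Loop displacement (`loop_displacement()`) is the change in relative
position between the first and last ten points, sign-oriented so that
motion towards (or across) the strand center is positive, and classified
static below 0.08. A loop starting exactly at the center can only move
towards a boundary, so its displacement is defined as negative.

## Population statistics

The looping probability of a condition divides the number of looping
strands by the number of strands with sufficient slack (baseline relative
extension below 0.6); taut strands cannot form loops and are excluded from
the denominator (`extrusion_probability()`, Wilson 95% intervals).

Conditions are compared with an exact binomial test
(`compare_conditions()`). The source only says "Binomial test", and the
obvious plug-in reading — test the treated count against the control's
point estimate — has a simulated type-I error of ~7% at a nominal 1%
for 40-strand arms, because it ignores the control's sampling noise. The
package default therefore *conditions on the total*: under equal looping
probabilities, the split of the $a+b$ events between two conditions with
$n_a$, $n_b$ eligible strands is tested against
$\mathrm{Binomial}(a+b,\; n_b/(n_a+n_b))$, which is exact under Poisson
sampling and conservative under binomial sampling (measured type-I error
\< 0.001 at $\alpha = 0.01$). The plug-in flavor is retained as
`method = "plugin"`; it is the more powerful of the two and matches the
closed-form tail example in the package tests.

`cluster_errorbars()` reproduces proximity-clustered scatter summaries:
1-D agglomerative clustering on the x axis with a 0.05 gap threshold
(configurable), per-cluster mean and SD, raw points preserved.

## The simulator: a stated world

`simulate_extrusion()` integrates, with forward Euler at the camera frame
interval,

$$\frac{d\,\mathrm{loop}}{dt} = [r_{L,0} + r_{R,0}]\,
\max\!\left(0,\, 1 - F/F_\mathrm{stall}\right)$$

with $F$ the WLC tension at the current relative extension. The linear
decay to stall is the simplest law reproducing the published
phenomenology (rates fall with tension; events stall at sub-pN forces);
the published data constrain no particular functional form. Euler at the
frame interval keeps the truth sampled exactly at frame times, and the
integration error at kb/s rates over 100-300 ms steps is negligible
against every tolerance used. The loop's genomic position drifts by half
the left/right reeling imbalance; its physical position is the fraction of
non-looped DNA to its left, assuming uniform stretching.

`render_kymograph()` spreads the non-looped DNA uniformly between the
anchors (fractional coverage at the end pixels), adds the loop as a
Gaussian spot of width 1.3 px (the diffraction limit for 561 nm emission
at 0.16 um/px; the study reports the optics, not a PSF width) whose
discrete mass is exactly `loop_kb * line_intensity_per_kb`, then applies
Poisson shot noise, Gaussian read noise (SD 5), and a constant offset of
50 photons/px. The study reports no photon budget or camera noise model;
the defaults (200 photons/kb/frame line intensity) give the spot and line
comfortable but not generous SNR and are stated once here, not fitted.

`generate_population()` samples the stated world: baseline relative
extension uniform in 0.35-0.55 (all strands pass the 0.6 slack filter),
zero-tension rates uniform in 1-3 kb/s, stall forces uniform in
0.15-0.6 pN, landing positions in the central 60% of the strand, and an
80/20 one-sided/two-sided mixture by default (two-sided events draw both
rates independently, so their scores land in [0, 0.5) and the score-based
classifier should recover the mixture exactly). The sampled tether
distance is snapped to the camera pixel grid so that the rendered anchor
span and the simulated geometry describe the *same* strand — near stall
the WLC force is so steep that a half-pixel inconsistency already moves
the apparent stall force by ~5%.

What the simulator does **not** emulate: nucleosome or protein obstacles,
multiple simultaneous loops per strand (the original analysis selected
single-loop strands), strand drift or photobleaching, depth-dependent
PSF changes, or direction switching of the extruder. A green round-trip
test therefore establishes that the *analysis* is faithful to its stated
model of the data — not that real movies obey that model.

## Observation windows and the stall plateau

The approach to stall is asymptotic (the rate decays linearly in the
remaining force gap), so a finite movie always ends slightly below
$F_\mathrm{stall}$. At the defaults (300 frames, 0.15 s) fast events are
fully converged but slow, high-stall events can sit ~5% low; the recovery
tests therefore observe for 600 frames (90 s), after which the residual
gap is far below every tolerance. Real experiments have the same
property; it is one reason reported stall forces can underestimate the
motor's true capability.

## Known limitations

* Single loop per strand; mixture fits for multiple loops are out of scope.
* The strand axis must be horizontal within the user-supplied ROI; no
  rotation or drift registration.
* Forces are meaningful up to a few pN only (inextensible WLC).
* Raster I/O uses plain-text TSV + JSON sidecars; the sandbox R library
  has no TIFF codec, and the schema carries the same calibration metadata.
* The exponential initial-rate estimator inherits the model mismatch
  described above; prefer the Savitzky-Golay estimate when the kinetics
  are tension-limited.
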