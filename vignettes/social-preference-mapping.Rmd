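---
title: "Quantifying social preference and whole-brain c-fos activity in zebrafish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying social preference and whole-brain c-fos activity in zebrafish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialfish)
```

## The assay and what the package computes

Juvenile zebrafish are strongly attracted to the sight of conspecifics. In
the three-chamber assay a single test fish swims in a central arena with a
window onto a chamber holding stimulus fish on one side (the social-cue, SC,
side) and an empty chamber on the other (No SC). Social preference is
summarized by the **visual preference index**

$$\mathrm{VPI} = \frac{n_{SC} - n_{NoSC}}{n_{\text{total}}},$$

the difference between the number of video frames spent on each side of a
virtual midline, divided by all frames. VPI ranges from $-1$ (complete
avoidance) to $+1$ (complete preference). Fish are classed *pro-social*
(`+S`) when VPI $> 0.5$, *anti-social* (`-S`) when VPI $< -0.5$, and
*non-social* (`ns`) otherwise. Alongside VPI the package scores *percent
time moving* (the fraction of frames with detectable pixel change against
the previous frame) and *percent time freezing* (the fraction of frames
inside continuous no-motion periods strictly longer than 3 s — an
anxiety-like behaviour), plus one-minute binned time courses of VPI and
movement.

The imaging arm quantifies whole-brain expression of the immediate early
gene *c-fos*, a proxy of recent neural activity, in registered fluorescence
volumes. Each volume is normalized to its own background fluorescence, the
fish of a condition are averaged into a voxel-wise map, conditions are
contrasted against a no-social-cue (nsc) baseline as
$(\text{group} - \text{nsc})/\text{nsc}$, and named 3D region masks (e.g.
posterior tuberal nucleus, optic tectum, dorsal/ventral caudal
hypothalamus and preoptic area) are reduced to per-fish mean intensities
for group statistics. All group comparisons use the two-sided Mann-Whitney
U test, because none of these metrics is close to normally distributed
across fish.

## Video tracking

Tracking follows the classical crop / background-subtract / threshold
chain:

1. **Background**: per-pixel median over a strided sample of frames
   (`background_stride`, default every 10th frame). The fish occupies any
   one pixel a minority of the time, so the median recovers the empty
   arena without a fish-free recording. The converse failure mode is
   informative: a fish that never moves is absorbed into the background
   and cannot be segmented — `track_video()` warns when detection falls
   below 50% of frames.
2. **Segmentation**: pixels whose absolute background difference exceeds
   `intensity_threshold` are labelled into connected components; the
   largest component above `min_area_px` is the fish. The centroid is the
   difference-weighted component centroid; the heading is the principal
   axis of the second-order moments, pointed toward the heavier half of
   the blob, with a confidence score from the mass asymmetry (for a
   symmetric blob the head/tail choice is arbitrary and the confidence is
   near zero).
3. **Motion**: `motion_px` counts pixels whose frame-to-frame change
   exceeds `pixel_delta_threshold`; a frame is *moving* when the count
   exceeds `motion_count_threshold`. Two thresholds are needed because a
   per-pixel threshold alone still fires on sensor noise somewhere in the
   frame: at the defaults (per-pixel threshold several times the noise sd,
   count floor 10 pixels) pure-noise frames are flagged moving in well
   under 1% of cases, while a displacement of a fraction of a body length
   changes tens of pixels.

Frames without a detection are retained with `is_valid = FALSE` so frame
indices stay aligned; all behavioural denominators use valid frames only.
Frames exactly on the midline count to neither side but stay in the VPI
denominator, and the boundary values $\pm 0.5$ fall in the `ns` class —
both are measure-zero conventions for continuous data but must be pinned
down for reproducibility. Coordinates are 0-based pixels, x rightward,
y downward. Because the cue chamber is randomized left/right across
sessions, the layout's `sc_side` carries that information; data are never
mirrored.

## The synthetic session generator

Every stage is validated against simulated data with known ground truth,
generated by `generate_trajectory()` and `rasterize_video()`.

Zebrafish swim in discrete bouts, so locomotion is modelled as a marked
Poisson process rather than a diffusion: bout onsets arrive at
`bout_rate_hz` (default 2 Hz, a typical juvenile bout rate), and between
bouts the fish is exactly stationary, which makes the moving/not-moving
ground truth unambiguous. At each bout the fish commits to the social-cue
side with probability `side_bias` and swims toward a uniformly drawn
target in the committed side by a gamma-distributed step (shape 4, mean
`bout_step_px`), capped at the target distance. A bout that changes sides
swims at least far enough to complete the midline crossing within the
bout. That last rule is what makes the generator *calibrated*: each
inter-bout interval is then spent entirely on an independently chosen
side, so the stationary occupancy of the SC side equals `side_bias`
exactly and

$$E[\mathrm{VPI}] = 2 \cdot \texttt{side\_bias} - 1.$$

Two seemingly natural alternatives fail this calibration and were
rejected: capping the step without the crossing rule lets high-bias
commitments abort unfinished crossings (occupancy overshoots the bias),
and persisting a crossing across bouts leaves partial-crossing intervals
that inflate the minority side (occupancy shrinks toward 0.5). Both
deviations are small (about 0.01–0.015 in VPI) but systematic, and the
calibration tests average 50 sessions, so they would dominate.

Freezing bouts are a second Poisson process (`freeze_rate_hz`,
exponential durations with mean `freeze_duration_s`) that suppresses swim
bouts, giving the freezing detector exact known intervals. Note that
inter-bout gaps occasionally exceed 3 s by chance (about
$e^{-3\,\cdot\,\texttt{bout\_rate\_hz}}$ per bout), so measured percent
freezing sits slightly above the injected amount even at
`freeze_rate_hz = 0` — real fish pause too, and the detector is defined on
motion, not on the generator's labels.

Rendering paints a uniform-intensity ellipse (semi-axes half and quarter
of `fish_length_px`) oriented along the heading onto a constant background
with Gaussian pixel noise, in `[0, 1]` intensity units. The generator does
**not** emulate: the stimulus fish (never tracked in the analysis),
reflections and illumination gradients, occlusions, body bending, or
identity swaps. Passing tests therefore demonstrate the correctness of the
measurement chain, not robustness to every artefact of real video; the
explicit thresholds in `track_config()` are the knobs a real deployment
would calibrate.

Default session geometry is a 200×200 px arena at 30 fps for 900 s (the
assay's 15-min periods); frame rate and geometry are free parameters of
the rig, not of the method.

## Volume normalization

Registered fluorescence volumes differ in intensity scale between imaging
sessions (staining efficiency, laser power, detector gain). Normalization
maps each volume onto a common scale on which background tissue
fluorescence equals 1:

1. histogram all voxels into 10000 bins spanning $[-4000, 70000]$
   (bin width 7.4 units);
2. **bias** = bin centre of the lowest-intensity bin holding at least 100
   voxels — the darkest population large enough not to be an outlier,
   i.e. the additive offset (detector dark level, registration padding);
3. **mode** = bin centre of the maximal-count bin — the tissue background
   plateau;
4. every voxel $v \mapsto (v - \text{bias}) / (\text{mode} - \text{bias})$.

Numerical conventions the procedure leaves open are fixed as: bin
representative values are bin centres (any choice shifts bias and mode by
at most half a bin, 3.7 units); "minimum value bin" means the
lowest-intensity qualifying bin, which is what makes it usable as an
offset; mode ties break to the lower bin and are reported; out-of-range
voxels are clamped into the terminal bins for counting, tallied, and left
untouched in the volume; a volume whose mode does not exceed its bias
(e.g. a constant volume) raises a degenerate-baseline error rather than
dividing by zero.

The map is strictly monotone, and for an affine distortion
$v \mapsto a v + c$ ($a > 0$) the normalized output is invariant *up to
the bin quantization of the bias and mode estimates*. That envelope is
voxel-dependent: writing $u$ for the normalized value and $w'$ for the
scaled bin width, quantization of bias and mode (each up to about one bin
including sampling noise of the histogram peak) propagates to at most
$(1 + |u|) \cdot 2 w'$ at that voxel. Tests assert this derived envelope;
a flat "one bin everywhere" bound is not attainable for bright voxels,
since a half-bin shift of the mode alone scales the whole upper range.
The bias rule also explains a structural requirement on the data: it
recovers the additive offset only because real volumes contain non-tissue
voxels near the dark level. The synthetic cohort generator therefore
surrounds its ellipsoidal "brain" (tissue background
`background_level` ± `background_sd`, default 1000 ± 50) with a dark rim
carrying reduced noise (`background_sd / 5`, read noise versus shot
noise); on a phantom without that floor the 100-voxel rule lands in a
scale-sensitive tail quantile of the tissue noise and affine invariance
genuinely degrades. Per-fish session distortions are drawn around
`session_gain` (lognormal, 10% CV) and `session_offset` (normal, sd 10%
of magnitude + 1 unit) so that no two volumes share a scale.

## Region quantification and group maps

Group maps are voxel-wise means of normalized volumes. Difference stacks
are $(\text{group} - \text{baseline})/\text{baseline}$ per voxel, with
voxels whose baseline mean falls below `eps` (default 0.1 normalized
units, well below any plausible tissue value) marked `NA` rather than
producing unstable ratios.

Regional activation subtracts and then divides the group's mask average by
the baseline group's: $100 (\bar g - \bar b)/\bar b$ percent. Because both
paths are linear, the mask average of the group-average volume equals the
group average of per-fish mask means, so the "voxel path" and the "region
path" agree by construction; the per-fish mask means are retained as the
sampling units for statistics, matching per-fish n reporting. Two baseline
conventions exist in practice — the matched same-rearing nsc siblings, or
the control-nsc group for all conditions — so `region_activation()` takes
the baseline cohort explicitly and records its label in the result; the
caller must choose, and reports name the choice. Masks are binary, with
no partial-volume weighting.

## Group statistics

`mann_whitney_u()` computes U from midrank sums and takes two-sided
p-values from the exact permutation distribution when
$n_a + n_b \le 16$ and the pooled sample is tie-free, and from the normal
approximation with tie and continuity correction otherwise (the p-value
computation is delegated to `stats::wilcox.test`, the reference
implementation). Two-sided tests are the conservative reading for
two-group comparisons. For tie-free samples the p-value depends only on U;
sweeping every achievable U at $n_a = n_b = 8$ shows the
continuity-corrected approximation stays within 0.011 of the exact value
(the worst case, 0.0109, occurs at mid-range U), which is the agreement
bound the tests assert. No multiple-testing correction is applied to the
primary report, matching per-comparison reporting conventions; a
Benjamini–Hochberg column is appended to comparison tables as an opt-in
annotation.

## The pipeline and problem sizes

`run_pipeline()` ties the stages together from a single config (R list or
YAML): simulate each behavioural group, score per-fish metrics and binned
time courses, simulate and normalize volume cohorts, quantify region
activations against the named baseline, and compare each group to its
reference. All randomness derives from the config seed, so every derived
table is reproducible from config alone.

Behavioural cohorts are scored on the simulated trajectories directly by
default (`render_videos = FALSE`); rendering thirty 15-minute videos per
group to pixels only to re-track them exercises no additional logic at
three orders of magnitude more compute, so video rendering plus tracking
is validated on shorter sessions (a 1000-frame session tracks with
centroid RMSE around 0.1 px and 100% moving-frame agreement) and the
equivalence of the two scoring routes is itself a test. The test suite
uses 64³ and 64×64×32 voxel volumes; the full-resolution 512×512×273
grid is supported by the same code but adds nothing to correctness
checks. Sociality classes are computed from social-period VPI only;
acclimation and social-cue periods are separate sessions and metrics never
mix them.

## Known limitations

* The tracker assumes a single animal; it keeps the largest blob and has
  no identity model.
* Heading is reliable only up to the blob's intensity asymmetry; for a
  nearly symmetric blob the head/tail flip is undetermined (flagged by
  `head_confidence`).
* The median background model fails for a fish immobile through most of
  the recording (detected and warned, not silently wrong).
* Registration is out of scope: volumes are assumed aligned to a common
  reference, and masks are inputs drawn in that space.
* The normalization's bias estimate requires a dark non-tissue population
  in the volume; fully cropped-to-tissue volumes would need a different
  offset estimate.
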