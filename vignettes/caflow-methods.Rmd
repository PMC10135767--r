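---
title: "Quantifying calcium transients of firmly adhering cells under flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying calcium transients of firmly adhering cells under flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caflow)
```

## The assay and the measurement model

In a parallel-plate flow chamber, cells carried by the perfusate interact
with an adhesion ligand immobilized on the bottom coverslip. Some cells
roll or slide across the field; some arrest. In arrested cells, receptor
engagement can trigger a cytosolic calcium burst, reported by a
calcium-sensitive dye as a fluorescence transient: a low plateau during a
latent delay, a swift rise to a peak, and a gradual relaxation back to the
original level.

`caflow` quantifies such recordings with the following operational chain:

1. **Firm adhesion.** A cell is *firmly adherent* when its travel
   displacement over a sliding 1-minute window is strictly less than
   10 µm. The displacement of a window is the net Euclidean distance
   between its first and last tracked positions (a cumulative path-length
   mode is available; net displacement is the weaker criterion and the
   common convention for rolling-versus-arrest classification). The start
   of the earliest qualifying window is the arrest onset and defines
   `t = 0` for the cell's calcium trace. The adhesion-assay readout is the
   number of firmly adherent cells arresting within a 7-minute window.

2. **Normalized fluorescence.** For each firmly adhered cell and frame,
   the mean cell fluorescence `F_IC` (arithmetic mean over the cell mask)
   is normalized against the local background `F_IB` as
   `F_IN = (F_IC - F_IB)/F_IB`. The background is the mean of the mean
   intensities of four equidistant round domains of area 36π µm² (radius
   6 µm) centered 24 µm from the cell centroid at 0°, 90°, 180° and 270°.
   The symmetric placement cancels a linear illumination gradient to first
   order; a domain that crosses the frame edge or touches another detected
   cell is dropped, and at least two domains must survive or the trace is
   flagged unreliable.

3. **Transient characteristics.** Per activated cell: the *delay time*
   `T_D` (arrest onset to rise onset), the *peak time* `T_P` (rise onset to
   trace maximum) and the *peak calcium intensity* `I_P` (peak over
   delay-plateau fluorescence ratio).

4. **Group statistics.** Student's two-sample t-test (pooled variance by
   default, Welch optional) for two groups; one-way ANOVA with Tukey's HSD
   for three or more; boxplot five-number summaries (maximum, upper
   quartile, median, lower quartile, minimum) plus mean ± SEM per group.
   The pipeline warns whenever a group carries fewer than 15 events, the
   assay's collection rule.

## Two printed definitions of I_P

The assay literature states the peak intensity both as "the ratio of the
normalized peak fluorescence to the normalized plateau fluorescence" and as
"the ratio of the highest fluorescence intensity to the average fluorescence
intensity during the delay period". These disagree exactly where it
matters: `F_IN` sits near 0 for a dim plateau, making the normalized ratio
numerically unstable and sign-sensitive. The default (`ip_mode =
"raw-ratio"`) therefore computes the raw-equivalent intensity ratio

    I_P = (1 + F_IN_peak) / (1 + F_IN_plateau)

which, under a stable background, is algebraically the ratio of raw cell
fluorescences and is also what the synthetic generator's `I_P` parameter
means. The literal normalized reading is available as
`ip_mode = "normalized-ratio"`; both are recorded in the run provenance.

## Onset and peak estimation

"Sharp increase" needs an operational rule. The trigger is the classic
running-plateau test: scan the trace and fire at the first time the signal
exceeds `plateau_mean + max(k * plateau_SD, floor)` for `m` consecutive
frames (`k = 3`, `m = 5`, floor 0.1 F_IN units), with plateau statistics
accumulated from `t = 0` up to the candidate and at least 2 s of plateau
data required. Two refinements make this rule meet frame-level accuracy,
and both were designed on simulations at the package's stated operating
points (noiseless traces, and peak signal-to-noise ratio 5, i.e. per-frame
noise SD equal to one fifth of the rise amplitude):

* **The trigger scans a smoothed copy of the trace** (centered moving
  average, 1 s by default). On a slow ramp under heavy noise, a raw-trace
  trigger loses a race: by the time the signal clears `k` noise SDs, the
  expanding plateau estimate has absorbed part of the ramp, inflating both
  its mean and SD, and the threshold runs away faster than the signal. In
  simulation at SNR 5 the raw-trace trigger missed roughly 90% of
  activated cells; the smoothed trigger, whose effective noise is several
  times smaller, fires at ~15% of the ramp and misses none. Only the
  trigger uses this filter — no feature value is read off a smoothed trace.

* **The onset is refined by a changepoint fit.** A threshold crossing is
  systematically late by `floor/slope` even without noise. The onset is
  therefore relocated by a two-segment least-squares fit (constant plateau,
  then a linear rise continuous at the knot) over the frames up to the
  rise top, followed by a sub-frame backcast: a line is fitted to the lower
  80% of the rise (the top excluded so curvature near the peak cannot tilt
  it) and intersected with the plateau level. On a noiseless linear ramp
  this recovers the onset exactly.

The peak is located as the **intersection of a rise line and a decay
line**. A moving-average argmax gives the peak locality; the rise line is
fitted on frames ending one smoothing window before it and the decay line
on frames starting one window after it, so both segments stay clear of the
kink even when the argmax jitters under noise. The intersection carries no
smoothing lag (a smoothed argmax alone is biased toward the slower side of
an asymmetric kink by up to half the filter width) and its value provides
the peak fluorescence for `I_P`. The decay-line length adapts to the
measured plateau noise: a long window (six smoothing widths) when the
variance of the extrapolated line dominates, a short one (one width) when
noise is negligible and the bias of fitting a straight line to a convex
exponential dominates. When the geometry degenerates (no decay data, slopes
that do not cross), the estimator falls back to the raw-trace mean in a
±0.25 s window around the argmax.

A cell is called **activated** when an onset was found *and* `I_P` reaches
the activation threshold (default 1.5, `>=` convention). The I_P condition
also suppresses false calls on flat noisy traces, where spurious triggers
produce near-unity ratios.

## Cell detection, tracking and mask policy

Detection is smoothing (optional) → global threshold → connected components
→ area filter → intensity-weighted centroids. The default threshold is
`median + max(k · 1.4826 · MAD, 0.2 · median)` rather than
`mean + k · SD`: on a field where cells occupy ~10% of the pixels, the
frame SD is inflated by the cells themselves and a mean-based threshold
climbs above the dimmer cells (on the generator's default scenes it misses
them outright); the median/MAD pair tracks the background. The floor term
is a fraction of the frame median so that detection — and everything
downstream — is exactly invariant under a global illumination rescaling.
The `mean_sd` method is retained as an option.

Linking is greedy nearest-neighbour with a deterministic tie-break
(candidate pairs sorted by distance, then track id, then detection index),
a maximum step per transition, and closure after `max_gap` missed frames.

For the calcium trace the cell mask and the background-domain pixel sets
are **frozen at the arrest-onset frame**: the cell does not move after
arrest, and a per-frame threshold mask would grow with brightness, coupling
the segmentation to the very signal being measured and biasing the
peak/plateau ratio. Background-domain exclusions use the union of the
detections at the onset frame and at the final frame, because a cell
arriving *after* this cell's onset would otherwise fire inside a domain
(in simulation this contaminated `F_IB` by several percent).

## The synthetic generator

No recordings ship with the assay, so the generator is the test bed. It
emulates, with known ground truth:

* the transient shape: plateau → latent delay `T_D` → linear rise of
  duration `T_P` to `plateau × I_P` → single-exponential relaxation with
  time constant τ (the rise is stated only as "swift" and the decay as
  "gradual" in the assay literature; a linear ramp makes the peak time
  unambiguous, and a smoothstep alternative is available);
* acquisition: 20 fps for calcium scenes (the assay's calcium-imaging
  rate; the adhesion assay's 50 fps/10× recording is emulated by the same
  machinery at the user's chosen rate); pixel size is a required scene
  parameter (2 µm/px default in cohorts) since no published value exists;
* imaging: cells as radially symmetric disks (Gaussian profile, SD =
  radius/2, truncated at the radius; default radius 7.5 µm, a typical
  lymphoid-cell scale) whose mask-mean intensity follows the cell's trace
  exactly, on a uniform background (default 100 a.u.) with optional
  Gaussian and Poisson noise;
* cohorts: per-condition lognormal distributions of `T_D`, `T_P`, `I_P`
  and plateau level, a non-activated fraction, and built-in designs that
  encode the assay's qualitative effect directions (ligand density, wall
  shear stress 0.15/0.30/0.60 dyn/cm², channel-inhibitor and
  adaptor-knockdown contrasts). The published per-condition values exist
  only as boxplots, so the medians here (e.g. delay 60/40/25 s across the
  three shear levels, peak intensity 2.2/3.0/4.0) are generator choices
  fixed once to plausible magnitudes with the published directions — not
  literature values.

Stack-mode cohorts place cells on a jittered grid wide enough (40 µm
spacing) that neither detection nor the 24 µm + 6 µm background-domain
geometry collides between neighbours, and let each cell enter the field at
its arrest time: at high magnification the focal plane contains the
adhering cells, and free-flowing cells pass out of focus. Arrest times are
drawn on the acquisition frame grid — an arrest is only ever observed at
frame resolution anyway. Translating (rolling/sliding) cells and
mid-recording arrests are available through `scene_spec()` for tracking
studies.

In traces-only mode each cell yields an arrest-relative trace directly
(`t_rel_s` from 0, constant background `F_IB`), matching the trace-CSV
input contract of the quantification stage; per-cell noise is parameterized
by the peak SNR (rise amplitude over per-frame noise SD). What the
generator does **not** emulate: photobleaching and dye kinetics, receptor–
ligand bond mechanics or hydrodynamics (shear stress is a covariate label
with stated effects, not a solved flow field), cell shape change,
multi-peak oscillations, and focus drift. Green tests therefore certify
the estimators against the stated trace model and imaging geometry, not
against every artifact of real microscopy.

## Numerical choices and degenerate inputs

* Window displacement uses strict inequality at the 10 µm threshold
  ("less than"); windows slide at frame resolution and the earliest
  qualifying window defines onset. Tracks shorter than the window are
  returned not-firm with an `insufficient_span` flag.
* Quartiles use linear interpolation between order statistics
  (`stats::quantile` type 7); boxplot quartile conventions vary between
  tools, so one rule is fixed and documented.
* A two-group comparison where both groups have zero variance and equal
  means reports `p = 1` with a `degenerate` flag instead of erroring;
  a single-value group reports SEM 0 with a flag.
* Traces with more than 20% QC-failed frames (unusable background) are
  rejected; fewer than two usable background domains marks the whole trace
  unreliable.
* Peak ties are broken toward the earliest frame; 16-bit TIFF output
  quantizes to the stated `max_value` scale and records it in the sidecar
  so a round trip restores intensities to within one level.
* All randomness flows from explicit integer seeds; rendering, cohort
  generation and the full pipeline are bit-reproducible for a fixed seed.

## Problem sizes used by the tests

The bundled checks run, among others: a noiseless rendered cohort of 60
cells at 20 fps (~2500 frames of 172×172 px, about one minute of compute),
a 60-cell trace cohort at peak SNR 5, a 200-track comparison of the
adhesion classifier against an exhaustive-window oracle, and a
1000-replicate null calibration of the two-group test and the ANOVA on
scaled-down trace cohorts (15 cells per group, 10 fps, shortened
transients — the spread of the features, not their absolute scale, is what
calibration exercises). These sizes were chosen to give stable estimates
of the quantities being checked while keeping the default suite in the
minutes range.

## Known limitations

* The arrest-onset estimate is bounded by the displacement criterion
  itself: for a cell that decelerates gradually, any window-based rule
  dates the arrest within `threshold/velocity` of the true stop. The
  synthetic acceptance cohorts use cells that appear at arrest, so this
  ambiguity — inherent to the assay definition, not to the implementation —
  is not folded into the accuracy figures.
* The detector is a global-threshold segmenter: it assumes roughly uniform
  background and non-touching cells, which the generator guarantees but a
  crowded real field may not.
* Decay kinetics are deliberately not fitted (no τ estimate is reported);
  the decay line in the peak estimator is a local linearization only.
* The activation call depends on two thresholds (`k`, `activation_threshold`)
  whose defaults were tuned on the generator's trace model; strongly
  non-Gaussian noise (e.g. uncorrected shot noise at very low counts) may
  need a higher `k` or the median pre-filter.
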