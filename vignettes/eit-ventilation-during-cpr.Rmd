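---
title: "Measuring lung ventilation with EIT during mechanical chest compressions"
author: "eitcpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring lung ventilation with EIT during mechanical chest compressions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eitcpr)
```

## The measurement problem

Electrical impedance tomography (EIT) reconstructs relative thoracic
impedance changes on a pixel grid at a fixed frame rate; regional impedance
change tracks regional air content. Summed over the lung region, the signal
rises and falls with each breath: the minima mark inspiration onsets, the
maxima end-inspiration, and the difference — VT\_EIT, in arbitrary units
(a.u.) — is proportional to tidal volume. The per-breath minimum, the
end-expiratory lung impedance (EELI), tracks end-expiratory lung volume.

During cardiopulmonary resuscitation with a mechanical piston device this
signal is buried under a large oscillatory artifact at the compression rate
(102/min, i.e. 1.7 Hz, against a ventilator at 10 breaths/min, 0.167 Hz).
`eitcpr` implements the complete analysis chain for this setting —
artifact filtering, breath segmentation, tidal and end-expiratory indexes,
regional heterogeneity indexes, respiratory mechanics from esophageal
manometry, and the inferential layer for comparing trunk inclinations
(flat, 18°, 35°) — together with a synthetic-data generator with known
ground truth so that every stage is verifiable by parameter recovery.

## Signal model of the generator

Each lung pixel carries

* a **tidal component**: the pixel's amplitude times a normalized cycle
  waveform — linear rise over the 1-s constant-flow insufflation, plateau
  over the 1-s end-inspiratory pause, exponential decay (time constant
  0.8 s by default) over the 4-s expiration, rescaled to end exactly at
  zero. The spatial amplitude pattern is anterior-dominant (ventilation
  skewed ventrally, as under anaesthesia with dorsal atelectasis).
* an optional **antiphase (pendelluft) component**: a posterior pixel blob
  uses the negated waveform. Its summed amplitude is parameterized as a
  fraction of the *net* global tidal change, so the pendelluft index truth
  is exactly −100 × fraction (default 8%, within the range seen in
  practice).
* a per-pixel **inflation-onset delay**, rising linearly toward the
  posterior rows (default up to 30% of the insufflation time). Delays are
  injected as pure time shifts of the periodic waveform. This matters:
  time shifts commute with the zero-phase linear filter, so inter-pixel
  timing differences — the substrate of the regional-ventilation-delay
  statistics — survive filtering exactly.
* a **compression artifact** inside annotated compression windows:
  fundamental plus a 30% second harmonic at the device rate (piston
  devices are not sinusoidal; one harmonic suffices to stress the filter),
  weighted per pixel by relative tidal amplitude.
* an **EELI drift**: a first-order fall (default magnitude 1.2 × VT\_EIT,
  time constant 10 s) during compression windows, held afterwards — the
  baseline settles at a new, lower stable level, as compression-induced
  loss of end-expiratory lung volume does.
* white Gaussian **pixel noise** (default SD 0.5 a.u. against mean pixel
  amplitudes of ~10 a.u.).

Trunk-inclination effects are injected as multiplicative tidal factors per
angle (defaults 1 / 0.95 / 0.55 for flat / 18° / 35° during compressions,
mimicking the direction and magnitude of the real effect: tidal impedance
roughly halves at 35° under compressions, and is stable without them).
The 18°→35° elevation ramp is linear over a configurable duration
(default 120 s; the corresponding ramp rate, 17°/120 s ≈ 0.14°/s, is
exposed as a parameter rather than fixed, since quoted ramp rates for such
devices vary).

```{r generator}
sim <- simulate_eit_recording(subject_params(grid_dims = c(16, 16)),
                              cc = compression_settings(windows = cbind(30, 90)),
                              duration_s = 96, seed = 1)
sim$truth
```

## Artifact filtering

The respiratory band (fundamental 0.167 Hz and its first harmonics) and the
compression band (1.7 Hz) are well separated, so a low-pass filter works.
The cutoff defaults to the geometric mean of the respiratory third harmonic
and the compression fundamental (√(0.5 × 1.7) ≈ 0.92 Hz); an order-4
Butterworth is applied forward–backward (zero phase), with even-reflection
end padding against edge transients. Applied twice, attenuation at 1.7 Hz
exceeds 40 dB while the respiratory fundamental passes essentially
unchanged. Zero phase matters because breath timing feeds every downstream
index. The filter is linear, so filtering each pixel with the same kernel
and summing equals filtering the global sum; pixel maps therefore conserve
the global tidal change exactly. All filter parameters (cutoff, order) are
configuration, not constants: the band placement depends only on the two
rates, and both are arguments.

Two properties of the filtered waveform shape the conventions downstream:

* An order-4 Butterworth rings slightly at the waveform's corners, so the
  filtered cycle amplitude overshoots the true amplitude by ~3.5% at these
  settings. This is the dominant (and bounded) bias of VT\_EIT recovery.
* With a 1-s inspiratory hold, the signal maximum is a *plateau*.
  Per-breath VT\_EIT is therefore defined as cycle maximum minus onset
  value, while the *timing* marker for end-inspiration is the last sample
  within 10% of the cycle maximum (contiguous with it) — i.e. the end of
  the hold, which is where the inflation window for delay statistics
  should end. The per-pixel tidal map is evaluated at the cycle-maximum
  frame, where every pixel has completed its (possibly delayed) rise.

## Breath segmentation

Candidate extrema of the filtered global signal are forced to alternate
(minimum–maximum–minimum) and swings smaller than 10% of the robust cycle
amplitude (5th–95th percentile span after running-median detrending) are
pruned, so residual artifact is never counted as breaths. Each breath spans
onset to next onset; partial edge cycles are discarded. EELI is the cycle
minimum, reported relative to a pre-compression baseline epoch, since EIT
is a relative measurement — only referenced EELI values are meaningful.

Compression windows can be taken from annotations or detected: short-time
spectral power in the 1.4–2.0 Hz band, an adaptive threshold
(median + 6 MAD of the quiescent lower half of window powers), a
band-power-fraction gate (≥10% of window power in band, which respiratory
harmonic leakage never reaches), and half-power boundary refinement, with
bouts merged across gaps under 2 s.

## The indexes

For each breath, from the filtered frames:

* **VT\_EIT** — global tidal impedance change (a.u.).
* **A/P ratio** — anterior-half over posterior-half sum of the pixel tidal
  map (row 1 is anterior; boundary at the grid midline). The image is
  partitioned into these two regions of interest; finer partitions are a
  configuration choice (`boundary_row`). A non-positive posterior sum
  yields a missing value, never an infinity.
* **Pendelluft** — 100 × (sum of negative pixels) / net VT\_EIT, in
  %VT\_EIT, ≤ 0. Computed from the global-breath tidal map by default
  (a per-pixel-extrema variant exists for sensitivity analysis); values
  below −100 are flagged, not clamped.
* **RVD / SDRVD** — per pixel, the time to reach 40% of the pixel's
  excursion within the inflation window, linearly interpolated,
  as % of inflation time; pixels with non-positive tidal change are
  excluded. SDRVD is the population SD over included pixels.
* **GII** — Σ|DI − median(DI)| / ΣDI over lung pixels of the tidal map:
  0 for homogeneous ventilation, scale-invariant.
* **EELI/VT\_EIT** — mean over the last three breaths of the epoch of
  (EELI − baseline reference) / VT\_EIT. Baseline breaths must end before
  the compressions start; a cycle straddling the compression onset is
  already contaminated by the drift.

Per-epoch aggregation uses the median of per-breath values over the 60-s
analysis window (10 cycles), attributing breaths to epochs by onset time.

## Respiratory mechanics

From 200-Hz flow, airway pressure (Paw) and esophageal pressure (Pes)
under volume-controlled ventilation, per breath: VT = ∫ inspiratory flow
(trapezoidal, window flanked by one sample each side); plateau pressures
over the final third of the end-inspiratory pause; end-expiratory
pressures over the final 200 ms before inspiration. Then
C\_rs = VT/ΔPaw, C\_cw = VT/ΔPes, and C\_lung = VT/Δ(Paw − Pes)
(transpulmonary partitioning). Elastances add: 1/C\_rs = 1/C\_lung +
1/C\_cw. Breaths without a usable pause, or overlapping compression
windows, are flagged and skipped — compliance is only meaningful in
compression-free time. Flow is lightly running-median smoothed (~125 ms)
for threshold detection only, and candidate inspirations must be sustained
(≥50 ms) and reach half of peak flow; pressures are never smoothed.
Esophageal-balloon cardiac oscillations are not modelled: the scope is
noiseless-to-moderate-noise synthetic validation, with the plateau and
end-expiration sampling rules exposed as arguments because automated
plateau detection conventions differ between laboratories.

## Statistics

Each index is compared across inclinations with a linear mixed model:
inclination (flat reference) as categorical fixed effect, a per-subject
random intercept, REML estimation, and Wald t-tests with within-subject
denominator degrees of freedom (for the balanced 7-subject × 3-level
design this gives 12 df, and the test is exact under normality — the
Monte-Carlo calibration in the test suite confirms the 5% size). On
degenerate data (zero between-subject or residual variance) the fit
degrades to a fixed-effects-only linear model with a flag rather than
failing. Before/after-compression contrasts use the same machinery with a
phase fixed effect on per-subject means. No multiplicity correction is
applied across indexes or sequences: tests are reported per sequence,
unadjusted, and should be read descriptively. Summaries are median
(1st–3rd quartile) with the linear-interpolation quartile convention
(R type 7).

```{r stats}
d <- expand.grid(subject = 1:7, inclination = c(0, 18, 35))
set.seed(1)
d$vt <- rnorm(7, 5000, 800)[d$subject] *
  ifelse(d$inclination == 35, 0.55, 1) + rnorm(21, 0, 150)
fit_inclination_model(d, "vt")
```

## What the generator does and does not emulate

The generator reproduces the *measurement situation*: waveform morphology,
artifact spectrum, baseline drift, anterior-dominant distribution,
antiphase pixels, inflation delays, protocol structure (5 sequences ×
3 inclinations with compression windows), and single-compartment
mechanics. It does not emulate electrode-contact changes during elevation,
cardiac-oscillation artifacts on the esophageal or impedance signals,
reconstruction artifacts of any particular device, non-linear
(recruitment/overdistension) mechanics, or hemodynamics. Passing recovery
tests therefore demonstrates that the analysis chain is correct and
unbiased under the stated signal model — not that it is robust to every
failure mode of real electrode belts.

## Numerical choices and edge cases

* Seeded runs are bit-reproducible; per-subject seeds derive
  deterministically from the master seed.
* The frame grid (13.58 Hz) is incommensurate with the 6-s cycle: sampled
  extrema can sit a frame away from the continuous-time ones, and the
  near-flat expiratory tail can tie numerically; tests allow for exactly
  this discretization, nothing more.
* Flat plateaus in extremum detection are resolved to the first plateau
  sample; ties in the alternation-collapse keep the more extreme value.
* The RVD threshold crossing is linearly interpolated between frames, so a
  linear inflation yields exactly the threshold (40%).
* Degenerate inputs (empty masks, all-excluded delay maps, non-positive
  tidal sums, posterior sums ≤ 0) raise classed conditions
  (`eitcpr_invalid_argument`, `eitcpr_undefined`, `eitcpr_format_error`)
  or return flagged missing values, as documented per function.
* Problem sizes in the test suite: 16×16 or 32×32 grids, 20–96 s
  recordings, 20-seed recovery loops, 500-replicate calibration — chosen
  as the smallest sizes at which every recovery tolerance is meaningfully
  exercised.

## Known limitations

* The filter assumes the respiratory third harmonic stays below the
  compression fundamental; at respiratory rates above ~20/min with a
  102/min device the bands overlap and the filter refuses
  (`eitcpr_infeasible_filter`) rather than silently distorting.
* SDRVD is expressed in % of the inflation window; its absolute scale
  therefore depends on the end-inspiration convention (here: end of the
  hold). Comparisons across packages with different conventions need
  rescaling.
* EELI/VT\_EIT requires a clean pre-compression baseline; without one the
  reference falls back to the earliest breaths with a warning.
* The mixed model uses a single random intercept; serial correlation
  within a sequence beyond that is not modelled.
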