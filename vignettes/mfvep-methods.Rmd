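---
title: "Models and methods behind mfvep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mfvep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented in `mfvep`, the assumptions
they rest on, the parameters that matter and how their defaults were
chosen, and what the package's synthetic-data tests do and do not establish
about real recordings.

## 1. Stimulus design: m-sequences, thinning, time-lagged streams

A maximal-length binary sequence of degree $k$ (period $2^k-1$) has two
properties the multifocal method relies on: it is balanced
($2^{k-1}$ ones), and its $\pm1$-mapped periodic autocorrelation is the
constant $-1/(2^k-1)$ at every nonzero lag. `generate_msequence()` runs a
Fibonacci LFSR and *verifies* maximality by walking the full state cycle,
so a non-primitive feedback polynomial is reported with the period it
actually achieved rather than silently producing a short cycle.

The raw sequence pulses too fast for comfortable viewing at 40 frames/s, so
`thin_pulse_stream()` reduces the density in two passes: keep only the
first 1 of every run, then keep every second survivor. For a degree-11
period this yields exactly 256 of the original 1024 pulses — *provided* the
period is first rotated so that it begins at a run boundary
(`rotate_to_run_boundary()`); a linear scan of an arbitrary rotation can
split one cyclic run into two and return 257. Pass 2 keeps the odd-ranked
survivors; keeping the even-ranked set would be equally valid, and we fix
odd for reproducibility.

`design_pulse_train()` assembles 16 cyclic shifts (lag spacing
$\lfloor 2047/16\rfloor = 127$ frames — the design does not prescribe a lag
schedule, so we use the maximal uniform spacing) and concatenates 10
repetitions built from *distinct* primitive polynomials found by seeded
search. The defaults give 2560 events per location, a mean per-location
rate of 5.0 Hz, and an any-location event rate near 35 Hz.

One caveat discovered during development and worth stating plainly:
thinning makes the pulse spacing quasi-periodic (mean spacing ≈ 8 frames).
Its autocorrelation therefore has small structured peaks at spacing
multiples, and because all 16 streams are shifts of the same period, those
peaks alias into *between-stream* correlations at specific lags (up to
|r| ≈ 0.14 for a single period; ≈ 0.04 for the 10-repetition train with
distinct sequences). The between/within asymmetry that protects the
deconvolution is real and tested, but a naive $3/\sqrt{n}$ "chance bound"
on between-stream correlation does not hold exactly. The practical effect
is the small stimulus-onset artifact visible in deconvolved waveforms
(an order of magnitude smaller than the response), which the test suite
demonstrates and which users should expect in pre-stimulus baselines.

## 2. Forward model

The package replaces subject MRIs, boundary-element modeling and a
retinotopy atlas with a desk-scale analytic substitute; externally computed
prediction matrices can be supplied through `load_prediction_matrix()`, and
everything downstream is agnostic to their origin.

**Volume conductor.** Three concentric spherical shells (brain/skull/scalp,
default radii 80/85/92 mm; conductivities 0.33/0.0042/0.33 S/m — standard
literature values). The potential of a current dipole is expanded in
Legendre terms; in each shell the radial part is
$A r^n + B r^{-(n+1)}$, and the interface conditions (continuity of
potential and of radial current; zero radial current at the scalp) are
eliminated analytically into a per-order $2\times2$ transfer matrix. The
analytic elimination matters numerically: assembling one global linear
system becomes singular beyond order ≈ 150, while the transfer form is
stable at the series lengths needed for superficial sources. The series is
truncated when two consecutive terms contribute < 1e-8 relative to the
accumulated sum (no earlier than order 20); failure to converge within
`max_terms` is an error reporting the achieved residual. For equal
conductivities the gains reduce to the homogeneous-sphere factor
$(2n+1)/n$, and the test suite checks the full solution against the
closed-form homogeneous-sphere potential to < 0.1%.

**Synthetic retinotopy.** `retinotopic_patches()` places one small dipole
patch per (area, wedge) on a spherical "cortex", following qualitative
signatures of human visual cortex: contralateral projection, upper-field
wedges mapping below the calcarine level and vice versa; V1 sources on the
medial wall whose orientation flips with the field sign (so upper- and
lower-field topographies anti-correlate — the cruciform/C1-polarity
signature) and rotates from vertical at the horizontal meridian to
medial–lateral at the vertical meridian (so topographies lateralize towards
the vertical meridian, much more than V3's do); extrastriate areas with
progressively weaker field-sign dependence and more radial orientations.
The free orientation parameters of the extrastriate areas were set by a
seeded search minimizing the largest between-area correlation of the
stacked 2048-element regressors (final maximum |r| = 0.71), because
identifiability of the source regression hinges on the areas predicting
distinct retinotopic patterns; `build_prediction_matrix()` warns if any
pair exceeds |r| = 0.95. These patches are a *caricature* of real
retinotopy: adequate for exercising and validating the machinery, not a
model of any subject's cortex.

## 3. Preprocessing

The conditioning chain mirrors standard continuous-EEG practice for this
paradigm: a 77-tap Hann-windowed-sinc low-pass whose underlying sinc cutoff
is tuned by scalar search so the *measured* −3 dB corner lands on the
requested 35.3 Hz (the one-parameter design then measures ≈ 50 dB
attenuation at 50 Hz, which is reported, not asserted — corner frequency
and mains attenuation cannot be prescribed independently in this family);
zero-phase application by group-delay compensation, per recording block;
spherical-spline interpolation (order-4 Legendre smoothing, 50 terms) for
bad channels; average reference; and piecewise linear detrending of 0.5-s
segments, which removes slow drift without the waveform distortion of
high-pass filtering. Bad-channel *identification* is out of scope — labels
come from the user or the simulator.

Filtering, detrending and referencing are linear, so they commute with the
(linear) deconvolution estimator up to block-edge effects. Note that
piecewise detrending does remove genuine low-frequency energy *within*
segments; on a recording whose content is entirely evoked lobes this is
visible at the raw-signal level. The meaningful invariant lives at the
*deconvolved*-waveform level, where the suite verifies on noiseless
synthetic data that the low-pass stage alone changes waveforms by < 2% RMS
and the full chain (with detrending) by < 5%, with shape correlation above
0.998 — detrending's small in-band bite is the price of drift removal
without high-pass distortion.

## 4. Deconvolution by lagged regression

For each epoch lag $\tau$ (−100…400 ms at 512 Hz: 257 lags), each channel
is regressed on the 16 location impulse streams shifted by $\tau$, plus an
intercept. The coefficient of location $\ell$ at lag $\tau$ is the waveform
value. Because the design matrix and its per-lag normal equations depend
only on the pulse train and block structure, `deconv_design()` precomputes
and factors them once; estimating a recording is then a single sparse
cross-product plus 257 small solves.

Choices worth knowing:

- *Intercept.* Included for robustness to residual DC. With a generic
  design the OLS intercept equals the off-event mean of the recording, so
  exact recovery of injected kernels (to 1e-8) holds only when that mean is
  zero; the test oracles construct balanced designs with this property.
- *Block boundaries.* A shifted regressor that would cross a recording
  break is zeroed for that event, so no epoch mixes data across blocks.
- *Event placement.* Events map to the nearest EEG sample (12.8 samples
  per 25-ms frame), bounding placement jitter below 1 ms.
- *Per-lag vs joint.* The estimator fits each lag independently, which is
  exactly unbiased for designs with zero within-stream autocorrelation and
  carries the small onset artifact described in section 1 for thinned
  designs. A joint all-lag deconvolution would remove that artifact but is
  deliberately not the estimator here; the per-lag form is the method being
  modeled.

## 5. Component analytics

Global field power is the spatial standard deviation across channels of
the average-referenced field (population SD), per location or averaged.
Components are the three most prominent local GFP maxima between 50 and
300 ms, ordered by latency (C1/C2/C3), each with a 10-ms averaging window
(±5 ms) — matching the width used for the 80–90 ms SNR window; dips are
the GFP minima between consecutive peaks. Component "patterns" are the
window-averaged fields stacked over channels × locations (2048 elements),
and all component/component and component/area correlations are Pearson
correlations of such vectors. The dip-correlation group test Fisher-z
transforms per-participant correlations and reports one-sample and paired
tests as $F(1, n-1) = t^2$ — the construction is an interpretation (the
reference analysis does not spell out its F-test), and its type-I error is
verified by Monte-Carlo calibration in the test suite.

## 6. Retinotopically constrained source regression

Responses and regressors are converted to z-scores before regression: each
area regressor by its own mean/SD over its 2048 elements, the mVEP by the
mean/SD of the *full stacked epoch* (one shared pair of moments for every
window, so window-to-window amplitude differences survive
standardization). Windows are half-open $[t, t+10)$ ms sliding in 5-ms
steps over −100…400 ms (99 windows). Per window we fit each area alone
(reporting $R^2$) and the full 8-area model (reporting standardized betas
and $R^2$); the forward-selection path minimizes
$BIC = n\ln(RSS/n) + k\ln n$ with $n = 2048$ and $k$ counting all
coefficients including the intercept, anchored on the 80–90 ms window, and
always records all 8 steps with the BIC-optimal prefix flagged. The 2048
stacked elements are treated as exchangeable observations (no
spatial-correlation correction), mirroring the plain-regression character
of the method; bootstrap standard errors (resampling participants with
replacement, default 1000 replicates, seeded) are the SD of replicate
betas. Z-scoring each regressor by its own SD affects beta *scale* but not
$R^2$ or the selection order.

## 7. The synthetic-data generator

`simulate_study()` generates the study structure the analysis assumes:
13 participants (default), 128 channels at 512 Hz, 16 locations, 10
repetitions of the thinned train per condition, with each repetition a
separate recording block. The signal is the forward model run generatively:
area kernels convolved with each location's impulses, projected through the
area × wedge topographies, uniform activation within each patch.

- *Kernels* are sums of Gaussian lobes. Pulse: V1 triphasic with peaks at
  90/155/240 ms and alternating polarity, amplitude at least twice any
  extrastriate kernel; extrastriate lobes mixed in sign. Reversal: an
  extrastriate-first cascade (V2/V3 carrying the largest early weights,
  ±0.9/0.85) followed by a biphasic V1 response delayed by 50 ms, the whole
  condition scaled by 1/3.2. Peak latencies and the qualitative structure
  are anchored; lobe widths and exact amplitudes are invented documented
  defaults and must not be read as estimates of any real study's source
  amplitudes.
- *Participant effects*: one multiplicative gain (SD 20%) and one latency
  jitter (SD 5 ms) per participant — invented, typical-magnitude values.
- *Noise*: Gaussian, spatially correlated through the truncated eigenbasis
  (99.5% of trace) of a squared-exponential angular kernel over the scalp
  (length scale 0.6 rad), with an approximately 1/f ("pink") temporal
  spectrum from the standard cascaded first-order-section generator;
  default RMS 20 µV against evoked peaks of a few µV, i.e.
  realistic-magnitude raw-EEG SNR before deconvolution gain.
- *Determinism*: a master seed derives per-participant seeds; identical
  seeds give bit-identical recordings, and the manifest records every seed.

What passing the parameter-recovery tests shows: the pipeline correctly
unmixes overlapping responses, attributes them to the generating areas, and
resolves a 50-ms latency shift, under noise and participant variability of
plausible magnitude. What it does not show: robustness to forward-model
*mismatch* (the simulator and the fit share the same prediction matrix,
unlike any real study, which is why synthetic $R^2$ values are far higher
than published ones), to ocular or muscle artifacts, to bad-channel
misidentification, or to real cortical geometry.

## 8. Problem sizes used by the packaged studies

The packaged simulation studies run at a reduced scale chosen to keep the
full suite comfortably reproducible on a laptop: 6 participants and 2
repetitions per condition for end-to-end recovery (20 seeded replicates),
1000 Monte-Carlo replicates at n = 13 for the dip-test calibration, and
small montages for unit tests. The generator itself defaults to the full
13-participant, 10-repetition design; `simulate_study(reduce = ...)` keeps
memory flat by reducing each recording (e.g. straight to its deconvolved
estimate) as it is produced.

## 9. Known limitations

- The spherical head model and parametric retinotopy are stand-ins;
  real applications should import atlas-derived prediction matrices.
- Per-lag deconvolution inherits the thinning-induced onset artifact; the
  package documents it rather than removing it, because removing it would
  change the estimator under study.
- The dip-test F construction and the component-window width are
  reasonable interpretations where the reference analysis is silent; both
  are isolated behind small functions and easy to vary.
- Second-order (nonlinear) response kernels, single-trial estimation, and
  artifact rejection are out of scope.
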