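---
title: "Responder calling from calcium-imaging traces and BMC-based neurite-specificity classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Responder calling from calcium-imaging traces and BMC-based neurite-specificity classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcitox)
library(dplyr)
```

## The assay and its two quantitative cores

Functional screening of peripheral-neurotoxicant effects on iPSC-derived
sensory neurons rests on two measurements that this package implements as
a reproducible pipeline.

**Single-cell calcium responder calling.** Cultures loaded with the
calcium indicator Fluo-4 are imaged for 45 s per stimulus; the stimulus is
applied after a 10-s baseline. In a standard experiment four stimuli are
applied to one well in sequence, each in its own recording: a negative
control (HBSS), a P2X3-selective agonist (α,β-methylene ATP), a TRPV1
agonist (capsaicin) and KCl depolarisation. For each cell the response
statistic is

$$\Delta F = F_1 - F_0,$$

where $F_0$ is the ground-state fluorescence before stimulus application
and $F_1$ the peak fluorescence afterwards. Each well gets a noise-derived
threshold from its own negative-control recording,

$$\theta = \min\{\,\mathrm{mean}(\Delta F_{\mathrm{HBSS}}) +
3\,\mathrm{SD}(\Delta F_{\mathrm{HBSS}}),\; 18\,\},$$

and a cell is *reactive* to a stimulus iff $\Delta F_{\mathrm{stim}} >
\theta$ (strictly; $\Delta F = \theta$ is non-reactive). Treatment
endpoints are the responsive fraction per stimulus, expressed as % of the
untreated control, and the resting-baseline index: the mean per-cell $F_0$
of the negative-control recording as % of control, an index of resting
intracellular calcium.

**The two-endpoint benchmark-concentration prediction model.** Neurite
area and cell viability are measured as % of untreated control across a
concentration series. For each endpoint the benchmark concentration
BMC$_{25}$ — the concentration at which the fitted curve reaches 75% of
control — is estimated; with $X$ = BMC$_{25}$(neurite area) and $Y$ =
BMC$_{25}$(viability), an effect with $Y/X > 3$ is classified as
*neurite-specific*; $Y/X \le 3$ is *not neurite-specific* ("cytotoxic").
The inequality is strict: a ratio of exactly 3 is not neurite-specific.
Censoring is explicit: if viability never drops to 75% within the tested
range, $Y$ is reported as "BMC$_{25} >$ max tested" rather than imputed,
and a censored $Y$ with finite $X$ still classifies as neurite-specific,
while two censored endpoints classify as "no effect". Two further
per-compound landmarks are read off the fitted curves on the tested
concentration series: the lowest concentration with fitted viability
below 90% (cytotoxicity threshold) and the lowest with fitted neurite
area below 75% (neurite-effect threshold).

## Exact conventions of the ΔF statistic

Published descriptions of this workflow leave some details open; the
package fixes them as follows and treats them as part of its contract:

* **$F_0$ is the mean over all pre-stimulus frames** (`time_s <
  baseline_end_s`), not a single frame. Averaging the full 10-s baseline
  minimises noise in the ground-state estimate. At least 2 baseline
  frames are required.
* **The peak search is restricted to frames at or after stimulus
  application.** "ΔF upon stimulation" semantics: a baseline noise spike
  can therefore never define $F_1$. The frame at exactly the application
  time belongs to the post-stimulus window. Ties at the peak resolve to
  the earliest frame, for determinism.
* **ΔF may be negative.** No flooring at zero — the negative-control
  mean/SD would otherwise be biased upward.
* **Sample (n−1) SD** is used for the threshold; wells have few enough
  cells that the distinction matters.
* **One threshold per well**, derived from that well's HBSS recording and
  reused for all its subsequent stimuli.
* Cells present in the negative-control recording but missing from a
  stimulated recording are dropped with a warning.

Replicate aggregation follows the assay's hierarchy: technical-replicate
wells are averaged within each biological replicate (independent cell
preparation) first, and mean ± SEM are computed over biological
replicates only.

## What the synthetic-data generator emulates

No raw imaging data are publicly deposited for this assay, so the package
ships a seeded generator that reproduces the statistical structure the
analysis assumes, starting at per-cell traces (no pixel-level synthesis,
no segmentation):

* **Acquisition**: 45-s recordings, stimulus at 10 s. The true
  acquisition rate of the instrument is not published ("as fast as
  possible"); the default is 2 frames/s (90 frames), coarse enough to be
  fast at desk scale and fine enough to resolve the baseline window.
* **Response kernels**: minimal kinetic forms with the observed
  morphologies — a difference of exponentials
  $(1-e^{-t/\tau_r})e^{-t/\tau_d}$ for the transient, self-inactivating
  P2X3 response (decaying despite continued agonist presence), the same
  form with a long decay for TRPV1, and a saturating rise
  $1-e^{-t/\tau_r}$ for the sustained KCl plateau. Kernels are
  normalised to unit peak (analytically, at
  $t^\* = \tau_r\log(1+\tau_d/\tau_r)$ for the transient) so that the
  amplitude parameter is the expected peak ΔF of a responder.
* **Noise model**: iid Gaussian noise per frame on top of a per-cell
  resting baseline drawn log-normally across cells (arithmetic mean
  preserved), the simplest model under which the mean+3·SD threshold
  logic is meaningful. Fluorescence units are instrument-specific; the
  defaults (baseline mean 100 a.u., cell CV 0.2, noise SD 2 a.u.) place
  the negative-control threshold around 7–9 a.u., so the fixed 18 a.u.
  cap is a realistic upper guard rather than always-binding or never
  relevant.
* **Responder identity** is drawn per cell *per stimulus*: the same cell
  may respond to KCl but not to the P2X3 agonist, which is exactly the
  situation after selective P2X3 shutdown. Default untreated responder
  fractions: P2X3 0.8, TRPV1 0.7, KCl 0.9, negative control 0.
* **Treatment effects** act through two parameters: a per-stimulus
  multiplier on the responder fraction (0 silences a receptor class) and
  a multiplicative shift of the resting baseline. The named presets —
  `"PI-like"` (P2X3 multiplier 0, KCl/TRPV1 1, baseline shift 1.2) and
  `"taxol-like"` (all neutral) — are illustrative parameterisations of
  the proteasome-inhibitor-like and microtubule-stabiliser-like effect
  structures, not measured values.
* **Dose–response tables** are drawn around a declining four-parameter
  logistic with top = 100% and multiplicative Gaussian noise (default CV
  0.10), in the standard replicate hierarchy (3 technical × 3
  biological).

What passing tests on these simulations show — and do not show: they
verify the algorithms (thresholding, calling, aggregation, fitting,
inversion, classification) under data that satisfy the model's
assumptions. Real recordings add features the generator deliberately
omits: photobleaching trends, motion, correlated noise across cells,
non-Gaussian tails, partial responders and segmentation errors. Agreement
here therefore validates the computation, not the biology of any specific
compound.

## Seeding and determinism

A run derives one integer substream seed per well (and per recording)
from the master seed and the well identifier via a deterministic byte
hash, so results are independent of well insertion order and bit-identical
across reruns with the same configuration and seed. The RNG draws within
a recording occur in fixed order (baselines, responder identities,
amplitudes, frame noise). The pipeline report reproduces all numeric
fields exactly under a fixed seed; a test asserts this.

## Curve fitting and BMC numerics

The 4PL fit pins the top asymptote to 100 because the data are already
normalised to the untreated control; `bottom`, `ec50` and `hill_slope`
are estimated by bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`; bounds keep `ec50 > 0` and `hill_slope` in
[0.05, 20]) on biological-replicate means with uniform weights. When the
fit fails to converge the package falls back to a monotone (isotonic,
non-increasing) interpolation of the concentration means, flagged in the
result; BMC inversion then uses root finding on the interpolant instead
of the logistic closed form

$$\mathrm{BMC}_{f} = ec50\left(\frac{top - L}{L - bottom}\right)^{1/h},
\qquad L = 100\,(1-f).$$

The fitted mean at an uncensored BMC$_{25}$ equals 75% to within $10^{-6}$
relative tolerance (tested). BMC values are taken from the fitted curve,
not raw means — sparse series with replicate noise invert badly
otherwise. Confidence intervals on BMC are out of scope in this version.

## Worked example

```{r pipeline, eval = FALSE}
cfg <- default_run_config(seed = 42)
report <- run_pipeline(cfg)
report
```

The default configuration simulates three conditions (untreated,
`PI-like`, `taxol-like`) at 300 cells × 3 technical wells × 3 biological
replicates, calls responders, and fits/classifies two synthetic
concentration–response scenarios. Under the PI-like preset the report
shows the expected effect structure: P2X3 responsive fraction below 5% of
control with KCl and TRPV1 fractions near 100%, and a baseline index near
120% — selective silencing of one receptor class with mildly elevated
resting calcium — while the taxol-like preset leaves all endpoints near
100%. These are the problem sizes used throughout the test suite and the
acceptance script; they were chosen once as a realistic desk-scale
experiment (a 96-well plate column per condition) and are configurable.

```{r plots, eval = FALSE}
exp <- simulate_experiment(sim_config(seed = 1),
                           effects = list(effect_preset("untreated")))
plot_traces(exp$traces)          # per-cell traces by stimulus
fit <- fit_curve(simulate_dose_response(ec50 = 10, seed = 1))
autoplot(fit)                    # curve with 90% / 75% threshold lines
tidy(fit); glance(fit)
```

## Known limitations

* The exact fitting family and replicate handling behind published BMC
  values for this assay are not documented; published per-compound BMC
  tables are therefore not exact reproduction targets of this
  implementation, although the classification rule itself is.
* The ΔF threshold cap (18 a.u.) is in instrument-specific arbitrary
  units; with differently scaled data the cap and the simulator's
  amplitude/noise defaults must be rescaled together.
* The responder-calling false-positive rate under the mean+3·SD rule is
  not the Gaussian 0.13%: ΔF of a null cell is the maximum of many noise
  frames minus a baseline mean, a right-skewed statistic. Simulated null
  calibration at the defaults gives ≈0.5% — still well under the 1%
  design bound that the tests assert.
* No bleaching or motion correction, no kinetic fitting of transients,
  and no significance testing are provided; inputs are assumed to be
  clean per-cell traces and normalised endpoint tables.
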