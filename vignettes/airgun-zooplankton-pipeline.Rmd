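---
title: "Methods: sound metrics, vertical-distribution indicators, and mortality models for airgun exposure studies"
author: "zooseis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sound metrics, vertical-distribution indicators, and mortality models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zooseis)
```

# The problem

Seismic surveys discharge airgun arrays every few tens of metres along
survey lines, producing impulsive low-frequency sound (most energy below
~100 Hz). Whether that sound kills or displaces zooplankton is assessed in
the field with four kinds of measurement, each with its own computational
chain:

1. **Hydrophone recordings** near a stationary research vessel while the
   seismic vessel approaches from ~10 km, reduced to per-window broadband
   sound exposure level (SEL) and peak-to-peak pressure.
2. **Upward-looking echosounder backscatter**, echo-integrated into a
   depth-by-time grid of volume backscattering strength and summarized by
   vertical-distribution indicators — center of mass and inertia — which
   are then regressed on distance to the source.
3. **Photographs of net-caught zooplankton** treated with Neutral Red, a
   vital stain taken up by living tissue, classified live/dead by color
   thresholding.
4. **Bag exposure experiments** with cultured copepods at known distances,
   inspected daily for a week, analyzed with binomial generalized linear
   models, plus net-haul mortality analyzed with rank tests.

`zooseis` implements all four chains and a synthetic-data generator that
emulates each measurement with known ground truth, so every stage can be
validated end to end without field data.

# Sound metrics

A recording is calibrated from raw counts with the hydrophone sensitivity
magnitude $S$ (dB re 1 µPa per raw unit): one raw unit equals
$10^{S/20}$ µPa. This treats the data-sheet figure (e.g. "205 dB re 1
µPa") as the magnitude of a $-S$ dB re 1 V/µPa receiver, the standard
hydrophone convention.

For a window of pressure samples $p_i$ (µPa) at spacing $\Delta t$,

$$\mathrm{SEL} = 10\log_{10}\!\Big(\sum_i p_i^2\,\Delta t\Big)
\quad\text{dB re 1 µPa}^2\text{s},$$

and peak-to-peak pressure is $\max p - \min p$ (Pa). Windows are
contiguous, non-overlapping, rectangular (no taper), and start at the
recording start; the field protocol does not state alignment or tapering,
so the simplest partition is used and stated. Because the analysis window
(10 s) is shorter than the shot interval (~10.7 s), some windows contain
no shot; they carry the vessel noise floor and are retained.

Band-limiting to 10 Hz–20 kHz uses a forward–backward (zero-phase)
Butterworth cascade — a 2nd-order high-pass at the lower edge and a
4th-order low-pass at the upper edge, each applied with `filtfilt`, giving
effective orders 4 and 8. Zero-phase filtering was chosen so that
peak-to-peak pressure is not distorted by phase lag. Measured contracts:
mid-band (1 kHz) gain within 1%, 1 Hz attenuated by more than 20 dB, DC by
more than 40 dB. Peak-to-peak is computed on the band-limited series
(`p2p_on_filtered: true` in the configuration); offset invariance of p2p
therefore holds only after filtering, which the tests assert in that
order. A silent window returns `-Inf` SEL as a sentinel rather than an
error, so recording gaps survive a batch run.

# Vertical-distribution indicators

The echo-integration grid holds volume backscattering strength
$S_v$ (dB re 1 m$^{-1}$) on 2 m depth × 2 s time cells. All moments are
computed in the **linear** domain $s_v = 10^{S_v/10}$ — integrating energy
is the echo-integration convention — over unmasked cells:

$$\mathrm{CM} = \frac{\sum_i z_i\, s_{v,i}\,\Delta z}{\sum_i s_{v,i}\,\Delta z},
\qquad
I = \frac{\sum_i (z_i-\mathrm{CM})^2\, s_{v,i}\,\Delta z}{\sum_i s_{v,i}\,\Delta z},
\qquad
s_A = 4\pi \cdot 1852^2 \sum_i s_{v,i}\,\Delta z.$$

These are the standard Woillez-style moment indicators: CM is the
backscatter-weighted mean depth (m), inertia the weighted variance
(m$^2$), $s_A$ the nautical area scattering coefficient. Depth is positive
downward, bins half-open $[z, z+\Delta z)$ with centers reported. Inertia
is reported in m$^2$ — the dimensionally correct unit for a second moment
of depth — even though field reports sometimes print m$^{-2}$; the
discrepancy is noted rather than propagated.

Exclusions mirror field practice: cells shallower than the surface
exclusion depth (default 5 m; surface turbulence) and within 5 m of the
deepest bin (transducer near-field, mounted 5 m off the seafloor) are
masked. Masked values are retained under the mask. A time bin with no
positive unmasked backscatter yields `NA` indicators and is excluded from
fits, never imputed; an all-masked grid is an error.

The indicator regression is an ordinary least squares fit (Gaussian
identity GLM) of CM or inertia on distance as a continuous covariate, run
on per-time-bin records. Distance binning (1 km bins, half-open, up to
9 km) is provided for reporting only; fitting on bin means would discard
the within-bin sample size.

Numerical notes: column moments are computed as
$E[z^2]-\mathrm{CM}^2$ on vectorized columns and match a brute-force
double-loop oracle to $10^{-9}$ relative on random masked grids; a
point-sampled Gaussian layer at 2 m spacing recovers its variance
essentially exactly, while cell-integrated weights pick up the usual
$\Delta z^2/12$ discretization term — both behaviors are pinned by tests.

# Stain-based live/dead classification

Organisms are photographed dark-on-light (dishes lit from below).
Segmentation thresholds the gray intensity with Otsu's method and labels
8-connected components within area bounds. Otsu always splits *something*,
so a guard requires the between-class contrast to exceed four times the
within-class spread before any foreground is accepted; a blank frame with
sensor noise therefore yields zero detections. Touching organisms are not
split (no watershed): the field procedure counted by manual marking, and
oversized components are surfaced through the area filter for review.

A pixel is **stained** when its HSV coordinates fall in a circular red hue
window (default 330°–30°, wrapping through 0°) with saturation ≥ 0.45 and
value in [0.1, 1]. An organism's stain fraction is the fraction of its
pixels that are stained; it is called **live** when that fraction reaches
the `min_stain_frac` threshold (default 0.3; the ≥ boundary counts as
live). Hue/saturation-based decisions make the call invariant to uniform
brightness scaling within the value window, and raising the fraction
threshold can only convert live calls to dead (monotonicity), both tested.
The macro thresholds used in the field are not published, so all
thresholds are explicit per-batch configuration; the defaults were chosen
once on synthetic fixtures. The audit overlay (`stain_overlay`) paints
stained pixels vivid green, reproducing the field macro's visual check,
and the dead-control calibration path — a generated batch of known-dead
organisms — must yield at most 5% live calls at the defaults.

# Mortality statistics

Net-haul mortality uses two rank tests on the proportion dead, with
mid-ranks for ties and two-sided p-values throughout (α = 0.05, no
multiple-testing correction, matching the field analysis):

* **Spearman correlation** with distance, exhaustive-permutation p for
  n ≤ 9 and the t approximation above;
* **Mann–Whitney** between hauls taken during versus after exposure,
  exhaustive over all group assignments for total n ≤ 14 (tie-exact) and
  a tie-corrected normal approximation above.

The exact layers are authored here because small-sample tie-exact
p-values are the point; they agree with `cor.test`/`wilcox.test` on
tie-free data and with brute-force enumeration on tied fixtures.

Bag experiments are modelled with a logit-link binomial GLM on per-bag-day
(dead, alive) counts — the faithful binomial encoding when bags hold 10 or
50 individuals — with treatment, day (continuous by default; factor coding
available) and their interaction:
`cbind(dead, alive) ~ treatment * day`. The reference level is `control`.
The reported treatment p-value is the likelihood-ratio test of all
treatment terms against the day-only model; per-coefficient Wald contrasts
are also returned, and the **immediate** variant restricts to day 0 with
treatment as the only fixed effect. Complete separation (a treatment with
no deaths or no survivors) is detected and flagged with a warning: the
likelihood-ratio p remains usable while the affected Wald tests are not.

**A calibration caveat that matters.** The cumulative response at day $d$
(deaths through $d$ over $n_0$) is strongly correlated across days within
a bag, and the GLM treats bag-days as independent. Simulation at the field
design's sample sizes shows the cumulative model's treatment test rejects
a true null far above its nominal level (~60% at α = 0.05), purely from
this pseudo-replication. The package therefore calibrates the machinery
where its assumptions hold — the day-0 model on simulated null experiments
(day-0 counts are independent binomials; measured size ≈ 5–6%) and the
full interaction model on independent per-bag-day draws (≈ 4%) — and
documents that the cumulative model's p-values on real repeated-measures
data are anti-conservative. The model is nonetheless provided exactly as
printed in field analyses, with the repeated-measures limitation stated
rather than silently repaired.

`power_analysis` runs the design forward: it simulates the bag experiment
under a scenario, fits the model to each replicate, and reports the
fraction significant with a binomial standard error — size under a null
scenario, power under an effect scenario.

# The synthetic generators

The generators define the study conditions; they are first-class, tested
code, not fixtures.

* **Approach** (`approach_scenario`): the vessel closes from 10 km at
  2.315 m/s (4.5 knots), distance linear in time through the pass. Shots
  every 10.7 s. The observed ~10.7 s interval is not consistent with 50 m
  spacing at 4.5 knots (~21.6 s); `shot_interval` is deliberately an
  independent parameter and the tension is left unresolved. The pulse is
  an exponentially damped 60 Hz sinusoid (decay 0.05 s) — airgun energy is
  concentrated below ~100 Hz, and only SEL/p2p recovery is tested, so the
  exact waveform is a free choice. Per-shot SEL follows
  $\mathrm{SEL}(r) = \mathrm{SEL}_{1\,\mathrm{m}} - 20\log_{10} r$
  (spherical spreading; absorption is negligible below 100 Hz within
  10 km). The default source level of 222 dB re 1 µPa²s at 1 m puts a
  ~100 m closest approach at ≈ 182 dB, the observed field maximum. Vessel
  noise is white Gaussian scaled so the expected SEL **within the analysis
  band** equals the 158 dB floor; the generator returns a shot log and a
  per-window expected-SEL table (noise energy plus nominal shot energies)
  as ground truth for recovery tests.
* **Layer** (`layer_scenario`): a Gaussian-in-depth scattering layer
  (default mean 25 m, sd 5 m, core −70 dB) in a 70 m column, gridded at
  2 m × 2 s with bins down to 5 m above the seafloor, multiplied by
  lognormal cell noise (sd 3 dB). A distance response shifts the mean by
  `cm_response_slope` m/km and the variance by `inertia_response_slope`
  m²/km; ground truth is the perturbed continuous-limit moments. The
  planted inertia slope used in validation, +2 m²/km, gives an 18 m²
  contrast across 9 km — comparable to the inertia range seen in field
  reports.
* **Mortality** (`mortality_scenario`): per bag, day-0 deaths are binomial
  with the immediate death probability $p_0$, and each survivor dies daily
  with hazard $h$ (geometric survival — daily inspection makes the hazard
  discrete), so expected cumulative mortality at day $d$ is
  $1-(1-p_0)(1-h)^d$. Default treatments follow the field design (12
  control, 18 handling-control, 9 far, 36 close bags of 10) with $h$
  calibrated so the day-7 expectations equal the observed means (25.1%,
  22.3%, 12.7%, 11.7%) given the observed immediate mortalities (5.4%
  close, 2.3% far). Immediate mortality of the two control groups is not
  reported in the field results; 2% was chosen once as a realistic
  handling baseline. Net hauls draw dead counts beta-binomially
  (intra-haul correlation 0.05, 100 individuals scored per haul) around a
  distance curve, defaulting to a flat 15% — natural non-predatory
  mortality is high and the field data showed no distance trend.
* **Images** (`image_scenario`): non-overlapping ellipses (rejection
  sampling, bounded retries) with red saturation drawn from
  class-conditional ranges — live 0.65–0.95, dead 0.05–0.25 (diffusive
  uptake only) — on a 0.92 background, with Gaussian pixel noise
  (sd 0.02).

All scenarios carry explicit seeds and touch no global RNG state;
identical seeds give identical output.

**What the generators do not emulate:** real airgun signatures (notional
source, ghosting, directivity), propagation beyond geometric spreading,
multi-species scattering layers, diel-migration dynamics unless scripted
via the time-varying layer functions, organism morphology beyond ellipses,
and optical artifacts (shadows, scale bars, debris). Passing recovery
tests on this synthetic world demonstrates that the *computational chain*
is correct and calibrated, not that field imagery or echograms of
arbitrary quality would be classified equally well.

# Pipeline and reproducibility

`run_config` gathers every scenario and analysis parameter with defaults
matching the field protocol (10 s windows over 10 Hz–20 kHz, 2 m × 2 s
grid, 5 m surface exclusion, 1 km bins to 9 km, α = 0.05); configs load
from YAML, and each stage derives its scenario seed from the master seed,
so a report is a pure function of its config. `simulate_dataset` writes a
complete dataset directory (WAV, CSVs, PNGs); `run_all` runs the stages
and writes `report.json` with the config embedded plus a markdown summary.
A thin command-line wrapper (`inst/cli/zooseis.R`) exposes `simulate` and
`run-all`; the R functions are the primary interface.

Validation problem sizes were chosen to keep a full check fast while
leaving no estimate power-starved: 120 s recordings at 44.1 kHz for
noise-floor recovery, full 9 km echograms (~1 944 time bins × 33 depth
bins) for indicator regressions, 100 seeded echogram runs for slope
recovery, 1 000 simulated experiments for GLM size, 200 bags of 50 per arm
for effect recovery, batches of 120 organisms for classifier accuracy, and
50 seeded end-to-end runs for the qualitative pattern check.

# Known limitations

* Windowed SEL assumes rectangular windows aligned to the recording
  start; shot-to-window association is out of scope (no per-shot SEL).
* The bag GLM does not model within-bag correlation of cumulative counts
  (see the calibration caveat above); a mixed-effects or cluster-robust
  extension would be the next step.
* Touching organisms segment as one region; counts are biased low in
  dense dishes unless dishes are prepared sparse, as in the field
  protocol.
* The echo chain starts from gridded Sv; raw-echogram processing
  (calibration, target separation) is upstream and out of scope.
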