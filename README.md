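# zooseis

Analysis pipeline for field studies of zooplankton around seismic airgun
surveys, for marine bioacousticians and quantitative ecologists. It covers
the four computational chains such a study needs, plus synthetic-data
generators that emulate each measurement with known ground truth:

* **Hydroacoustics** — calibrate hydrophone recordings (WAV), band-limit to
  10 Hz–20 kHz, and compute per-window broadband sound exposure level
  `SEL = 10·log10(Σ p² Δt)` (dB re 1 µPa²s) and peak-to-peak pressure,
  joined to the distance of the approaching source.
* **Echo indicators** — from a gridded volume-backscatter field
  Sv (dB re 1 m⁻¹), compute the vertical-distribution indicators in the
  linear domain sv = 10^(Sv/10):
  center of mass `CM = Σ z·sv·Δz / Σ sv·Δz`, inertia
  `I = Σ (z−CM)²·sv·Δz / Σ sv·Δz`, and the nautical area scattering
  coefficient `s_A = 4π·1852²·Σ sv·Δz`, then regress CM and I on source
  distance.
* **Stain imaging** — segment photographed zooplankton (dark organisms on a
  back-lit background), score the fraction of pixels inside a red HSV
  window (Neutral Red vital stain), and call each organism live or dead.
* **Mortality statistics** — Spearman and Mann–Whitney rank tests with
  exact small-sample permutation p-values, cumulative-mortality curves,
  binomial GLMs of per-bag-day (dead, alive) counts with a
  treatment × day interaction, and Monte-Carlo power analysis of the bag
  design.

The synthetic generators simulate a seismic vessel approaching from 10 km
at 4.5 knots firing every ~10.7 s over a 158 dB re 1 µPa²s vessel-noise
floor, a Gaussian scattering layer in a 70 m water column on a 2 m × 2 s
grid, bag exposure experiments with geometric daily survival, overdispersed
net hauls, and stained-organism photographs — each returning the planted
ground truth so recovery can be measured.

## Worked example

Simulate a full approach with an inertia response of +2 m² per km of
source distance planted in the scattering layer, and run the ecological
stages:

```r
library(zooseis)
cfg <- run_config(seed = 7, layer = list(inertia_response_slope = 2))
rep <- run_all(cfg, stages = c("echo", "mortality"))
print(rep)
```

```
# Pipeline run summary
seed: 7

## Vertical distribution
- CM slope 0.00463 m/km (p = 0.591); inertia slope 1.97 m^2/km (p = 4.97e-197); planted 0 / 2
## Mortality
- cumulative treatment p = 5.93e-51; immediate p = 0.0686; Spearman rho = -0.028 (p = 0.889); Mann-Whitney p = 0.681
```

Reading this: the layer's center of mass shows no distance trend (none was
planted; p = 0.59), while the planted spread response is recovered —
1.97 m²/km against a true 2 m²/km, strongly significant across ~1 900 time
bins. In the bag experiment the close-exposure treatment (expected day-7
mortality 25.1% vs 11.7% in handling controls) produces a clearly
significant cumulative treatment effect, while immediate (day-0) mortality
does not differ significantly, and the net hauls show neither a
mortality–distance correlation nor a during/after difference — the
qualitative pattern such field studies report.

Lower-level entry points do the same work piecewise: `gen_echogram()` →
`apply_exclusions()` → `indicators_by_time()` → `fit_indicator_glm()`, or
`calibrate()` → `bandlimit()` → `metrics_vs_distance()`. A thin CLI lives
at `inst/cli/zooseis.R` (`simulate`, `run-all`).

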