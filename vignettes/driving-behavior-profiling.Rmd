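---
title: "Profiling motorcyclist driving behavior from GPS speed logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling motorcyclist driving behavior from GPS speed logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motoprofile)
```

## The problem and the model

Naturalistic riding studies log a motorcycle's speed with a phone app at
roughly one reading per second and ask two questions of the trace: how
often does the rider accelerate or brake harshly, and how often do they
exceed the road's speed limit? `motoprofile` answers both with a two-stage
procedure: first *learn* what counts as harsh from the cohort's own
empirical distribution, then *classify* every sample against the learned
cut-offs and aggregate per-rider profiles.

The kinematic primitive is the per-interval acceleration between
consecutive readings,

$$a_i = \frac{(v_i - v_{i-1}) / 3.6}{t_i - t_{i-1}} \quad [\mathrm{m/s^2}],$$

with speeds in km/h and timestamps in seconds. No smoothing is applied by
default — the quantity of interest is exactly the per-second speed change —
and irregular gaps are handled by dividing by the actual `dt` rather than
assuming a 1 Hz cadence (app logs drift and drop samples).

Severity cut-offs come from the classic mean-plus-sigma construction. Let
$\bar{x}$ and $s$ be the sample mean and standard deviation (N−1
denominator) of the *positive* accelerations pooled over the cohort. Then

- normal: $a \le \bar{x} + s$,
- aggressive: $\bar{x} + s < a \le \bar{x} + 2s$,
- dangerous: $a > \bar{x} + 2s$.

The rationale is the Gaussian coverage identity
$\Pr(\mu - k\sigma \le X \le \mu + k\sigma) \approx 68.27\%,\ 95.45\%,\
99.73\%$ for $k = 1, 2, 3$ (`gaussian_coverage()` checks it empirically):
behavior within one sigma of the mean is the most frequent and is taken as
normal; the thinning tail between one and two sigma is aggressive; beyond
two sigma, dangerous. Only the upper half of the distribution defines
thresholds — values far *below* the mean reflect slow riding, not risk.
Braking is handled symmetrically on magnitudes: summarize $|a|$ over the
deceleration samples, derive $\bar{x} + ks$, negate, and read "more
negative is worse".

Speed readings are labeled against a road policy: at or below the posted
limit is normal ("over-speed" means strictly above), and readings above
`limit * dangerous_factor` form a dangerous tier.

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| `k1`, `k2` | — | 1, 2 | the one/two-sigma construction above; other domains use mean ± 2 s.d. for anomaly cuts, so both multipliers are exposed |
| `zero_eps` | m/s² | 0 | the zero band. App speeds are quantized, so consecutive equal readings give exact zeros; published cohort counts show only a handful of zero events per ~3000 samples, consistent with exact equality. Raise it for noisier sources |
| `limit` | km/h | 80 | the study road's posted limit |
| `dangerous_factor` | — | 1.25 | 100 km/h on an 80 km/h road. No dangerous-speed cut-off is published anywhere for the cohort; this is a package policy default, and no bundled-fixture test depends on it |
| `smooth_window` | samples | 1 (off) | optional centred moving average for noisy speed sources; off because the method is defined on plain differences |
| dialect `decimals` | — | 4 | the app's true printed precision is unknown; 4 decimals keeps the write→parse round trip below 10⁻⁴ mph of error |

Threshold modes: `pooled` (default) learns one set from all riders'
samples together — a cohort defines its own normality, and per-rider
thresholds would label every rider's own tail as abnormal regardless of how
harsh it is in absolute terms. `per-driver`, `preset` (two published
sets), and `frozen` (reuse a JSON-saved set across cohorts) are available.

## Boundary conventions and numerical choices

- Classification boundaries are closed on the *less severe* side:
  `a = t1` is normal, `a = t2` aggressive; `v = limit` is normal speed.
- The zero band is evaluated before the sign split, so `|a| <= zero_eps`
  is `zero` even when `zero_eps = 0` and `a` is exactly 0.
- Duplicate or backwards timestamps: first occurrence wins; later rows are
  dropped with reasons `duplicate_timestamp` / `non_monotonic_time`. Each
  dropped row gets exactly one primary reason, checked in the order
  empty → non-numeric → negative → duplicate → non-monotonic.
- Cleaning drops rows rather than imputing: the field practice for these
  logs is to remove noise, and imputation would manufacture kinematics.
- Unit conversions use the exact international definitions
  (1 mile = 1.609344 km, 1 ft = 0.3048 m), unrounded.
- `sdev = 0` (constant input) yields degenerate `t1 = t2` with a warning
  rather than an error; fewer than two values on either side of zero is an
  error, since no s.d. exists.
- Acceleration is attached to the interval-*ending* timestamp (either
  endpoint is defensible; the end is when the maneuver is observed).
- Internal arithmetic is full precision; table rendering is separate.
  Percent cells round half away from zero, falling back to one decimal
  only where whole-percent rounding would saturate to 0% or 100% for a
  non-extreme share (so 0.14% prints as 0.1% against a 99.9% complement,
  while 99.4% still prints as 99%).

## Two published preset threshold sets

The cohort study this package replays reports its acceleration cut-offs
twice, inconsistently: (1.3, 2.5) m/s² in its stepwise derivation and
(4.73, 7.48) m/s² in its conclusions. Both are shipped verbatim as presets
(`threshold_preset("methods")`, `threshold_preset("conclusions")`), both
with the braking pair (−6.01, −9.54); the package treats them as
dataset-dependent outputs and asserts nothing about which is correct. The
same source also prints its braking Step-5 ordering backwards (normal
≥ −9.54 yet dangerous < −6.01); only the conclusions' ordering (normal
≥ −6.01, dangerous < −9.54) is consistent with the mean+σ < mean+2σ
construction, so that ordering is implemented.

Similarly, replaying the published per-driver counts reproduces the
published ratio table at its printed precision except for three cells
whose final digits contradict their own printed counts (two
normal-acceleration cells and one dangerous-acceleration cell); the
package reports the recomputed values. The published cohort speed-table
average row matches neither an average over the 15 printed riders nor over
16 (one rider's row is absent from that table), so only the ratio averages
— which do reproduce (over-speed 19%, normal 79%) — are asserted. The
published narrative's "88%" normal-share figure disagrees with its own
figure caption (89%); recomputation from the counts gives 89.2%, and the
package reports the computed value.

## What the synthetic generator emulates — and what it does not

`simulate_trip()` builds the *acceleration sequence first* and integrates
it into the speed trace. That ordering is the key design choice: because
speed is exactly the integral of the constructed accelerations, every
sample's ground-truth label (its "ledger" entry) is exact by construction,
and any disagreement with the pipeline is a pipeline defect, not
generator noise. Per sample the sequence is:

- Gaussian speed jitter (`speed_noise_sd`, default 0.5 km/h per step) —
  the quantization-and-GPS wobble of cruise riding;
- with probability `maneuver_rate`, an ordinary maneuver whose direction
  a controller picks to hold the cruise band (±`band` km/h around the
  target speed) and whose magnitude is drawn from the throttle or braking
  Gaussian burst model, rejecting non-positive draws (a magnitude must be
  positive);
- at seeded, non-overlapping random indices, injected severe events with
  magnitudes uniform in a range validated against the active threshold
  set, so their labels are unambiguous;
- over-speed segments, during which the controller targets a
  higher-than-limit speed.

Integration clips at standstill; a clipped step is re-zeroed in both trace
and ledger so they stay consistent. Defaults emulate the study conditions
the generator stands in for: 1200 s trips at 1 Hz (so a trip holds
`duration/dt` readings and one fewer kinematic samples), cruising at
60 km/h under an 80 km/h limit, 16 riders × 3 trips in
`cohort_trip_specs()`, with per-(rider, trip) sub-seeds derived
deterministically from one master seed.

One statistical subtlety: when a burst model has appreciable mass below
zero (say N(0.5, 0.3), 4.8% negative), rejection makes the realized
magnitude population the >0-truncated Gaussian, whose mean+s.d. differs
slightly from the nominal μ+σ. The threshold-recovery tests therefore use
a burst model with negligible negative mass, N(1.2, 0.25), for which the
learned cut-offs converge to μ+σ and μ+2σ cleanly; recovery against a
heavier-tailed model should be compared to the truncated distribution's
moments, not the nominal ones.

What the generator does **not** emulate: GPS position noise and multipath
(the track is a smooth dead-reckoned line, for format completeness only),
multi-second maneuvers (injected events occupy single samples, matching
per-sample event counting), speed quantization to the app's display
precision, rider heterogeneity beyond seed differences, and road grade.
Passing tests on synthetic cohorts therefore validate the *pipeline
mechanics and estimators*, not the field realism of any particular
threshold value.

## Test problem sizes

The suite replays the full published tables exactly (16 riders, 53,141
samples, at desk scale); stochastic checks use 10⁵ standard-normal draws
for the coverage identities and, for threshold recovery, 20 replicates of
a 16-rider cohort at two pooled sizes (~400 vs ~6,400 samples, a 16-fold
ratio) to confirm the error shrinks at the 1/√n rate, with the
mean learned cut-off within three replicate standard errors of μ+σ and
μ+2σ. Ledger-agreement checks push ~16 trips through the full
write → parse → clean → derive → classify path and compare every sample
whose true acceleration is more than 10⁻³ m/s² from any threshold
boundary (the 4-decimal log precision perturbs accelerations by at most
~5 × 10⁻⁵ m/s²).

## Known limitations

- Thresholds are mean ± kσ only; no robust (median/MAD) or quantile
  alternatives, and no normality test of the empirical distribution — the
  construction is used as a convention, not a verified model.
- Consecutive severe samples are counted individually, not merged into
  maneuvers; counts are therefore cadence-dependent.
- Speed is taken as the app reports it; no re-derivation from positions,
  no map matching, and the BD09 coordinates are parsed but never used.
- The over-speed analysis assumes a single posted limit per cohort run.
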