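---
title: "Models and methods behind posturelab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind posturelab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

posturelab analyses standing-balance experiments on a tilting support
surface: it generates the pseudo-random ternary tilt stimulus, calibrates
whole-body centre-of-mass (COM) sway from sway-rod and centre-of-pressure
(COP) signals, reduces each trial to scalar sway outcomes, and tests
condition effects with a within-subject ANOVA. A closed-loop stander
simulator provides synthetic raw data with the statistical structure the
pipeline assumes, so every stage can be exercised and validated without
laboratory recordings. This vignette documents the models, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic data can and cannot establish.

## The tilt stimulus (PRTS)

The support-surface stimulus is a pseudo-random ternary sequence: a
maximal-length sequence over GF(3) produced by a linear feedback shift
register with `stages = 4`, giving a period of $3^4 - 1 = 80$ symbols. Each
symbol becomes a 0.25-s velocity state at $+v$, $0$ or $-v$ with
$v = 1.78$°/s; the platform tilt is the time integral, a piecewise-linear
trace. One cycle lasts 20 s; thirteen cycles are concatenated into a 260-s
trial. Over one period each nonzero symbol occurs 27 times and the zero
symbol 26 times, so with the two nonzero symbols mapped to opposite signs
the velocity integral closes exactly and concatenated cycles join without
discontinuity.

Neither the feedback polynomial nor the symbol mapping of the original
stimulus is published, only its geometry. `prts_stimulus()` therefore
searches the eight primitive 4-stage tap sets in a fixed lexicographic
order, with the canonical initial state $(0,0,0,1)$ and the canonical
balanced mapping $0\to0, 1\to+1, 2\to-1$, and ships the first configuration
whose cumulative-sum range is 9 state units. The realisable peak-to-peak
amplitudes are $\text{range} \times 1.78 \times 0.25 = \text{range} \times
0.445$° with integer range (9 or 11 across the primitive sets), so the
closest realisable value to the published 4° is $4.005$° — exact agreement
is impossible on this grid, a point the stimulus metadata makes auditable
(taps, initial state, mapping, range, amplitude, and whether the amplitude
came from the sequence search or explicit taps).

## COM calibration

During a quasi-static calibration motion (very slow ankle and hip
movements), the COP — ankle torque divided by body weight — tracks the COM
projection. Regressing COP jointly on the hip and shoulder sway-rod
translations gives coefficients $(a, b, c)$ such that

$$x_{com}(t) = a + b\,x_{hip}(t) + c\,x_{sho}(t),$$

which then converts sway-rod signals into COM position in dynamic trials
where the COP no longer tracks the COM. The angular sway used everywhere
downstream is $\theta_{com} = \arcsin(x_{com}/h_{com})$ in degrees.

Numerical choices: the fit is ordinary least squares on both predictors
jointly (the one-at-a-time reading of the regression is not implemented); a
condition-number guard (default $10^8$ on the standardised design) rejects
collinear rod signals instead of returning an unstable fit; negative
segment weights trigger a warning, not an error, since they are physically
implausible but numerically legitimate. The COM height $h_{com}$ is a
required per-subject input; `h_com_default()` provides a coarse
0.55 × body-height approximation, flagged as such, for when no
anthropometric estimate exists.

## Sway metrics

For quiet-stance and sway-referenced segments, the COM angle trace is
low-pass filtered (2nd-order Butterworth, 5 Hz cutoff), the first 15 s are
discarded, and the mean sway velocity over the following 30-s window is the
sway path $\sum_t |\Delta\theta|$ divided by the window duration. The
filter is applied forward and backward so it has exactly zero phase: a
causal pass would delay the trace without consequence, but any residual
phase distortion would inflate the rectified path sum. The price is that
the effective attenuation is the squared Butterworth response (effective
order 4); this is documented rather than compensated. The window is
half-open in samples: samples strictly before `discard × rate` are dropped.

For tilt trials the 260-s trace is cut into its thirteen 20-s stimulus
cycles; the first cycle is discarded (stimulus-onset transient), each
retained cycle is centred on its own mean, and the pointwise mean and
sample standard deviation (n−1 denominator, switchable) across the twelve
retained cycles give the periodic component (stimulus-evoked sway) and the
random component (sway not evoked by the stimulus). Sway power of either
component is the raw sum of squares, with no normalisation by length — the
natural units are deg²·samples. Whether the 5-Hz low-pass was also applied
before decomposition is not stated in the source analysis; posturelab
defaults to not filtering tilt trials and exposes `filter_tilt` to switch.

## The repeated-measures ANOVA

Outcomes form a balanced subject × visual (EO, LAB, ABS, EC) × platform
table, where the "platform" factor levels are four outcome parameters: sway
velocity on the fixed surface, sway velocity under sway referencing, and
periodic and random tilt-response power. These have different units, so by
default each platform-level column is z-scored before the combined ANOVA
(`normalization = "zscore"`, with `"log"` and `"raw"` alternatives). A
consequence worth stating plainly: z-scoring forces every platform-level
mean to zero, so the platform *main effect* in the combined ANOVA is
identically zero by construction — only the visual effect and the
interaction are meaningful there. Per-platform one-way ANOVAs
(`single_level_posthoc()`) are unaffected.

The decomposition is the classical univariate within-subject one: each
effect is tested against its own subject-by-effect stratum,
$F = MS_{effect}/MS_{subject \times effect}$, with
$df = (n-1) \times df_{effect}$; for 9 subjects and 4×4 factors this gives
the familiar (3, 24), (3, 24) and (9, 72) df triples. Effect size is
$\eta^2 = SS_{effect}/SS_{total}$ with the between-subject stratum included
in the total. No sphericity correction is applied by default (none was
applied in the analysis this mirrors); Greenhouse–Geisser is available
behind `gg_correction = TRUE`. Simple contrasts compare each visual level
against the eyes-open reference: the estimate is the mean per-subject
difference averaged over the other factor, and the standard error is pooled
from the factor's error stratum on subject-level means,
$SE = \sqrt{2\,MS_{err}/n}$ — identical across comparisons, equal to the
paired t-test for a two-level factor, and unadjusted for multiple testing.
Subject exclusion is an explicit input list only; nothing is dropped
automatically.

## The synthetic stander

The simulator is a deliberately simple stand-in, not a validated
physiological model: a single-link inverted pendulum in the sagittal plane,

$$J\ddot\theta = mgh\,\theta - T(t), \qquad
T(t) = K_p e(t-\tau) + K_d \dot e(t-\tau) + n(t),$$

with a weighted sensory error
$e = w_{prop}(\theta_{leg} - \theta_{platform}) + (w_{vis}+w_{vest})\theta$.
The proprioceptive cue is the ankle angle (leg tilt minus platform tilt);
vision and the vestibular system both sense body-in-space orientation.
Per visual condition $w_{vis}$ is EO 0.35, LAB 0.33, ABS 0.15, EC 0, with
$w_{vest} = 0.35$ and $w_{prop} = 1 - w_{vis} - w_{vest}$, so the weights
always sum to one. Closing the eyes or sway-referencing the platform
removes feedback gain, and the torque noise — white noise low-passed at
0.5 Hz, SD 9 N·m — then drives larger sway. That single mechanism
reproduces the qualitative experimental pattern (EO ≈ LAB < ABS < EC;
sway-referenced > fixed; tilt-evoked periodic power growing with
$w_{prop}$) without any per-condition tuning.

Parameter defaults and why:

* **Body**: 75 kg, 1.75 m; segment fractions give readout coefficients
  $b = 0.584$, $c = 0.272$ and $h_{com} = 0.89$ m; $J = 1.2\,mh_{com}^2$.
* **Gains**: $K_p = 2800$ N·m/rad, $K_d = 700$ N·m·s/rad, delay
  $\tau = 100$ ms. Chosen by a phase-margin analysis of the delayed loop:
  the effective loop weight spans 0.35 (EC, sway-referenced) to ~0.95 (EO,
  fixed), and these gains keep ≳12° of phase margin across that whole range
  including ±10% per-subject jitter. $K_p$ must exceed $mgh/0.35 \approx
  1900$ N·m/rad for static stability in the weakest condition.
* **Servo**: the sway-referencing platform follows the leg tilt through a
  first-order lag; the default time constant is 0 (perfect tracking, the
  stated tuning goal of sway referencing). A nonzero lag feeds a
  high-passed proprioceptive term into the delayed PD loop and can
  destabilise the low-gain conditions, which is why the lag is a
  configurable stand-in rather than the default.
* **Noise**: SD 9 N·m puts the EO fixed-surface sway velocity near
  0.2 deg/s, inside the physiological 0.1–0.5 deg/s range.
* **Readout**: leg tilt is $0.8\,\theta$ plus an independent slow
  "hip-strategy" wiggle (SD 0.3°, 0.3 Hz low-passed) so the hip and
  shoulder channels are linearly independent; shoulder translation is then
  solved so that $x_{com} = b\,x_{hip} + c\,x_{sho}$ holds exactly.
* **Integration**: fixed-step classical RK4 at 1000 Hz with the delayed
  torque held constant within a step; the delay is a sample ring buffer.
  A trial aborts with an explicit "fall" error if $|\theta|$ exceeds 10°.
* **Subjects**: `generate_study()` jitters anthropometrics, gains, noise
  and visual weights multiplicatively by ±10% (uniform), with gains scaled
  to body size first ($K_p \sim mh$, $K_d \sim mh^2$) so the jitter moves
  the stability margin, not the body-to-gain mismatch. EC keeps
  $w_{vis} = 0$ exactly. Everything is a pure function of (config, seed).

The calibration routine is simulated as *prescribed* slow sinusoidal ankle
and hip movements (0.02 and 0.035 Hz, incommensurate, seed-jittered phases
and amplitudes) with the torque channel from single-pendulum inverse
dynamics, $T = mg\,x_{com} - J\ddot\theta_{com}$. The COP–COM discrepancy
is the inertial term, which scales with movement frequency squared: at
calibration frequencies it is below 1% of the sway range, and an order of
magnitude larger in dynamic trials — exactly the regime separation the
calibration method relies on.

What a green end-to-end test establishes: that the pipeline's arithmetic
(stimulus geometry, calibration regression, metric definitions, ANOVA
decomposition) is correct, and that the analysis detects the direction of
condition effects that the generator plants. What it does not establish:
anything about real postural control — the simulator has no medio-lateral
dynamics, no nonlinear reweighting, no multi-link coordination beyond a
kinematic readout, and its parameter values are tuning choices, not
physiological estimates. Numeric reproduction of the original group-level
F values and contrast estimates is out of reach by design: those depend on
the human sample and on an outcome normalisation the source does not state.

## Known limitations

* The combined ANOVA's platform main effect is degenerate under the default
  z-score normalisation (see above).
* Zero-phase filtering doubles the effective filter order relative to a
  single causal pass.
* The sway-velocity/window bookkeeping assumes the sampling grid divides
  the discard and window durations exactly; the sum over a finite grid is
  (n−1)/n of the continuum total variation, visible only in contrived
  exact-closed-form comparisons.
* The simulator's fall error is a feature for detecting unstable
  configurations, but it means extreme custom configurations (very low
  gains, very high noise) end trials with an error rather than data.
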