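---
title: "Identifying heart-rate dynamics from paired exercise tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying heart-rate dynamics from paired exercise tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrsysid)
```

## The problem

Heart rate responds to a change in exercise intensity with several
superimposed dynamic modes: a fast component that follows the workload
after a short transport delay, and a much slower, low-amplitude drift.
Feedback control of exercise intensity — and any quantitative description
of cardiovascular response — needs a dynamic model of this map from
intensity (treadmill speed in m/s, or cycle-ergometer work rate in W) to
heart rate (bpm). `hrsysid` implements the full identification analysis
for this setting: candidate model structures, exact simulation, bounded
least-squares estimation, an NRMSE fit metric with counterbalanced
cross-validation over a subject's two replicate tests, and a comparison
pipeline that ranks structures by how well they predict the *other* test
of each pair.

## Model family

All candidates are continuous-time transfer functions. The general
single-branch form has up to two poles, a zero and a dead time,

$$P_o(s) = k\,\frac{T_z s + 1}{(\tau_1 s + 1)(\tau_2 s + 1)}\,e^{-T_d s},$$

and is constrained to six named structures (P1, P1D, P2, P2D, P2Z, P2ZD)
by zeroing subsets of $\{\tau_2, T_z, T_d\}$. The seventh candidate is the
parallel connection of two first-order branches, one delayed and one not,

$$P_o(s) = \frac{k_{p1}}{\tau_{p1} s + 1}
         + \frac{k_{p2}}{\tau_{p2} s + 1}\,e^{-T_d s},$$

which mirrors the classical two-phase picture of heart-rate kinetics: an
undelayed slow mode and a delayed fast mode. Gains are in bpm per input
unit; $\tau$'s, $T_z$ and $T_d$ in seconds. $T_z$ may be negative
(initially inverse response); time constants and the dead time are
non-negative.

```{r}
model_structures()
```

## Exact simulation under zero-order hold

Measured inputs are sampled every 5 s and treated as held constant between
samples. The simulator decomposes each rational block into decoupled
first-order modes (partial fractions; an analytic Jordan pair when the two
poles coincide within a relative tie tolerance of $10^{-9}$; a direct
feedthrough term when a pole degenerates to zero), and propagates the
modal states *exactly* — scalar exponentials, `expm1` for small exponents —
across every sub-interval on which the delayed input is constant. The
sub-interval boundaries are the union of the sample instants and the
delayed switch times, so a dead time that is not a multiple of the 5 s
sample period introduces no discretization error; the response is reported
at the sample instants only. The zero $T_z$ enters through the residues,
never by differentiating sampled data. Degenerate configurations (both
time constants zero) collapse to a delayed static gain and still simulate
correctly.

```{r}
m <- make_model("P1D", list(k = 25.0, tau1 = 47.7, Td = 13.1))
step_response(m, 1, horizon = 60)  # 1 m/s step: delay, then first-order rise
```

## Preprocessing: deviations, transients, trends

Estimation works on deviations around mean levels. The default profile
(`preprocess_config()`: center only) mirrors the primary analysis; a
stricter profile with `skip_initial = 300` discards the first five
minutes, which covers initial heart-rate drifts with time constants in the
140–180 s range, and `detrend = TRUE` removes a least-squares straight
line (the package's own choice of detrending method). The pipeline always
trims first and centers afterwards, so means are computed over the
retained evaluation period.

## Estimation and the fit metric

For a structure with free parameters $\theta$, `fit_model()` minimises
$\sum_i (y_i - \hat y_i(\theta))^2$ by Levenberg–Marquardt under box
constraints, from 10 starting points: the mid-range point plus seeded
draws, log-uniform for time constants and dead time (whose scales span
decades), uniform for gains and $T_z$. Dead time is a continuous decision
variable inside the search — not a grid over whole samples — and the
multi-start mitigates the local minima this creates. The default bounds
("physiologically plausible ranges", all overridable) are: $\tau \in [1,
600]$ s, $T_d \in [0, 60]$ s, $T_z \in [-120, 120]$ s, gains $[0, 100]$
bpm/(m/s) for treadmill or $[0, 2]$ bpm/W for ergometer. Convergence
tolerance is $10^{-10}$ on the objective, at most 500 iterations per
start; the seed is recorded in the result. Exchangeable pole pairs are
reported canonically with $\tau_1 \le \tau_2$.

Goodness of fit is the NRMSE fit in percent,

$$\mathrm{fit} = 100\left(1 -
  \frac{\lVert y - y_{sim}\rVert_2}{\lVert y - \bar y\rVert_2}\right),$$

with 100 % a perfect reproduction, 0 % no better than the mean heart rate,
and negative values possible. A sum-of-squares variant (no square root) is
available via `fit_options(fit_variant = "ss")`.

### Handling the operating-point offset

Centering $y$ by its arithmetic mean cannot remove the operating-point
offset exactly: the mean of the model's own start-up transient survives
it, and with a zero-state simulation this constant would contaminate every
residual (several fit points, and strong bias on weakly identified
parameters such as $T_z$ or a slow branch's gain). The package therefore
compares the measured deviations against the simulated output's *own*
deviations around its mean over the evaluation period — algebraically
equivalent to concentrating a single free offset out of the least-squares
problem. This is the package's convention, on by default and switchable
off (`fit_options(center_sim = FALSE)`); with it, a noise-free generated
record is explained with fit = 100 % and all parameters are recovered to
machine precision. Initial conditions are otherwise taken as zero
(deviation-form data from rest); the preprocessing stage, not the
optimizer, is the intended tool for removing transients.

### Counterbalanced cross-validation

`cross_validate()` estimates the structure separately on each of a
subject's two replicate tests and scores each model against the *other*
test (zero initial state on the validation record). Downstream tables
report these validation fits; estimation fits are kept alongside, because
their divergence — validation falling below estimation — is precisely the
overfitting signal that structures with a free zero tend to show.

## The synthetic-data generator

`generate_cohort()` emulates the paired open-loop experiments so that the
whole chain is testable without any data download:

* **Excitation** — a pseudo-random binary sequence: a maximal-length LFSR
  (orders 3–16, standard taps, seed-selected non-zero initial state)
  mapped to two intensity levels and held per clock tick. Defaults: clock
  period 30 s, register length 7, duration 1800 s, so the excitation
  bandwidth brackets response time constants of roughly 30–180 s. The
  original studies' PRBS designs are not published; these are declared
  emulation choices, as are the intensity levels (1.6–2.4 m/s treadmill,
  75–125 W ergometer) and mean heart-rate levels (140 / 120 bpm).
* **Truth** — the parallel two-branch model, centred per modality on
  nominal values typical of healthy adults (treadmill: fast branch 20.2 bpm/(m/s), 34.3 s,
  delay 17.9 s; drift branch 7.0 bpm/(m/s), 141.5 s; ergometer: 0.35
  bpm/W, 37.9 s, 17.1 s; 0.09 bpm/W, 180.7 s), with independent ±20 %
  uniform jitter per subject. Drift is the slow *input-driven* branch, not
  an exogenous ramp (an optional bpm/min ramp exists to stress the
  detrending stage). Truths always lie inside the default bounds, keeping
  recovery well-posed.
* **Noise** — white Gaussian at the 5 s sample level, default SD 2 bpm,
  seeded per (subject, test) so a pair shares its truth and excitation but
  not its noise.

What the generator does *not* emulate: autocorrelated heart-rate
variability, breathing artefacts, above-threshold nonlinear drift, or
device dropouts. Passing recovery tests therefore demonstrate correctness
of the estimation machinery under the model's own assumptions, not
robustness to real-data pathologies.

## The comparison pipeline

```{r, eval = FALSE}
res <- run_synthetic_study("TM", n_subjects = 11, seed = 1)
res$table     # mean validation fit per structure
res$summary   # mean parameter estimates, parallel form as two branch rows
score_recovery(res, attr(res, "truth"))
```

`run_comparison()` preprocesses every pair, fits all seven structures to
each record, cross-validates within pairs, and averages validation fits
over all records of a modality (both cross-validation directions, one fit
per record — 22 values for an 11-subject cohort). Failed fits are
recorded and excluded from means with per-cell counts, never silently
imputed. Per-cell random seeds derive from the base seed and the pair and
structure indices, so results are independent of evaluation order, and
`write_report()` saves a run manifest from which `rerun_manifest()`
reproduces the output tables byte for byte.

## Numerical choices and problem sizes

* Tie tolerance for repeated poles: $|\tau_1-\tau_2| <
  10^{-9}\max(\tau_1,\tau_2)$; event-grid merge tolerance $10^{-9} h$.
* Time grids are validated against `sample_period` at $10^{-6} h$ on read.
* The test suite validates the simulator against closed-form step
  responses (all seven structures, relative error below $10^{-6}$) and
  against an independent companion-form state-space oracle propagated on a
  100-fold oversampled grid (20 random PRBS cases, relative RMS below
  $10^{-4}$).
* Recovery experiments use single 1800 s records at 5 s sampling
  (360 samples), 20 Monte-Carlo pairs for the noisy case, and an
  11-subject cohort for the structure ranking — sizes at which the full
  suite completes in a couple of minutes while leaving the Monte-Carlo
  margins wide.

## Known limitations

* Linear, time-invariant models only; no above-threshold (Phase III)
  nonlinearity, no time-varying gain with fatigue.
* No confidence intervals on parameters and no formal hypothesis tests
  between structures; the pipeline reports means and leaves inference to
  purpose-built study designs.
* The estimation convention (zero initial state plus one concentrated
  offset) absorbs level mismatch but not genuine low-frequency drift;
  records dominated by drift should use the trimming/detrending profile.
* The synthetic cohort is an emulation: its PRBS design and noise model
  are declared choices, so synthetic fit levels should be compared to
  real-data fit levels qualitatively (orderings, gaps), not numerically.
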