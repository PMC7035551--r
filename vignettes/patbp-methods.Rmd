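---
title: "PAT-based BP estimation: models, calibration, and the synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PAT-based BP estimation: models, calibration, and the synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patbp)
```

## The problem

Arterial pulse waves travel faster in stiffer, more pressurised
vessels. Pulse arrival time (PAT) — measured from the ECG R-peak to
the maximum upslope of the same beat's photoplethysmogram — therefore
shortens as blood pressure rises, and a subject-specific calibration
can turn a continuous PAT stream from two wearable sensors into a
continuous, cuff-less BP estimate. The open question this package
addresses is methodological: *which* BP–PAT functional form performs
best when all candidates are calibrated under one identical protocol,
and how sensitive the best-performing form is to its physiological
constant.

## The five models

Four vascular-elasticity (VE) forms follow from the Moens–Korteweg
equation combined with different arterial-wall assumptions; one
elastic-tube (ET) form follows from conservation of mass and momentum:

* **MK-EE** — exponential wall-elasticity model, giving
  $BP = a\,\ln PAT + b$ per channel. Two unknowns per channel.
* **L-MK** — linearised Moens–Korteweg: $BP = a + b\,PAT$. Two
  unknowns.
* **MK-BH** — Moens–Korteweg + Bramwell–Hill anchored at a resting
  baseline: $SBP = SBP_0 - \frac{2}{\gamma PAT_0}(PAT - PAT_0)$, then
  $DBP = SBP - PP_0 (PAT_0/PAT)^2$ where $SBP$ is the model's own
  estimate at the same PAT (the two channels share one anchor). One
  free pair-point: the baseline itself.
* **dMK-BH** — the development of MK-BH through mean pressure:
  $DBP = MBP_0 + \frac{2}{\gamma}\ln\frac{PAT_0}{PAT} -
  \frac{PP_0}{3}\left(\frac{PAT_0}{PAT}\right)^2$ and
  $SBP = DBP + PP_0 (PAT_0/PAT)^2$. One point.
* **M-M** — elastic-tube model, implemented as
  $BP = a + \sqrt{b + c/PAT^2}$ per channel. Three unknowns. The
  printed source for this form is typographically ambiguous about the
  radical's extent; this reading is adopted because the radicand can
  genuinely go negative during calibration (the documented calibration
  failure mode of the model) and because the resulting function is
  bounded and monotone decreasing for $c > 0$, matching the model's
  described premature convergence at long PAT. The form is isolated in
  a single internal function so it can be swapped.

Derived baseline quantities: $PP_0 = SBP_0 - DBP_0$,
$MBP_0 = SBP_0/3 + 2\,DBP_0/3$. The vascular information parameter
$\gamma$ (mmHg⁻¹) defaults to 0.031, the published value for healthy
young adults; it is always an input, never fitted.

Two useful identities follow directly and are enforced by tests:
MK-BH and dMK-BH return $(SBP_0, DBP_0)$ exactly at $PAT = PAT_0$, and
dMK-BH's pulse pressure is $PP_0 (PAT_0/PAT)^2$ identically. The
dMK-BH channels are evaluated in a re-centred arrangement
($DBP = DBP_0 + \ldots$, $SBP = SBP_0 + \ldots$ with terms that vanish
at $PAT = PAT_0$) so the anchor identity holds in floating point
exactly, not just analytically.

## Advanced PTP calibration

Point-to-point pairing (PTP) solves a model's parameters exactly from
as many (30-s mean PAT, cuff BP) pairs as the model has unknowns —
closed forms throughout: two-point formulas for MK-EE/L-MK, direct
anchoring for MK-BH/dMK-BH, and for M-M a pairwise subtraction that
reduces $(BP_i - a)^2 = b + c/PAT_i^2$ to a 2×2 linear system in
$(a, c)$, with $b$ recovered afterwards. Solutions are rejected when a
calibration point would need the negative square-root branch or a
negative radicand ("no real solution").

The *advanced* protocol collects four pairs per round and repeats four
rounds (sixteen 30-s cuff cycles, about eight minutes). For a model
needing $k$ points, every $\binom{4}{k}$ subset of each round is
solved — 4 subsets for the 1- and 3-point models, 6 for the 2-point
ones — and every scalar parameter is averaged arithmetically across
all successful subsets of all rounds; $PP_0$ and $MBP_0$ are recomputed
from the averaged anchors so the baseline identities survive
averaging. Parameters are then frozen. Design choices worth noting:

* *Subset enumeration is exhaustive.* The source protocol's "four sets
  of parameters" matches $\binom{4}{1}$ and $\binom{4}{3}$ but not
  $\binom{4}{2} = 6$; enumerating all subsets is order-invariant and
  coincides with the stated counts for the 1- and 3-point models.
* *Averaging happens in parameter space*, not prediction space (the
  alternative was genuinely open; parameter averaging is what the
  protocol describes being averaged).
* *Rounds are fresh pairs*, collected sequentially, not re-uses of one
  quadruple.
* *Degenerate subsets are skipped with a recorded reason*, and a
  subset whose pairwise mean-PAT separations fall below
  `min_pat_spread` (default 0.002 s, twice the 1 kHz delineation
  resolution) is treated as degenerate too: a PAT difference at timing
  resolution carries no slope information and would amplify cuff error
  without bound. Calibration fails only when *no* subset anywhere is
  usable, and then reports every subset's reason.

`ptp_calibrate()` returns a fitted-model object with an audit trail
(`$audit`: per-subset parameters, skip reasons) and the usual methods
(`print`, `summary`, `coef`, `predict`, `plot`).

## The synthetic testbed

No recordings ship with the package; a seeded generator reproduces the
study design so every stage is testable.

**Cohort.** Twelve subjects by default; resting SBP/DBP drawn from
118.37 ± 12.95 / 69.40 ± 8.79 mmHg (the study population), resting PAT
0.25 ± 0.02 s, γ fixed at 0.031 mmHg⁻¹. Draws violating physiological
constraints (SBP₀ > DBP₀ > 0, positive post-drop PAT, peak HR ≥
resting HR) are re-drawn with a bounded retry count.

**PAT is the primary stochastic process; BP derives from it.** Each
subject's ground-truth BP is the generating model evaluated at the
true per-beat PAT, which makes the data exactly model-consistent —
the property that parameter-recovery tests need — whereas simulating
BP first would require numerically inverting dMK-BH or M-M. For
coefficient models (MK-EE, L-MK, M-M) the generating parameters are
themselves obtained by exact calibration to the subject's
dMK-BH-shaped baseline curve at $k$ anchor PATs spanning the subject's
simulated range, so "generated from model M" holds exactly for every
M.

**Two physiological states.**

* *Rest* (the calibration segment by default, as in the protocol's
  quiet-state calibration): constant resting heart rate; mean PAT
  wanders slowly about PAT₀ as the sum of two incommensurate
  sinusoids (periods ≈ 110 s and 40 s, amplitude `pat_rest_fluct`,
  default 0.030 s ≈ 5 mmHg of resting SBP fluctuation). Without this
  wander, quiet-state calibration pairs would differ only by noise and
  the 2- and 3-point models would be unidentifiable — resting BP
  variability is precisely what repeated calibration rounds average
  over.
* *Post-exercise* (the monitoring segment): heart rate and PAT recover
  exponentially with a shared time constant (default 180 s); the PAT
  drop (default 0.080 s ≈ 20 mmHg of SBP elevation, matching a
  protocol designed to raise BP substantially) decays across the
  15-minute recording, so measured BP falls throughout monitoring.

Per-beat Gaussian jitter (default 5 ms) applies in both states.

**Waveforms.** ECG is a train of narrow Gaussian R-spikes; PPG one
pulse per beat, built from two Gaussian CDFs (sharp rise, slow
offset decay) so the maximum first derivative sits at
beat time + PAT by construction. Only the two fiducial timings are
physiological; PQRST morphology, dicrotic notches, respiration and
motion artefacts are deliberately absent, so passing signal tests
demonstrates timing correctness of the delineation chain, not
robustness to real-world ECG/PPG pathology.

**Cuff readings.** One reading per 30-s window, Gaussian device error
of SD 2.5 mmHg (a consumer oscillometric monitor of roughly 3 mmHg
accuracy; the error distribution is not documented, Gaussian is
assumed). Two definitions of the noiseless reading are provided:
`"beat_mean"` (default) averages the per-beat true BP over the window;
`"model_at_patbar"` evaluates the generating model at the window-mean
PAT. The two differ by a Jensen gap (≈ 0.2 mmHg under default drift)
because the models are nonlinear; recovery tests use the second so
that exactness claims are meaningful, while the first is the natural
reading of "the cuff averages pressure over its measurement window".

## Signal processing

Filters are 4th-order Butterworth high- and low-pass sections applied
forward–backward (`signal::filtfilt`): ECG 1–40 Hz, PPG 0.5–20 Hz,
zero phase so fiducial timings are not delayed. R-peaks are local
maxima above an adaptive threshold (midway between the record median
and maximum) with a 250 ms refractory rule keeping the taller of any
conflicting pair. Each cardiac cycle $[r_i, r_{i+1})$ contributes the
time of the maximum first difference of the PPG on the rising edge
between the pulse foot (the pre-peak minimum) and the cycle's pulse
peak; restricting to the rising edge avoids dicrotic-notch artefacts.
Both fiducials get sub-sample parabolic refinement through the
neighbouring samples, which brings the end-to-end noiseless PAT error
to ≈ 0.02 ms at 1 kHz — comfortably inside the one-sample bound the
tests assert. Windows admit a mean PAT only with at least eight
cardiac cycles (guarding against respiratory modulation of shorter
averages); underfilled windows are excluded and counted.

## Evaluation

With per-window errors $x_i = BP_{est,i} - BP_{cuf,i}$: ME, MAD,
$SSE = \sum x_i^2$, $\sigma = \sqrt{SSE/(n-1)}$, c.v. $= \sigma/ME$,
$SD = \sqrt{\tfrac1n \sum (x_i - \bar x)^2}$, $RMSE = \sqrt{SSE/n}$.
Both dispersion divisors are implemented exactly as defined ($1/n$ for
SD, $1/(n-1)$ for σ) because both appear in the reported statistics;
AAMI-style mean ± SD reporting uses the $1/n$ SD. The c.v. is
undefined at ME = 0 and reported as absent rather than infinite —
near-zero mean errors produce enormous c.v. values by construction,
which is a property of the statistic, not a bug.

Correlations pool all windows of all subjects into one coefficient per
model/channel (one published R per model suggests pooling rather than
per-subject averaging). Model comparisons use Kruskal–Wallis
(`stats::kruskal.test`) followed by Dunn's pairwise z tests with tie
correction; the multiplicity correction is selectable and defaults to
Bonferroni, the common companion of "Dunn's multiple comparison" in
statistical software. AAMI bounds are inclusive: |ME| ≤ 5 mmHg and
SD ≤ 8 mmHg.

The γ sweep recalibrates dMK-BH per subject at each grid value
(default grid 0.0005–0.05 in 0.0005 steps, covering the range where
per-subject optima concentrate), pools MAD separately for SBP and DBP,
and reports the raw grid argmin — no interpolation between grid
points. On noiseless rest-calibrated cohorts generated with
γ* = 0.031 the pooled-MAD argmin lands exactly on 0.031 for both
channels, with MAD numerically zero there.

## Numerical and design choices, in brief

* Exact closed forms everywhere in calibration; no iterative fitting.
* The M-M solve rejects negative radicands *and* points that would
  need the negative branch; both reasons surface in the audit log.
* `estimate_bp()` flags (but returns) estimates with SBP ≤ DBP — the
  models do produce such values in parts of their domain.
* The experiment layout separates an ~8-minute calibration segment
  (quiet state) from a 15-minute monitoring segment (post-exercise
  decay); `calibration_state = "post_exercise"` instead produces one
  continuous decaying session with calibration first.
* `run_experiment()` defaults to feeding the generator's beat-level
  PAT series directly into windowing; `waveforms = TRUE` renders 1 kHz
  ECG/PPG and re-extracts PAT through the full chain. The two paths
  agree to within a sample (a pipeline test asserts it); the direct
  path keeps cohort-scale Monte-Carlo runs cheap.
* Determinism: every stochastic stage is seeded from the experiment
  seed; identical configs produce byte-identical report files, and the
  summary JSON records the seed and a config hash.

## Problem sizes used by the test-suite

Unit and property tests run on records of 10–60 s, cohorts of 1–3
subjects, and 40–1000-case property loops; the end-to-end checks use
one 15-minute 1 kHz record for the signal round trip, 100-point γ
grids on 3-subject noiseless cohorts, and twenty 12-subject noisy
cohorts for the correlation-ranking property. These sizes were chosen
to exercise every claim at full fidelity while keeping a complete run
in minutes on one CPU.

## Limitations

The generator's PAT-to-BP link is exactly one of the five candidate
models, so cross-model comparisons on synthetic cohorts measure
robustness to calibration noise and model mismatch relative to a
dMK-BH-shaped truth — not which model best fits human physiology.
Pre-ejection period (contained in real PAT, unmodelled here), vascular
tone, arrhythmias, and measurement artefacts are out of scope, as are
multi-regressor extensions (heart rate, PPG intensity ratio) and
least-squares calibration over large samples.
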