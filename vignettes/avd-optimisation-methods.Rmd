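---
title: "Haemodynamic AV-delay optimisation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haemodynamic AV-delay optimisation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avdopt)
```

## The measurement model

During a protocolised optimisation the pacemaker alternates between a
reference AV delay (120 ms) and one tested setting at a time. For each
transition we take a window of complete beats immediately before and
immediately after the setting change and compute the difference of the
mean per-beat feature — systolic peak for arterial pressure (ABP), peak or
mean for central venous pressure (CVP) — signed as tested-minus-reference.
Replicate transitions (8 per setting by default, both directions,
sign-corrected) give a mean change and a standard error of the mean (SEM)
per tested AVD.

The per-AVD mean change $y$ is modelled as a parabola in the delay $x$:

$$y = a x^2 + b x + c, \qquad x_{opt} = -\frac{b}{2a}.$$

The fit is weighted least squares with weights $1/\mathrm{SEM}^2$
(zero-SEM points receive the smallest nonzero SEM; an all-zero-SEM
response falls back to an unweighted fit). With the SEMs treated as known
standard deviations, the coefficient covariance is
$(X^\top W X)^{-1}$, and the vertex standard error follows by first-order
(delta-method) propagation through $x_{opt} = -b/2a$:

$$\mathrm{SE}_{opt} = \sqrt{g^\top \Sigma_{ab}\, g}, \qquad
  g = \left(\frac{b}{2a^2},\; -\frac{1}{2a}\right).$$

A parametric bootstrap (`se_opt_bootstrap()`: resample each per-AVD mean
from $\mathcal{N}(\text{mean},\mathrm{SEM})$, refit, take the SD of the
vertices over correctly-oriented non-degenerate refits) is the robust
cross-check. The delta method is the fast default; when the two disagree by
more than 50% the pipeline gates quality control on the bootstrap value,
which behaves better near degeneracy ($a \to 0$, where the vertex
distribution becomes heavy-tailed and the linearisation fails).

Quality control applies two tests per channel: the fitted parabola must
open the physiologically correct way (concave for ABP — the arterial
response has a maximum; convex for CVP — the venous response has a
minimum), and $\mathrm{SE}_{opt}$ must not exceed a threshold, 50 ms by
default. The threshold is configurable
(`analysis_config(qc_seopt_threshold_ms=)`) because sources differ on how
strict the gate should be; 50 ms is the stricter published choice and is
the default here. The gate is strict only above the threshold: a fit at
exactly 50 ms passes.

## Respiratory correction

Respiration moves both pressures by a few mmHg — of the same order as the
pacing effect on CVP — so three corrections are provided:

* **Respiratory-cycle windows** (`window_mode = "resp_cycle"`): the
  pre/post windows are set per subject to
  $\mathrm{round}(\mathrm{HR} / (60 f_{resp}))$ beats, one full respiratory
  cycle, so the respiratory swing averages out of each window mean. At the
  default 90 bpm and 0.25 Hz this is the standard 6-beat window; it matters
  when the respiratory rate deviates from that coincidence.
* **Asymmetric least squares** (`estimate_resp_als()`): a Whittaker
  smoother minimising $\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i
  (\Delta^2 z_i)^2$ with $w_i = p$ where $y_i > z_i$ and $1-p$ otherwise.
  The default $p = 0.5$ tracks the midline of the respiratory swing, which
  is the right target when the trace is later subtracted (the classic
  small-$p$ lower-envelope behaviour is available via `als_config()`).
  $\lambda$ defaults to $10^7 (f_s/250)^4$: the smoother's half-power
  cutoff is approximately $f_s \lambda^{-1/4} / 2\pi \approx 0.7$ Hz,
  between the respiratory (≤ 0.5 Hz) and cardiac (≥ 1 Hz at 90 bpm) bands,
  and the $f_s^4$ scaling keeps that cutoff fixed across sampling rates.
* **Wavelet subtraction** (`estimate_resp_dwt()`): a maximal-overlap
  discrete wavelet transform (Daubechies least-asymmetric 8-tap filter)
  decomposes the signal; the detail levels whose nominal bands
  $[f_s/2^{j+1}, f_s/2^j]$ overlap $[f_{resp}/1.75,\, 1.75 f_{resp}]$ are
  reconstructed as the respiratory trace. The maximal-overlap (undecimated)
  variant is used because it is shift-invariant — no alignment artefacts at
  the pacing transitions, which is exactly where the analysis reads the
  signal — and defined for any record length. Boundaries are handled by
  reflecting the signal to twice its length and discarding the pad.

Subtraction is level-preserving (`subtract_resp()` adds the trace mean
back), so corrected signals stay in absolute mmHg. Correction is applied
to the full continuous trace *before* beat detection and feature
extraction, matching the order correct-then-pick-peaks.

The respiratory frequency is estimated by block-averaging the signal to
about 5 Hz (which also suppresses the cardiac line), Hann-windowing, and
taking the periodogram peak in 0.05–1 Hz with parabolic interpolation;
a peak less than five times the median band power is treated as
"respiration not detected", and callers fall back to the fixed window (or
raise, where no fallback makes sense). Note one boundary effect: at a true
rate of exactly 0.2 Hz and 90 bpm the cycle length is exactly 7.5 beats,
so the rounded window is legitimately either 7 or 8 beats depending on
sub-mHz estimation error.

## The synthetic generator

`generate_subject()` renders the study conditions the analysis assumes:
atrial pacing at 90 bpm sampled at 250 Hz (100 Hz in most tests and
examples — the waveforms are smooth and 100 Hz more than resolves beat
peaks while keeping simulations fast); tested AVDs 40–280 ms in 40 ms
steps against a 120 ms reference; 8 reference→tested transitions per
setting each followed by a return to reference (16 direction changes —
whether "8 replicates" means 8 or 16 direction changes is ambiguous, so
the count is configurable); 10 beats per pacing phase; a quadratic
per-beat peak response with best-to-worst span 11.4 mmHg for systolic ABP,
mirrored (inverted, span 4.15 mmHg) for peak CVP; sinusoidal respiration
at 0.25 Hz with peak-to-trough 2.5 mmHg (ABP) and 2.3 mmHg (CVP) plus
Poisson-timed multiplicative inspiratory spikes (≈2/min, ×2.5, scaled by
`resp_irregularity`); and Gaussian beat-to-beat amplitude noise,
SD 2.5 mmHg by default — chosen once so replicate SEMs land on the
sub-mmHg-to-mmHg scale typical of invasive recordings.

Spans rather than raw curvatures parameterise the effect size because a
span is invariant to where the subject's optimum sits relative to the
grid; curvature is derived as $\text{span}/\max_x (x - x_{opt})^2$.
Morphology is fixed — a raised-sine systolic pulse for ABP and a
two-peaked cycle (dominant a-wave, smaller v-wave) for CVP — and only the
per-beat amplitude carries the AVD effect, since the analysis consumes
only per-beat peaks and means. Each rendered beat is normalised so its
*sampled* maximum equals the target amplitude exactly, which is what makes
noiseless recovery exact to machine precision rather than to sampling
error. Transitions take effect mid-beat (the annotated event falls inside
the last beat of the outgoing phase), so the straddling beat belongs to
neither analysis window — the window logic excludes it explicitly.
Settling is instantaneous by default (`settle_beats = 0`), with an
optional exponential transient.

What the generator deliberately does not emulate: ectopy and arrhythmia,
ventilator-synchronised breathing, baseline drift unrelated to
respiration, measurement-chain artefacts (catheter damping, flushes), and
any asymmetry of the true response around its optimum. Passing tests
therefore show that the pipeline is correct *for data obeying its own
model* — quadratic response, additive respiration, stationary noise — and
calibrated at those conditions; they cannot show robustness to
model-violating clinical data.

`simulate_response()` is a response-level shortcut (replicate deltas drawn
directly around the quadratic) used for Monte-Carlo calibration of the
vertex estimator, where rendering waveforms adds nothing; 500 subjects at
per-AVD SEM ≈ 1 mmHg is the calibration condition used by the acceptance
checks, and the waveform cohorts there use 16 subjects with optima drawn
uniformly on 100–320 ms.

## Numerical choices and degenerate inputs

* Degeneracy: $|a| < 10^{-12}$ mmHg/ms² marks the vertex undefined; the
  fit is flagged, $\mathrm{SE}_{opt}$ is `Inf`, and QC fails with
  `degenerate_fit` rather than reporting a meaningless optimum.
* Fewer than 3 distinct tested AVDs: the parabola is refused
  (`insufficient_settings`) — it would be underdetermined.
* Vertices outside the tested grid are allowed (clinical optima can sit
  beyond 280 ms) but flagged `extrapolated` beyond 40 ms outside the grid.
* The fit uses per-AVD means, not per-replicate deltas, matching the
  mean ± SEM pipeline the protocol defines; the reference-vs-reference
  point (tested 120 vs reference 120, true change 0) is included as an
  ordinary point.
* Spearman correlation uses midranks for ties; p-values use the
  t-approximation for $n \ge 10$ and exact permutation below. Degenerate
  margins (all ties, e.g. a noiseless cohort) report `NA` with a note
  rather than a spurious coefficient.
* CVP "peak" is the higher of the two per-cycle peaks (the natural reading
  of peak venous pressure); taking the per-beat mean instead is a
  configuration choice (`cvp_feature = "mean"`).
* Beat onsets are pulse feet (the minimum before the upstroke); beats are
  attributed to the setting in force at onset; no post-transition blanking
  beats are skipped by default.
* All randomness (generator, cohort draws, bootstrap) flows from explicit
  integer seeds; repeated runs are bit-identical, and the generators
  restore the caller's RNG state.

## Known limitations

The delta-method SE is slightly anticonservative at high noise (the
empirical vertex SD runs ~10–15% above the mean reported SE at the
calibration conditions — within the tolerance the acceptance checks
assert, and the motivation for the bootstrap cross-check and the QC gate).
The ALS and wavelet parameters were calibrated on the synthetic generator,
not on clinical data; the respiratory-frequency estimator assumes a single
dominant respiratory line in 0.05–1 Hz and will refuse mixed or apnoeic
patterns. Beat detection presumes the programmed pacing rate is
approximately honoured; it flags but does not repair gross rate
mismatches.
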