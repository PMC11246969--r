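---
title: "Quantifying fidgeting from task-synchronized actigraphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fidgeting from task-synchronized actigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fidgetr)
```

## The problem

Hyperactivity in adults with ADHD typically surfaces as fidgeting:
non-goal-directed, repetitive movement of the hands, arms and legs. Whether
fidgeting helps or merely accompanies attention is an empirical question,
but answering it requires movement variables that are (a) defined on raw
accelerometry rather than proprietary device counts, and (b) synchronized
with the trials of a cognitive task so that movement can be compared between
task conditions. `fidgetr` provides such a pipeline for 3-axis actigraphy
recorded during an Eriksen flanker session, together with the reaction-time
model and cohort-level analyses such a study needs, and a synthetic
generator that makes the whole chain verifiable.

## The model and its assumptions

**From position to movement.** Raw actigraphy encodes position over time.
Repetition is a property of movement, so each axis is differentiated first:
a forward first difference scaled by the sampling interval. This is the
simplest consistent derivative estimator; its output is one sample shorter
than the recording, and each movement sample carries the timestamp of the
later of its two parents so that epoch boundaries stay aligned with the
task clock.

**Band-limited reconstruction.** The movement signal is decomposed with a
plain FFT, every bin outside a closed band is zeroed (symmetrically in
negative frequencies, keeping the reconstruction real), and the inverse FFT
returns a smooth band-limited signal. The default band of 1–20 Hz is a
hyperparameter: human repetitive movement lives well below 20 Hz, and the
content above it in a 500 Hz stream is dominated by device noise. With the
default low edge of 1 Hz the DC bin is removed, so the filtered signal is
mean-free; setting the low edge to 0 retains DC.

Assumptions worth stating: the recording is uniformly sampled (jitter above
1% of the nominal interval triggers a warning on read); no taper is applied
before the FFT, so spectral leakage at session edges and at bout onsets is
accepted; and filtering is applied **once per session**, not per trial.
The per-trial alternative would let edge artifacts of 2 s windows dominate
a 1–20 Hz band whose lowest period is itself 1 s; per-session filtering
confines edge effects to the two session ends. Both modes of thinking are
compatible with the epoching that follows, and per-session is the default.

**Fidget variables.** Peaks of the band-limited signal are samples strictly
greater than both neighbours (a plateau of equal values counts once, at its
first sample) whose height exceeds a threshold. Heights are signal values
referenced to zero, not peak-to-valley prominences — with DC removed the
band-limited signal is mean-free, so zero is a meaningful reference. Each
trial is an epoch (default: stimulus plus inter-trial interval, 2000 ms,
half-open `[onset, onset + 2000)`), scored with:

* **number of fidgets** — the peak count;
* **fidget time variability** — the population variance, in ms², of the
  intervals between consecutive peaks; undefined below 3 peaks;
* **fidget intensity** — the mean peak height; undefined with no peaks.

Undefined values stay `NA` and are skipped by aggregation: imputing zero
would conflate "no fidgeting" with "perfectly regular fidgeting". Per-axis
values are summed across the three axes, the same convention used to
combine sensors into "arm + leg" rows, so that a single summation rule
covers both combinations. The axis rule is a design choice the field has
not standardized; it is recorded here as such.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| band (low, high) | 1, 20 | Hz | repetitive-movement band; a hyperparameter by design |
| epoch | stimulus + ITI | — | 2000 ms; trials are independent epochs |
| peak threshold | 3 × stationary SD | signal units | noise floor from the no-movement calibration |
| sample rate | 500 | Hz | research actigraph default; any rate with Nyquist above the band works |
| RT floor | 100 (flag only) | ms | anticipatory responses are flagged, retained by default |

**A practical caveat on the threshold.** The stationary calibration bounds
*device noise*, but an untapered per-session filter adds a second, subtler
floor: strong planted (or real) bouts leak across FFT bins, and because the
movement signal's length is not an integer number of bout periods, the
leakage forms a slow beat along the session. Peaks of that ripple sit at a
few percent of the bout amplitude; a threshold below it counts leakage
ripple, which drifts systematically across the session, rather than
movement — in our validation this miscalibrated the null of the Q1/Q4
comparison until the threshold was raised to 30% of the bout amplitude.
Rule of thumb: set the threshold above `max(3 × stationary SD, ~20% of the
typical bout amplitude seen in the simulated-fidget calibration)`.

## The reaction-time model

Reaction times in ADHD samples carry a heavy right tail; the ex-Gaussian
distribution — Normal(mu, sigma) convolved with Exponential(tau), mean
`mu + tau`, variance `sigma^2 + tau^2` — represents it well, with sigma and
tau as complementary variability parameters. The log density is evaluated
in a numerically stable form: the direct expression
`-log(tau) + s^2/2 - a*s + log Phi(a - s)` (with `a = (x-mu)/sigma`,
`s = sigma/tau`) suffers catastrophic cancellation when `s` is huge, so for
`a - s < -30` the package switches to a Mills-ratio expansion in which the
cancellation is performed analytically, leaving the Gaussian-limit term
`-a^2/2`. Without this, the likelihood surface develops spurious ridges at
absurd sigma values and the optimizer can escape to them.

Estimation is maximum likelihood over `(mu, log sigma, log tau)` with BFGS,
initialized by moments (`tau0` from the third central moment,
`mu0 = mean - tau0`, `sigma0^2 = max(var - tau0^2, eps)`). The fit never
returns anything worse than the initializer; failure to improve on it is
flagged as non-convergence. Omissions are excluded before fitting, and the
paper-level convention of fitting correct trials only is a caller decision
(the pipeline's report fits correct, responded trials).

## Analyses

Correct-vs-incorrect and Q1-vs-Q4 (first vs last 30 of 120 trials)
comparisons are **paired** t tests: each participant contributes both
conditions, so the within-participant difference is the natural unit.
Participants lacking a condition — commonly, no incorrect trials in a
high-accuracy adult sample — are dropped from that comparison only.
Degenerate inputs follow an explicit contract (zero variance with equal
means gives t = 0, p = 1; otherwise an infinite t is flagged). No
multiple-testing correction is applied; the comparison count is reported so
readers can apply their own.

Median splits assign values strictly below the cohort median to the low
group; ties straddling the median go high, with a warning recording any
imbalance. The six-predictor linear models use ordinary least squares and
report `R = sqrt(1 - RSS/TSS)` with the overall F test on `(6, n - 7)`
degrees of freedom; six predictors are used in every model (arm and leg
values of the three fidget variables, or six task-performance scores) so
that goodness of fit is comparable across models.

## The synthetic generator: what it emulates, what it does not

The generator synthesizes the **movement** signal first — within each
trial's bout window, a sinusoid at the bout frequency, phase zero at bout
onset — and integrates it into position by cumulative summation. Because
the pipeline starts with a forward difference, differentiating the
generated recording recovers the designed movement samples exactly, giving
bit-level ground truth after the first stage. Bouts occupy a contiguous
interval at the start of each trial epoch (simplest reproducible
placement); occupancy is settable per trial, which is how time effects
(more fidgeting in later trials) are planted. Device noise is white
Gaussian noise on the movement signal, optionally plus a high-frequency
sinusoidal artifact above the band, mimicking the narrow-band device noise
seen in real spectra. Calibration regimes mirror practice: stationary
(noise only), simulated fidgeting (sustained in-band bout), and rapid
movement (stronger, broadband).

Deliberately not emulated: gravity and orientation drift, biomechanical
coupling between axes (the bout lives on one axis), amplitude scales of any
particular device (units are arbitrary and documented as such), non-sinusoidal
bout shapes, and omission mechanisms other than missing-at-random. A green
end-to-end test therefore establishes that the pipeline recovers planted
band-limited repetitive structure under realistic noise — not that any
particular hardware's output will look like the generator's.

Defaults describe the stated world of the validation cohort: 120 trials
(40 per type), 1000 ms stimulus + 1000 ms ITI, ex-Gaussian RT parameters
(369.3, 51.9, 70.0) ms, omission and error rates near the published 2.2%
and 3%, and synthetic cohorts whose fidget variables are drawn around the
published per-trial means and SDs, truncated at zero. Bout frequency
defaults to 4 Hz (a typical leg-bounce rate) with 30% epoch occupancy —
chosen once as a realistic mid-range and not revisited.

## Numerical choices

* Band edges are **inclusive** (`[low, high]`), and the bin at exactly the
  Nyquist frequency is kept when the band reaches it.
* The inverse FFT's imaginary residue is checked against `1e-8` of the
  signal norm before being discarded.
* Peak detection uses run-length encoding, so exact plateaus (possible in
  quantized or clipped signals) produce a single peak deterministically.
* Inter-peak variability is a **population** variance, so two intervals
  yield a defined (possibly zero) value and perfectly regular planted bouts
  report exactly 0; the fast epoching path computes it via
  `E[x^2] - E[x]^2` with a guard clamping tiny negative round-off to zero,
  and is verified in the tests against the direct per-window path.
* Ties in `median_split` and rank deficiency in the linear model are
  reported, not silently absorbed.
* Seeded generation uses a local RNG scope, so calling generators does not
  disturb the caller's random stream; identical seeds give byte-identical
  output.

## Known limitations

Impulsive, non-repetitive movements are outside the variables' reach by
construction. Absolute magnitudes of intensity are device-specific; only
conventions (summation across axes and sensors) are reproducible across
hardware. The untapered FFT filter's leakage is acceptable for long
sessions but would dominate if filtering were applied per 2 s trial — a
mode the API supports but does not default to. Cohort-level findings from
any single study (group means, t scores, R values) depend on participant
data and are not reproduced here; the package reproduces the *methods*,
validated on synthetic ground truth.
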