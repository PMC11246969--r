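# fidgetr

Quantifying fidgeting from task-synchronized actigraphy.

Fidgeting — non-goal-directed, repetitive body movement — is a hallmark of
hyperactivity in adult ADHD, yet studies usually quantify it with
device-defined activity counts that cannot be reproduced across hardware.
`fidgetr` implements a device-independent pipeline for researchers who record
raw 3-axis accelerometry (wrist and ankle) while participants perform a
cognitive task such as the Eriksen flanker, and who want interpretable,
per-trial movement variables they can relate to task performance, reaction
time and symptom rating scales.

## The method

For each sensor site, raw position samples \(s_x, s_y, s_z\) sampled at rate
\(f_s\) are transformed per axis:

1. **Movement signal** — forward time derivative,
   \(m_i = (s_{i+1} - s_i)\, f_s\).
2. **Band-limited reconstruction** — FFT of the whole-session movement
   signal, zeroing every bin outside a closed band \([f_{lo}, f_{hi}]\)
   (default 1–20 Hz, a hyperparameter), inverse FFT. Low frequencies carry
   the smooth repetitive component that characterizes fidgeting; higher
   frequencies are dominated by device noise.
3. **Peak detection** — local maxima whose height exceeds a threshold,
   calibrated as 3 SD of the band-limited signal from a stationary
   (no-movement) calibration recording.
4. **Per-trial fidget variables** — treating each task trial as an epoch
   (default: stimulus + inter-trial interval, 2000 ms):
   * **number of fidgets** — peak count in the epoch,
   * **fidget time variability** — population variance (ms²) of inter-peak
     intervals (undefined below 3 peaks),
   * **fidget intensity** — mean peak height (undefined with no peaks).

   Variables are summed across the three axes, and across sensors
   ("arm + leg") by the same rule.
5. **Reaction-time model** — the ex-Gaussian distribution
   (Normal(\(\mu, \sigma\)) + Exponential(\(\tau\)); mean \(\mu + \tau\),
   variance \(\sigma^2 + \tau^2\)), fitted by maximum likelihood with a
   moments initializer.
6. **Analyses** — paired comparisons of fidget variables between correct and
   incorrect trials and between the first (Q1) and last (Q4) 30 trials of a
   120-trial session; cohort median splits on \(\mu\), \(\sigma\), \(\tau\);
   and six-predictor ordinary-least-squares models relating fidget variables
   to rating-scale totals (BAARS-IV, BDEFS section 5, ARI), reporting the
   multiple correlation \(R\) and the overall F test.

A seeded synthetic generator plants sinusoidal fidget bouts with known
frequency, amplitude and per-trial occupancy inside device noise, so the
whole pipeline is testable without access to participant data.

## Worked example

```r
library(fidgetr)

sched  <- task_schedule(seed = 1)                     # 120 flanker trials
prof   <- fidget_profile(bout_frequency_hz = 4,       # 4 Hz leg-bounce bouts
                         bout_occupancy = 0.3,        # 30% of each 2 s epoch
                         noise_sd = 0.05)
wrist  <- simulate_recording(prof, sched, sample_rate_hz = 100, seed = 1)
events <- simulate_session(sched, seed = 1)

filtered <- band_reconstruct(differentiate(wrist), frequency_band(1, 20))
metrics  <- epoch_metrics(filtered, sched, threshold = 0.3)
aggregate_metrics(metrics)
#>          variable       mean        sd   n
#> 1       n_fidgets  3.0000000  0.000000 120
#> 2 variability_ms2 32.7083333 38.045173 120
#> 3       intensity  0.9500499  0.015911 120

fit_exgaussian(events$rt_ms)
#> <exgauss_fit> mu = 378.1 ms, sigma = 44.1 ms, tau = 63.7 ms (n = 116)
```

The generator plants 4 Hz sine bouts covering the first 0.6 s of every 2 s
epoch; a sine's maxima fall at \((k + 0.25)/f\), so each bout holds exactly
3 peaks — recovered as a mean of 3.0 with zero SD. Intensity ≈ 0.95 is the
planted unit amplitude sampled just off the crest at 100 Hz, and the small
variability (≈ 33 ms² against perfectly regular 250 ms spacing) is the
±10 ms sampling jitter of peak placement. The reaction-time fit recovers
the generator's ex-Gaussian parameters (369.3, 51.9, 70.0 ms) within
sampling error from 116 responded trials (4 omissions are excluded).

The full pipeline — CSV in, per-trial metrics CSV and a provenance-bearing
JSON report out — is available as `run_pipeline()` or from the shell:

```sh
inst/cli/fidget simulate --out sim --seed 3 --sample-rate 100
inst/cli/fidget analyze --wrist sim/wrist.csv --ankle sim/ankle.csv \
    --events sim/events.csv --threshold 0.3 --out results
```

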