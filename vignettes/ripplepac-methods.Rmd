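---
title: "Methods: ripple detection and theta-gamma coupling in ripplepac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ripple detection and theta-gamma coupling in ripplepac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
```

```{r load}
library(ripplepac)
library(dplyr)
```

ripplepac analyzes hippocampal local field potentials (LFPs) along two axes:
transient sharp-wave-ripple (SWR) events in the 140–220 Hz band, and
theta-gamma phase-amplitude coupling (PAC). Both analyses operate on tidy
tibbles and compose into a session pipeline that emits mixed-model-ready
feature tables. A synthetic generator with exact ground truth backs every
quantitative claim in the test suite.

## Signal model

An LFP recording is a regularly sampled voltage series, represented as a
tibble (`time_s`, `voltage`) with the sampling rate, channel and trial as
attributes (`lfp_recording()`). Four canonical bands are built in:

| band        | range (Hz) |
|-------------|-----------|
| theta       | 4–12      |
| low_gamma   | 25–50     |
| mid_gamma   | 50–100    |
| ripple      | 140–220   |

## Filtering and the analytic signal

Band-passing uses a single order-4 Butterworth design (`signal::butter`,
type `"pass"`) applied forward and backward for exact zero phase, with
odd-reflection padding scaled to the filter's ringing time so edges do not
leak transients. A single band-pass section is used rather than a
high-pass/low-pass cascade because a cascade of two order-4 zero-phase
sections attenuates the in-band centre (gain ≈ 0.74 at 180 Hz) while the
single section keeps in-band gain within [0.9, 1.05].

The 60 Hz line notch is an RBJ-cookbook biquad (Q = 30, ≥ 30 dB at 60 Hz,
≤ 3 dB at 50/70 Hz), also applied forward-backward.

Instantaneous amplitude and phase come from the FFT-constructed analytic
signal (`analytic()`). Phase follows the **cosine convention**: phase 0 at
the positive peak of the band-passed oscillation. All phase quantities in
the package (preferred phase, phase bins) use this convention.

## SWR detection rule

Detection operates on the z-scored ripple-band envelope (z-scored over the
whole trial, or over a declared reference window). The rule:

1. events are maximal runs where z strictly exceeds 3 SD for at least
   15 ms;
2. events within 15 ms of one another are merged, and features are
   recomputed over the merged span (the minimum-duration filter applies to
   the merged span);
3. per-event features: duration (ms), peak z, and the SWR *integral* — the
   sum of z-scored envelope samples from event start to end.

Trial summaries (`summarize_trial()`) report event count, rate, and mean
peak/duration/integral; stimulus trials can be expressed ratio-wise against
a baseline trial (`normalize_to_baseline()`), with degenerate baselines
flagged as `NA` rather than silently propagated.

One consequence of the rule's order of operations is worth knowing: because
the minimum-duration filter applies *after* merging, two sub-minimum runs
that coalesce under a wider merge gap can raise the event count from 0 to
1, so the count is not globally monotone in `merge_gap_ms`. With a minimum
duration below every run width, merging can only coalesce events and the
count is non-increasing in the gap.

## Modulation Index

PAC between a phase band and an amplitude band is quantified by the
entropy-based Modulation Index over 18 phase bins:

MI = (log N − H(p)) / log N,  p_j = ⟨amp⟩_j / Σ_k ⟨amp⟩_k

with natural logarithms and N = 18. MI is 0 for a uniform
phase-conditioned amplitude distribution and 1 for a point mass.
`pac_for_trial()` composes band-passing, the analytic transform and
binning; `mi_surrogate_null()` provides a circular-shift surrogate null.

## Synthetic ground truth

`generate_background()` shapes white Gaussian noise in the frequency
domain (amplitude ∝ f^(−exponent/2)), rescales to the target RMS exactly,
and optionally adds a 60 Hz line. `generate_pac()` adds a theta carrier
and a gamma component whose amplitude is modulated against the carrier's
cosine-convention instantaneous phase, so the theta phase of maximal gamma
amplitude equals `preferred_phase` exactly as `analytic()` measures it.

`inject_ripples()` places Tukey-enveloped (taper fraction 0.5) sinusoidal
bursts at Poisson times thinned to a minimum gap. The Tukey envelope's
flat central half guarantees that a supra-threshold burst stays above
threshold for longer than the 15 ms minimum; a Gaussian envelope of the
same support leaves the supra-threshold width knife-edge at the duration
rule.

Burst amplitude is specified in *detector units*: the target value of the
z-scored ripple-band envelope at the burst centre, with z-scoring performed
on the burst-containing trial, exactly as the detector does it. Because the
injected bursts themselves inflate the trial-wide envelope mean and SD,
the calibration cannot simply divide by the filter gain. The package
exploits linearity of the zero-phase filter and the analytic transform:
with $A_0$ the analytic ripple-band background and $A_B$ the analytic
ripple-band unit burst train, the envelope at burst amplitude $a$ is
$|A_0 + a A_B|$, and the calibration equation

mean(env at centres) = mean(env) + amplitude_z · sd(env)

is solved on that exact empirical envelope by root finding. A side effect
of doing this honestly: at high burst rates, trial-wide z-scoring
saturates — the bursts inflate the SD faster than they raise the centre
envelope — and sufficiently aggressive `amplitude_z`/`rate` combinations
are genuinely unreachable. `inject_ripples()` raises an informative error
in that case instead of silently under-delivering.

```{r recovery}
bg <- generate_background(60, fs = 1000, noise_spec(exponent = 1), seed = 1)
inj <- inject_ripples(bg, ripple_spec(rate = 0.3, amplitude_z = 6,
                                      duration_ms = 50), seed = 2)
events <- detect_swr(inj$recording)
nrow(events); nrow(inj$ground_truth)
```

## Session and cohort pipeline

`run_session()` walks a declared design (animal, genotype, drug, trial
segments, channels) over supplied recordings and emits one tidy row per
(channel, segment, feature), with stimulus features both raw and
baseline-normalized, plus a JSON-able manifest recording every parameter
and the downstream mixed-model formula
(`feature ~ genotype * drug + (1 | animal_id)`). Mixed-model estimation
itself is deliberately out of scope — the table is shaped for `lme4` — and
in-package group comparisons use an exact-enumeration permutation test
(`perm_test_two_group()`).

`batch_simulate_and_analyze()` simulates whole cohorts with per-genotype
ripple-rate multipliers and per-stimulus coupling, and is the engine of the
cohort-recovery validation. The package's default problem size — 10
animals × 2 channels, 50 s baseline and stimulus segments at 500 Hz, 0.4
events/s baseline rate — was chosen by a power analysis: it detects a 2×
stimulus rate effect in ≈ 98% of cohorts via the exact permutation test on
channel-averaged normalized rates, at about 2.7 s per cohort, while trial
durations and cohort counts far beyond this add runtime without changing
what is being validated.

## Numerical choices and limitations

- Z-scoring is trial-wide by default; a reference window can be declared.
  Trial-wide z-scoring is scale-free but saturates under very high event
  density (see above).
- MI's amplitude-scale invariance holds to ~1e-13 relative tolerance, not
  bit-exactly: the normalization `p = mean_amp / sum(mean_amp)` cancels
  scale only in exact arithmetic.
- The detection comparison is strict (`z > threshold`); ties at the
  threshold are astronomically unlikely on real envelopes.
- The synthetic generator validates the *pipeline*, not hippocampal
  biology: bursts are stationary sinusoids under a fixed envelope, the
  background is a pure power law, and PAC is a deterministic modulation —
  all chosen so every recovered quantity has a known target.
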