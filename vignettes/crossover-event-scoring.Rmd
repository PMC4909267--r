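---
title: "Scoring neonatal cardiorespiratory events in an ON/OFF crossover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring neonatal cardiorespiratory events in an ON/OFF crossover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoapnea)
```

## The analysis in one paragraph

Premature infants with apnea of prematurity are monitored for 24 hours
while an intervention is alternated in four 6-hour blocks (ON/OFF/ON/OFF or
the reverse, order chosen by coin flip), giving 12 hours per condition.
From the monitor's channels — respiratory effort, pulse-oximetry SpO2 and
heart rate (or ECG) — we score three families of events: breathing pauses,
intermittent-hypoxia (IH) episodes at nested SpO2 thresholds, and
bradycardia episodes at two heart-rate thresholds. Events are assigned to
the block containing their onset; per-subject, per-condition counts and
total durations feed a paired analysis: a t-test on ln(x+1)-transformed
values per outcome, with raw-scale mean differences reported for
interpretation.

## Event definitions and detector design

### Breathing pauses

The respiratory effort channel carries a quasi-periodic wave at roughly
40–70 breaths/min in this population. `detect_breaths()` band-passes the
effort signal over 0.3–2.5 Hz (Butterworth order 2, zero-phase) and marks
breaths at local maxima that clear an adaptive amplitude threshold: a
fraction (default 0.3) of the rolling median height of ~100 neighbouring
peaks, floored at half the record-wide median so that minutes of apneic
low-level noise cannot drag the reference down and admit noise peaks.
Signals sampled faster than ~10× the band edge are first decimated by block
averaging to 25 Hz; breathing carries no information above a few Hz, and
the decimation cuts filtering cost an order of magnitude while keeping peak
timing to a few tens of milliseconds.

A *pause* is deliberately not the raw inter-breath interval: that
definition would count slow-but-regular breathing as pathology. Instead
`detect_pauses()` takes each inter-onset interval, subtracts the subject's
median breath period, and clips at zero — the *silent time beyond one
expected cycle*. Pauses with duration in (3, 5] s are short, > 5 s long;
the two classes partition everything beyond 3 s and a boundary value of
exactly 5 s is short. The pause onset is placed one median period after
the last breath.

### IH episodes

Pulse oximeters report saturation through an internal moving average;
`smooth_spo2()` models this as a trailing (causal) boxcar of 8 s — the
averaging time of common NICU oximeters — taken over valid samples only,
with the output marked invalid when a window contains no valid sample. A
step change settles exactly one window after the step, with a linear ramp
in between; this closed form is asserted in the tests. Monitor trend
exports are typically already device-averaged, so the detection wrapper
does not smooth again by default (`spo2_window = NULL`).

`detect_desaturations()` finds, per threshold (90, 88, 85%), maximal runs
of valid samples *strictly* below the threshold ("fell below 90%" reads as
< 90, so a sample equal to the threshold ends an episode) lasting at least
5 s. Runs separated by even a single recovery sample are distinct events: a
`merge_gap` parameter exists but defaults to 0, because no merging rule is
part of the definitions above and merging silently deflates counts.
Durations at nested thresholds are therefore monotone by construction
(total time below 85% ≤ below 88% ≤ below 90%), and the test suite checks
this invariant on every generated input.

### Bradycardia

With a neonatal baseline of 150–165 bpm, bradycardia thresholds of 110 bpm
(mild) and 100 bpm (moderate) correspond to the conventional one-third drop
from baseline. `detect_bradycardia()` applies the same strict run-length
rule with a minimum duration of 1 s — no minimum is inherent in the
definition, but a one-sample floor suppresses single-sample telemetry
artifacts; the parameter is exposed.

When only ECG is recorded, `compute_heart_rate()` derives a 1-Hz heart-rate
channel: squared-derivative energy, a block-adaptive threshold (fraction of
the rolling median of 2-s block maxima), a 0.2-s refractory period, then
60/RR held sample-wise. RR intervals outside 0.2–3 s (20–300 bpm) are
implausible and masked, as is any stretch lying inside an implausibly long
RR gap — undetectable QRS yields invalid time, not fabricated rate.

### Conventions shared by all detectors

Invalid samples break runs and contribute no events; artifact is masked,
never imputed. Events are timestamped by onset and never split across
block boundaries, so an episode beginning just before a transition belongs
wholly to the earlier block; with whole-episode counting this is the only
rule that avoids fractional events. All detectors are verified against an
independent brute-force scanner on thousands of randomized signals, and
shifting a recording in time shifts onsets without changing any count.

## Block aggregation

`assign_events()` labels each event with the condition of the block
containing its onset (an onset exactly on a boundary belongs to the later
block) and errors on onsets outside the schedule. `summarize_subject()`
tallies counts and total durations per outcome and condition, and carries
the valid monitored time per condition computed from a channel mask.
Totals, not rates, are the primary outputs — the design guarantees equal
12-h exposure per condition — but the valid-time columns let an analyst
detect unequal artifact burden and fall back to rates when needed.

## Statistics

Counts and total durations are right-skewed, so the paired t-test is run
on a transformed scale. The package computes square-root, log10(x+1) and
ln(x+1) transforms and a normality screen (Lilliefors-corrected
Kolmogorov–Smirnov for n ≥ 5, plus Shapiro–Wilk) of the paired differences
for each; ln(x+1) is the default because it is the standard choice for
event counts with zeros. The screen is *reported, never auto-enforced*:
"pick the transform with the best normality" is not a well-defined
selector, and silent automatic selection would make analyses
irreproducible across cohorts.

`paired_test()` reports the t statistic, df = n − 1 and a two-sided p from
the transformed scale, and the raw-scale condition means, standard errors,
mean difference and percent change. The MD sign convention is OFF − ON, so
a beneficial intervention gives positive MDs; the per-subject
percent-change table (`percent_change_table()`) uses 100·(ON − OFF)/OFF,
where negative indicates a reduction, and OFF = 0 yields a missing value
rather than an infinity. `cohort_report()` runs all 14 outcome × measure
combinations and attaches an explicit note that no multiple-testing
correction is applied — the analysis mirrors the single-outcome paired
design it reproduces, and a correction choice belongs to the analyst.
Degenerate inputs (zero-variance differences) yield a flagged degenerate
result, not an error. Crossover sequence/period effects are out of scope:
the paired t-test ignores them by design, and a mixed-model extension is
noted as future work.

## The synthetic-data generator

The generator exists so that every pipeline stage can be validated against
known ground truth. It emulates:

* **Breathing** at 55 breaths/min (Gaussian period jitter, SD 0.05 s),
  rendered as one sinusoidal effort cycle per breath at 250 Hz.
* **Apneas** as a renewal process: default 40 events/h during OFF blocks
  (yielding on the order of 280 long and 190 short pauses per 12 h under
  the default log-normal duration distribution, median 5.5 s, log-SD 0.5),
  multiplied by a stimulation rate ratio (default 0.61, a 39% reduction)
  during ON blocks. A 30-s minimum separation keeps events unambiguous;
  the exponential waiting time is dead-time-compensated so the requested
  hourly rate is attained, which keeps the realized ON/OFF ratio equal to
  the configured one instead of biased toward 1.
* **The cascade**: each pause triggers a raised-cosine heart-rate
  deceleration (lag 4 s, depth 6 bpm per second of pause, floor 70 bpm)
  and a slower, longer desaturation (lag 8 s, depth 1.2% per second of
  pause, floor 75%, width ≈ twice the pause plus 15 s) — bradycardia
  preceding the desaturation. With these defaults a 13-s pause produces
  bradycardia below 80 bpm and roughly 25 s below 90% saturation, the
  canonical severe-event profile in this population.
* **Observation**: SpO2 is passed through the 8-s oximeter average; SpO2
  and heart rate are emitted at 1 Hz (monitors export vitals trends at
  about that rate), effort and optional ECG at 250 Hz; Gaussian
  measurement noise (0.05 a.u. effort, 0.3% SpO2, 1 bpm) is added after
  the deterministic physiology, so the ground truth lists the events
  implied by the noiseless record.

Numerical care at class boundaries: pause onsets are snapped to the breath
grid and the *realized* silent time is what ground truth reports; realized
durations within 0.1 s of the 3-s or 5-s class boundary are extended
slightly, so short/long classification can never flip at the detector's
peak-timing resolution. Setting all noise terms and the period jitter to
zero makes the record fully deterministic, and detection then recovers the
ground-truth counts exactly — a property the acceptance tests assert on a
full 24-h record.

`generate_cohort()` produces study-scale tables in two modes. *Signal*
mode runs the complete pipeline per subject (generate → detect → assign →
summarize) with a log-normal subject frailty scaling the apnea rate,
truncated to [1/3, 2] so extreme draws stay within a physiologic and
feasible apnea load. *Counts* mode skips the waveforms: negative-binomial
counts around frailty-scaled means with per-outcome OFF means and ON/OFF
ratios set by `cohort_calibration()` — long-pause counts down 39%, short
pauses 21%, IH below 90% down 28% (30% of duration), bradycardia roughly
3-fold, with the <88/<85 thresholds sharing the <90 ratios because
separate ratios are not identified by the aggregate effects being
emulated. Frailty SD 0.6 and NB size 12 were chosen once as plausible
between- and within-subject dispersion for event counts of this magnitude.

What the generator does *not* emulate: sleep-state structure, caffeine or
oxygen-supplementation effects, chemoreflex feedback loops, obstructive
versus central apnea morphology, day-scale drift in baseline rate, or
correlated artifact (probe-offs, motion). Consequently, passing the
recovery tests shows the detectors implement their definitions correctly
and the statistics are calibrated — it does not certify performance on
clinical waveforms, where breath morphology and artifact are far richer.
One visible consequence: in signal mode the only within-subject,
between-condition variability is Poisson event sampling, so simulated t
statistics run noticeably larger than those typically seen in clinical
crossovers with comparable mean effects.

## Problem sizes used in validation

The shipped tests and the acceptance script validate at study scale while
staying desk-sized: oracle-equivalence over 1000 randomized signals of up
to 4000 samples; exact noise-free recovery on one 24-h record; noisy
sensitivity/precision for long pauses over 20 (tests) or 8 (script) 24-h
records; rate-ratio recovery over 200 simulated days at the event level;
and type-I error over 1000 null cohorts of 15 subjects in counts mode.

## Known limitations

* The breath detector assumes an effort channel with visible cyclic
  morphology; it is untested on flow or impedance signals with strong
  cardiac cross-talk.
* Desaturation episodes are never merged across brief recoveries by
  default; cohorts scored with merging conventions will show lower counts.
* EDF support covers continuous 16-bit recordings with integer-Hz
  channels; EDF+ annotations and discontinuous files are not interpreted.
* The statistics module implements the paired t-test family only; it does
  not model sequence or period effects, nor correct for multiplicity.
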