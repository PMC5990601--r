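---
title: "Bilateral gait trend analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilateral gait trend analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilatgait)
```

## The problem

After a stroke or brain-tumour resection, one body side is weakened
(hemiparesis). Rehabilitation aims to restore symmetric movement, and a
clinically useful question is whether the affected side's walking parameters
are *converging* toward the non-affected side's over weeks of therapy.
`bilatgait` implements a rule-based pipeline that takes day-long 50 Hz
tri-axial accelerometer recordings from four body-worn sensors (both thighs,
both upper arms), extracts natural walking, segments strides on both sides,
computes daily per-side movement parameters, and summarises recovery as the
extrapolated intersection day of the two sides' linear trends.

## The four stages

**1. Preprocessing.** Streams are linearly interpolated onto one 50 Hz grid
over their common time span (`align_streams()`), relabelled from left/right
to `Aff`/`NonAff` given the patient's affected side (`assign_sides()`), and
reduced to non-overlapping 1-s windows (50 samples) with per-axis mean
$\mu_k$ and variance $\sigma^2_k$ (`window_features()`). The axis convention
is $x$ mediolateral, $y$ vertical (thigh-longitudinal), $z$ anteroposterior.
We use the population variance (divide by $n$); with $n = 50$ the difference
from the sample variance is at most 2 % and the choice is fixed and
documented. Trailing partial windows are dropped rather than padded because
the detection thresholds apply to full windows.

**2. Walking extraction.** A window of the *non-affected* thigh counts as
walking iff all three strict inequalities hold:

$$\mathbb{1}_{WS} \;=\; \mu_{y} > \theta_1 \;\wedge\; \mu_{z} < \theta_2
\;\wedge\; \sigma^2_{y} > \theta_3$$

with $\theta_1 = 8\,\mathrm{m/s^2}$, $\theta_2 = 4\,\mathrm{m/s^2}$, and
$\theta_3 = 0.7\,(\mathrm{m/s^2})^2$ for walkers or $0.25$ for wheelchair
users, whose walking is gentler. The thresholds act on raw,
gravity-inclusive means: an upright thigh carries most of gravity on its
longitudinal axis, which is what makes $\mu_y > 8$ discriminate upright
locomotion from sitting. Maximal runs of flagged windows become walking
segments with no gap bridging — downstream filters remove spurious short
segments, so this stage is deliberately permissive.

**3. Stride segmentation and movement parameters.** Candidate segments pass
an autocorrelation filter (maximum normalised autocorrelation of the
mean-removed vertical signal over lags 0.25–3 s must reach 0.3); both
thighs' signals are median-smoothed (5 samples = 0.1 s), differentiated by
central differences, and peaks of the derivative are found by hill-climbing:
every sample above the amplitude threshold (0.3 times the 95th percentile of
the absolute derivative) ascends to its local maximum, with a 0.25 s minimum
peak separation (the shortest admissible stride; ties keep the earlier
peak). The bilateral verification then anchors on the non-affected side:
non-affected strides are peak-to-peak intervals, each interval keeps exactly
one affected peak (the within-interval maximum of the affected derivative;
surplus candidates are dropped, and an interval with no detected candidate
falls back to the interval's derivative argmax), and one trailing affected
peak may form one extra stride — so per-segment counts differ by at most
one. The final affected stride has no following affected peak to close it;
we close it at its peak plus the last non-affected interval's duration, a
documented convention. Individual strides outside 0.25–3 s are discarded,
and a segment is rejected unless at least 5 consecutive in-bounds strides
remain on the non-affected side.

Per day and side we report stride count, normalized stride count (strides
per *hour* of recording — the only unit under which a daily total of a few
thousand strides and a normalized count in the hundreds are mutually
consistent over ~9 h recordings), and mean/SD of stride duration, cadence
and sway. Cadence is strides per minute of the walking segment (half the
step-based cadence used elsewhere), averaged unweighted across segments.
Sway is read as the mean absolute mediolateral upper-arm acceleration over a
stride's samples — a literal indicator reading of the defining sum would be
identically 1, contradicting the observed 0.7–4.2 m/s² range — computed from
the side-matched arm sensor with raw (not detrended) samples. Walking during
annotated physiotherapy is masked out before parameter computation (a
segment is dropped when more than half of it overlaps an excluded label),
switchable via `pipeline_config(exclude_physio = )`.

**4. Trend analysis.** For each parameter and side, ordinary least squares
$y = \alpha + \beta t$ over days since study begin (day 1 = first recording;
days without walking are omitted, not zero-filled). The *convergence point*
solves $\alpha_{NonAff} + \beta_{NonAff}t = \alpha_{Aff} + \beta_{Aff}t$;
solutions outside $[1, t_{max}]$ with $t_{max} = 3650$ days (10 years) are
reported as capped, never as a number, so no emitted convergence day exceeds
the cut-off. A trend pair is *parallel* when the Pearson correlation of the
paired daily values is positive with $p < 0.05$; otherwise it is converging
or diverging by the sign of the fitted slope of the absolute side
difference. Continuous convergence estimates refit both trends on growing
windows of the first $k = 2, \dots, K$ days. Side differences are tested
with a paired two-sided t-test — sides are measured on the same days, which
makes the paired form the natural choice.

## The synthetic-data generator

The study's recordings are not publicly available, so the package ships a
seeded generator (`simulate_recording_day()`) that produces the four sensor
streams for a scripted day plus the ground truth every stage is validated
against: walking intervals, per-side true stride boundary times, and
per-side analytic sway values.

The signal model, per walking bout and side: the thigh's vertical axis is a
gravity-dominated baseline (9.4 m/s² upright) plus a stride-frequency
oscillation plus one sharp-onset, exponentially decaying pulse per true
stride boundary (onset time constant 0.12 s), plus white noise. The pulse's
acceleration maximum and derivative maximum coincide at the onset, which is
what lets the noiseless oracle demand sample-exact agreement between
detected and true boundaries. The oscillation's phase is locked to the
actual (possibly jittered) stride boundaries — each stride spans exactly one
cycle — so oscillation extrema coincide with the pulses instead of drifting
away and creating spurious derivative peaks, and so each stride covers one
full period of the arm's sway sinusoid, making the analytic per-stride sway
exactly $2A/\pi$ for amplitude $A$. Sitting places the thigh horizontal
(vertical mean 2 m/s², violating $\mu_y > 8$), standing is upright but quiet
(violating the variance condition), and wheelchair propulsion is seated with
rhythmic ~1 Hz arm pushes (violating $\mu_y > 8$); the propulsion model is a
stipulation, since no quantitative description of propulsion accelerations
was available.

Defaults were chosen once from the cohort's summary statistics and are not
tuned: stride duration means 1.40 s (affected) / 1.38 s (non-affected), arm
sway amplitudes 3.7 / 1.8 m/s² (so that $2A/\pi$ matches the cohort's mean
sway of 2.34 / 1.16 m/s²), affected-thigh dynamic amplitude scaled by 0.7,
sensor noise SD 0.05 m/s² (MEMS accelerometer class at 50 Hz), stride-time
jitter drawn from a normal truncated to the admissible 0.25–3 s band. The
oscillation amplitude is 1.8 m/s² for walkers and 1.1 m/s² for wheelchair
users; a worst-case analysis of a 1-s window over a non-integer number of
sinusoid periods gives a variance floor of about $0.27 A^2$ at 1.4 s
strides, i.e. 0.89 and 0.33 (m/s²)² — above the respective $\theta_3$
thresholds with margin, and mirroring why the wheelchair threshold is lower.
For stride durations beyond roughly 1.6 s that floor sinks below the
walker's threshold: slow gait genuinely contains quiet windows, window
sensitivity degrades, and that is a property of the rule, not of the
generator.

Both sides share the stride-grid start phase (`phase_lag = 0` by default): a
half-stride offset would make the last affected stride overhang the bout and
per-side in-bout stride counts would no longer equal
$\lfloor \text{bout}/\text{stride duration} \rfloor$; asymmetry is modelled
in amplitude, where the pipeline is actually sensitive, and a nonzero
`phase_lag` remains available for pairing experiments. Each recording day
derives its RNG stream from `(seed, day_index)`, so single days reproduce
bit for bit.

What the generator does *not* emulate: soft-tissue and clothing artefacts,
sensor re-orientation drift, turning, stairs, walking aids, gyroscope or
magnetometer channels, and any musculoskeletal realism. Passing tests
therefore show the pipeline implements its contracts, not that it would
reach the same sensitivity on free-living hospital data — the packaged
per-patient validation fixtures are the empirical anchor for that.

## Numerical choices and degenerate inputs

* Resampling: linear interpolation onto the overlap span; empty overlap and
  rate mismatches above 1 % are errors.
* Derivative: first-order central difference (symmetric, phase-neutral) with
  one-sided ends.
* $R^2$ of a zero-variance response is defined as 0 to avoid 0/0.
* Fitted slopes are never bitwise equal; slope differences at floating-point
  noise level (relative $10^{-9}$) are classified parallel.
* A paired test with zero within-pair variance has an undefined statistic:
  identical series give $p = 1$, a constant non-zero offset gives `NA`.
* Zero-stride days report zero counts and absent (`NA`) means; a
  single-segment day has an absent cadence SD.
* Detection scoring is window-level with majority-overlap labelling: the
  published truth-table quantities are percentages of recorded time and the
  1-s window is the pipeline's time quantum; the evaluation granularity was
  not stated and this choice is documented. Undefined ratios (no positive
  or no negative windows) are `NaN`, never 0.
* Constant signals: zero-variance segments are rejected by the periodicity
  filter; flat derivatives yield no peaks.

## Problem sizes in the test-suite

The suite validates on compact instances chosen to exercise every code
path: scripted days of 10 minutes with two walking bouts, single bouts of
36–45 s (25–35 strides), 20 seeds for the detection contract, 200 seeds for
slope and convergence recovery at 30 days, and 50 seeds for the white-noise
rejection rate of the periodicity filter. These sizes keep the full suite
within a couple of minutes while leaving the Monte-Carlo error well inside
the asserted margins.

## Known limitations

* Stride boundaries are derivative peaks, not heel-strike events; absolute
  timing offsets cancel in durations but the method yields no gait-phase
  decomposition, stride length, or velocity.
* Cadence is aggregated unweighted across segments, so short segments weigh
  as much as long ones.
* The five-consecutive-strides rule is anchored on the non-affected side;
  whether the original rule counted per side or combined is unknown.
* Linear trends are a deliberate simplification; recovery is often
  non-linear, and the convergence point extrapolates far beyond the observed
  span, which is why the 10-year cap and the growing-window series exist.
* No multiple-testing correction is applied across parameters.
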