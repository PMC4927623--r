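---
title: "Methods: occupational sEMG activity profiles and group comparison"
author: "semgprofile"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

Sustained, repetitive upper-limb work — the motivating case is
milking-parlor work — loads muscles in ways that are poorly captured by a
single summary number. The accepted practice in occupational sEMG is to
normalize the recorded signal to a subject- and muscle-specific maximal
reference (the functional maximum voluntary contraction, fMVC), and to
describe the resulting amplitude profile by a small set of summaries: the
mean of the RMS envelope, the 10th/50th/90th percentiles of its amplitude
probability distribution function (APDF; static, median and peak load),
and the percent of time at muscular rest (%MR). Published limit values
(static 2/5, median 10/14, peak 50/70 %MVC) then turn a profile into an
exposure verdict, and a mixed ANOVA compares profiles across worker
groups. `semgprofile` implements that pipeline end to end.

# The single-recording pipeline

## Calibration

For each subject × muscle, at least three maximal-effort trials are
scored by the RMS of their **middle 3 s** (the centered window; with
`N` total samples and `W` window samples the window starts at sample
offset `floor((N - W)/2)`, a convention pinned so results are exactly
reproducible). The fMVC denominator is the **maximum** across trials,
matching MVC convention; the mean across trials is available as an
option (`trial_statistic = "mean"`). Fewer than three trials raises a
warning, never an error: field protocols drift, and a usable
calibration beats a discarded subject. An all-zero calibration is a
hard error — normalization is impossible.

The 30-s resting baseline is summarized by its whole-recording RMS and
*reported, not subtracted*: subtraction is not part of the standard
profile definition, and silently offsetting the envelope changes %MR.
An explicit flag (`subtract_baseline = TRUE`) enables envelope-level
subtraction floored at zero for users who want it. Likewise no
band-pass or notch filter runs by default — the profile must be
reproducible from the stated pipeline alone — but an optional
Butterworth pre-filter stage (`bandpass_filter()`, zero-phase, order 4)
can be switched on in the pipeline config.

## Envelope and metrics

The RMS envelope uses a **0.1-s window with a 0.05-s step**. 0.1 s is
the conventional smoothing scale for occupational sEMG amplitude
estimates, and the 0.05-s step resolves the 0.25-s minimum rest gap
with five envelope points. The k-th value covers samples
`[kS, kS + W)`; the trailing partial window is discarded, giving
`floor((N - W)/S) + 1` values. Envelope values are computed from a
cumulative sum of squares (exact to within double rounding; the test
suite checks equality with a brute-force window loop at 1e-12).

APDF percentiles are empirical quantiles with **linear interpolation
between closest order statistics** (`stats::quantile` type 7). The
convention matters at the second decimal on short envelopes, so it is
pinned.

%MR applies the standard gap rule: maximal runs of envelope values **at
or below 0.5 %fMVC** ("maximum threshold" is read as inclusive) whose
span reaches **0.25 s**. Spans are whole envelope steps — a run of `n`
values spans `n × 0.05 s`, with no sub-step interpolation of run
boundaries. That keeps the metric exactly testable (the suite compares
against an explicit run-enumeration oracle) at the cost of a
discretization bias discussed below. Requesting a minimum gap finer
than the envelope step is an error advising a smaller step.

Exposure classification is strict: "should not exceed X" leaves X
itself permissible, so flags trip only for values strictly above the
limit. `exceeds_must_not` implies `exceeds_should_not` by construction
of the ordered thresholds.

# Group comparison

Per-subject metrics go into a long table (group, subject, muscle,
metric, value). Group summaries are means and sample SDs (n − 1) per
group × muscle × metric; single-subject cells report an undefined SD
rather than zero.

The ANOVA follows the random-block layout: each subject is a block that
belongs to exactly one group and contributes one observation per
muscle. We fit

```
value ~ group * muscle + (1 | subject)
```

with sum-to-zero contrasts and type-III F tests using **Satterthwaite**
denominator degrees of freedom (via `lmerTest`). The df method is
pinned in code so runs are reproducible; on balanced complete data the
fixed-effect estimates equal cell means and the layout coincides with
the classical split-plot ANOVA. Subjects missing any muscle for a
metric are dropped listwise with a logged count. Degenerate designs — a
single-subject group, a constant response, fewer than two muscles — are
refused with a diagnostic naming the deficiency, never fitted into a
spurious result.

Simple main effects of group within muscle come from the model's
estimated marginal means (`emmeans`). The adjustment family is the five
within-muscle group contrasts per metric. Tukey's honest significant
difference is defined for all pairwise comparisons of one set of means;
for this family of five non-pairwise contrasts the exact counterpart is
the **multivariate-t adjustment**, which accounts for the contrasts'
correlation the same way the studentized range does for pairs. Its
quadrature is randomized, so it is evaluated under a fixed internal
seed, and adjusted p-values are floored at the unadjusted ones — the
adjustment can never be anti-conservative, a property the test suite
asserts across simulation seeds. Deltas are reported as first group
minus second (manifest order; by convention the large-herd group
first), so relabeling groups negates every delta and leaves p-values
unchanged.

## Monte-Carlo calibration

The interaction test is calibrated by simulation at the metric level
(`simulate_metric_dataset()` draws `cell mean + subject intercept +
residual` directly, skipping signal synthesis): a 2 × 20 × 5 null
design with unit block SD and unit residual SD — the model's own null,
all fixed effects zero — rejects at alpha = 0.05 in ≈ 5% of 500
replicates, and a single-muscle group difference of 2 residual SDs is
detected in ≫ 90% of 200 replicates. The unit block SD reflects that a
random-block design's null still has between-subject variability; the
boundary case (zero block variance) was also checked during
development and stays near nominal.

# The synthetic-data generator

The generator exists so every stage can be scored against known truth.

**Signal model.** A zero-mean Gaussian carrier is band-limited to
20–450 Hz (order-4 zero-phase Butterworth; the standard sEMG bandwidth
at the 1000-Hz sampling rate) and amplitude-modulated by a task
schedule: an ordered list of (label, duration, %MVC) segments that tile
the recording exactly. Each segment is rescaled so its realized RMS
equals `(%MVC / 100) × mvc_reference_amplitude` **exactly**; zero
segments are exactly zero. Exact-by-construction amplitudes keep the
ground truth analytic and the recovery tolerances tight. Transitions
are instantaneous — ramps would blur the rest-bout boundaries that %MR
recovery tests rely on.

**Ground truth** is computed from the schedule, never from realized
noise: the duration-weighted mean amplitude; APDF percentiles of the
duration-weighted discrete amplitude distribution, with the midpoint
convention when a probability lands exactly on the boundary between
two amplitude masses; and the scheduled rest fraction using the *same*
inclusion rule as the %MR metric (consecutive sub-threshold segments
merge into bouts; bouts shorter than the minimum gap do not count), so
recovery is well-posed.

**Seeds.** A master seed deterministically derives child seeds
(`child = (master + 1000003·i) mod (2^31 − 1)`), giving bit-reproducible
cohorts with mutually distinct streams. Identical config + seed yields
identical sample streams; the suite asserts this byte-for-byte.

**Calibration sets** mirror the field protocol: a 30-s baseline at
0.2 %MVC and three 5-s trials at 100 %MVC. **Cohorts** draw each
subject × muscle work intensity as `group truth + Normal(0,
between-subject SD)`, floored at zero, write every recording through
the package's own writer, and return the truth matrix so ANOVA recovery
can be scored. The demo cohort is 2 groups × 6 subjects × 5 muscles
with 60-s recordings — large enough to exercise every code path, small
enough to simulate in seconds.

## Two deliberate design points in the recovery studies

**%MR discretization.** An envelope value counts as rest only if its
whole 0.1-s window lies inside the rest bout, and spans are whole
steps, so each bout is recovered about one window short — a bias of
roughly `window / cycle` duration per rest bout. With 1-s bouts every
3.3 s that bias alone is ≈ 2.5 percentage points on a 30% rest
fraction; with the 3-s bouts of the canonical milking cycle it is
≈ 0.5 points. Micro-breaks at the seconds scale are what parlor work
actually contains, so the canonical cycle (`milking_schedule()`: one
3-s rest bout plus five graded tasks per 10-s cycle) uses 3-s bouts,
and the recovery suite demonstrates %MR within ±2 points of the
scheduled 30%. Sub-second bouts remain measurable but are resolved to
one envelope step per edge; users who need finer gap resolution should
shrink the window and step together.

**Where the median falls.** The schedule's theoretical APDF is a step
function; the realized envelope smears each amplitude level with
sampling noise (relative SD ≈ 8% for a 0.1-s window of 20–450 Hz
noise). If the theoretical median sits exactly at a boundary between
two levels — as it does for any single-work-level schedule with rest —
the empirical median lands a fixed fraction into the adjacent level's
noise distribution and is biased by several percent. The milking cycle
therefore grades its task levels so the median falls *inside* a task
plateau (cumulative mass 0.38 below the 15 %MVC level, which carries
mass 0.25), where the empirical median is an unbiased estimate of the
analytic one. This is a statement about what the analytic ground truth
can promise, not a special case in the metric code.

# Problem sizes and numerical choices

- Recovery studies: 10-minute recordings at 1000 Hz (600k samples), 20
  seeds in the test suite; simulation plus profiling runs in a couple
  of seconds per recording.
- Monte-Carlo calibration: 500 null and 200 powered replicates of the
  2 × 20 × 5 design, ≈ 50 ms per mixed-model fit.
- Envelope/quantile/%MR oracle equivalence: 100 random envelopes of up
  to 1000 points, tolerance 1e-12 relative.
- Floating-point guards: run spans are compared to the minimum gap with
  a 1e-9 slack (so 5 × 0.05 s ≥ 0.25 s holds exactly); schedule segment
  boundaries come from rounded cumulative durations to avoid drift;
  quantile boundary detection in the ground truth uses a 1e-12 slack.
- Report CSVs round to 2 decimals (the convention of published
  tables); `metrics_long.csv` keeps full precision for downstream use.

# What passing tests do and do not show

The generator produces stationary band-limited Gaussian amplitude
modulation with instantaneous transitions. Real sEMG adds motor-unit
structure, electrode and motion artifacts, cross-talk, slow drifts and
non-stationary task execution. Passing recovery tests therefore
validates the *pipeline arithmetic* — normalization, envelope, APDF,
gap analysis, aggregation and inference recover known structure — not
the field validity of sEMG itself. Exposure limit values are published
conventions for task durations of an hour or more; classification of
shorter recordings should be read accordingly. Left/right electrode
pairs are not modeled: one instrumented (dominant-side) channel per
muscle, which is how the motivating field protocol was run.

# Known limitations

- No frequency-domain fatigue indices (median-frequency shift), no
  exposure variation analysis, no gaps-per-minute metrics beyond %MR.
- The mixed ANOVA assumes one observation per subject × muscle; designs
  with replicate recordings per subject need pre-aggregation.
- Exact p-values depend on the denominator-df approximation; deltas and
  estimates are the stable quantities to compare across software.
- The delimited-text reader expects one header line; proprietary binary
  instrument formats must be exported to text first.
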