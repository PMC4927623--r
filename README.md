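# semgprofile

Quantifying occupational muscle load from surface electromyography
(sEMG), for ergonomics and occupational-health researchers who record
muscle activity during real work — the motivating application is
upper-limb load during milking-parlor work, compared between worker
groups (e.g., large-herd vs. small-herd dairy operations).

## What it computes

Given raw sEMG recordings, per-subject calibration recordings (a 30-s
resting baseline and at least three functional maximum voluntary
contraction trials), and a cohort manifest, the package computes for
each subject × muscle:

- **RMS envelope** — moving-window root mean square of the raw signal
  (default 0.1-s window, 0.05-s step), normalized to **%fMVC** where
  fMVC is the maximum across trials of the middle-3-s RMS:
  `fMVC = max_j RMS_3s(trial_j)`, `ẽ(t) = 100 · e(t) / fMVC`.
- **Mean RMS** — the time average of the normalized envelope.
- **APDF percentiles** — the 10th/50th/90th percentiles of the
  envelope's amplitude probability distribution function (static,
  median and peak load).
- **Percent muscular rest (%MR)** — gap analysis: the share of
  recording time in runs where the envelope stays at or below
  0.5 %fMVC for at least 0.25 s.
- **Exposure classification** against published limit values: static
  load 2/5, median load 10/14, peak load 50/70 %MVC
  ("should not" / "must not" exceed).

Groups are compared with a **random-block mixed ANOVA** — fixed
effects group, muscle and group × muscle with a random subject
intercept (the block, nested in group) — followed by Tukey-style
adjusted **simple main effects** of group within each muscle
(multivariate-t adjustment over the five within-muscle contrasts,
Satterthwaite degrees of freedom).

A first-class synthetic-data module generates band-limited,
amplitude-modulated sEMG recordings and whole cohorts with *analytic*
ground truth (segment RMS is exact by construction), so the entire
pipeline is testable end to end without field recordings.

## Worked example

Simulate a 10-minute milking-parlor recording (a repeating 10-s cycle:
one 3-s rest bout plus the five milking tasks at graded intensities,
30% scheduled rest), calibrate, and profile it:

```r
library(semgprofile)

cfg   <- simulation_config(seed = 42)
sched <- milking_schedule(n_cycles = 60)          # 600 s, 30% rest
cal   <- calibrate(simulate_calibration(cfg, seed = 43))
rec   <- simulate_recording(cfg, sched)$recording

build_profile(rec, cal)
#> <muscle_activity_profile>
#>   mean RMS     15.50 %fMVC
#>   APDF p10      0.19 %fMVC
#>   APDF p50     14.96 %fMVC
#>   APDF p90     34.49 %fMVC
#>   %MR          29.50 % of 600.0 s
```

The schedule's analytic ground truth is mean 15.5 %fMVC, median
15 %fMVC, 30% rest: the recovered mean (15.50), median (14.96) and
%MR (29.50) land within the sampling error of a 10-minute recording.
The calibration recovers the simulator's 100 %MVC reference amplitude
(fMVC = 1.0003 against a reference of 1). Classifying the profile:

```r
classify_exposure(build_profile(rec, cal))
#>    load percentile should_not must_not      value             flag
#>  static        p10          2        5  0.1927184           within
#>  median        p50         10       14 14.9559618 exceeds_must_not
#>    peak        p90         50       70 34.4887719           within
```

i.e., this simulated job's median load exceeds both the 10 and the
14 %MVC median-load limits — the same verdict published group-level
biceps profiles receive (`reference_tables()`).

Whole cohorts run end to end from a manifest:

```r
sim <- simulate_command(simulation_config(seed = 1), "demo_cohort")
rep <- run_pipeline(list(manifest = sim$manifest_path), out_dir = "demo_out")
rep$simple_effects$mean_rms     # per-muscle group estimates, deltas, adjusted p
```

A thin command-line wrapper with `simulate` and `analyze` subcommands
is installed at `inst/scripts/semg-pipeline.R`.

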