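---
title: "Building scheduled PRM assays from DIA translation libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building scheduled PRM assays from DIA translation libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prmsched)
```

## The problem

Nominal-mass instruments (linear ion traps, triple quadrupoles) are fast and
sensitive but cannot resolve precursors by exact mass, so targeted parallel
reaction monitoring (PRM) on them depends entirely on *scheduling*: each
peptide precursor is monitored only inside a retention-time window, and the
number of concurrently monitored targets — the **assay density** — is bounded
by the cycle-time budget. prmsched turns a "translation library" (peptides
with instrument-specific retention times and fragmentation, typically
exported from a gas-phase-fractionated DIA experiment on the same instrument
and gradient) into a scheduled PRM inclusion list, and provides the
surrounding arithmetic: acquisition feasibility, matrix-matched background
design, and calibration-curve figures of merit.

## Candidate ranking

PRM convention requires at least three quantifiable transitions per peptide,
so candidates are ordered by the intensity of their **third-largest fragment
ion** (`rank_candidates()`): a peptide whose third-best fragment is intense
can be quantified on at least three strong transitions. Entries with fewer
than three fragments are never promoted to candidates. The ordering must be
reproducible run-to-run, so ties are broken by descending total fragment
intensity, then ascending precursor m/z, then sequence. Each precursor
(sequence, charge) is an independent candidate: the scheduler places
precursors, not peptide sequences.

Shared peptides default to exclusion (`proteotypic_only = TRUE`), the
conservative SRM/PRM convention: quantity attributed to a protein should
come from peptides unique to it. Inclusion-list peptides are promoted ahead
of all other candidates but keep their relative order, and exclusion-list
peptides are removed before anything else.

## Retention-time re-calibration

Library retention times were measured on an earlier injection; column aging
and re-equilibration shift them. `fit_rt_mapping()` maps library times onto
anchors from a recent DIA injection. Two families are offered because the
drift shape is not knowable in advance:

* `linear` — ordinary least squares, for well-behaved columns (≥ 2 anchors);
* `monotone_smooth` (default) — a monotone piecewise-cubic interpolant
  through 2-minute bin medians, isotonised so the mapping can never invert
  elution order (≥ 10 anchors).

Anchors from mis-assigned peptides sit minutes off the trend. They are
rejected by iterative trimming at 3 × MAD of residuals (at most 5 rounds)
against a **straight-line prefit** rather than the smoother itself: genuine
drift curvature is sub-minute while gross mis-assignments are minutes, so
the line separates them cleanly, whereas a fine interpolant would chase the
very anchors it should reject and deflate the MAD. Outside the anchor range
the mapping extrapolates linearly from the terminal knots; the scheduler
widens any window touching that region by the mapping's residual SD on each
side, trading a little density for robustness where the calibration is
least trustworthy.

The 2-minute default bin width balances knot noise (about 3–7 anchors per
bin on a typical 100-anchor, 60-minute calibration) against flexibility;
with fewer than two occupied bins the fit refuses and suggests the linear
method.

## The greedy scheduler

`build_schedule()` visits candidates once in rank order. A candidate's
window is `rt_window_min` wide, centered on its mapped retention time and
clipped to the gradient. It is accepted iff

1. no time point of its window would exceed `max_assay_density`, and
2. none of its proteins has reached `peptides_per_protein_cap` (default 5)
   accepted peptides.

"Time point" is continuous: the density check is an exact closed-interval
overlap maximum (evaluated at interval boundaries, where a step function of
closed intervals attains its maximum), never a discretized grid. Candidates
whose mapped time leaves the gradient are skipped as `out_of_gradient`
rather than clipped, since a window pinned to the gradient edge would no
longer bracket the peak. Every candidate lands in exactly one of
`targets` or `skipped` (with its reason), which is what the scheduling
report serialises.

Isolation windows are `isolation_width_mz` (default 2 Th) wide and centered
`0.25/z` Th above the precursor m/z so the window spans the monoisotopic
and +1 isotopes; the offset is a documented configuration default.

Tiered assays (`build_tiered_assays()`) rebuild from the same candidate
bank at several density budgets — e.g. 10, 20 and 50 peptides per cycle for
1, 10 and 100 ng input — because lower loads need longer fill times and
therefore fewer concurrent targets (see below).

### A subtlety: density monotonicity is a tendency, not a theorem

It is tempting to assume that raising `max_assay_density` can only add
targets. For single-pass greedy interval packing this is *almost always*
true but not guaranteed: a larger budget admits extra early candidates
whose windows can stack inside a later candidate's window and crowd it out;
and when the per-protein cap binds, a larger budget admits a protein's
higher-ranked peptides, which then consume its cap and displace
lower-ranked ones that were previously scheduled. In randomized experiments
(100 instances, cap non-binding) we observe a violation rate of a few
percent from the interval mechanism alone. Practically this means tiered
assays should be compared by what each tier schedules, not assumed to nest.

## Acquisition feasibility

The cycle-time model is injection-time dominated: with `n` concurrent
targets each allotted `maxIIT` milliseconds (plus a per-scan overhead,
default 0 ms with 5 ms a realistic allowance for ion routing),

> cycle time = n × (maxIIT + overhead) / 1000 seconds.

Ten targets at 200 ms fill a 2-second cycle; twenty targets fit the same
budget at 95 ms once a 5 ms routing overhead is charged. This is a
worst-case bound — at high load scans rarely fill — and the package labels
it as such. `points_per_peak()` divides the chromatographic peak width
(about 15 s on a 60-minute gradient) by the cycle time: 2-second cycles
give at least 7–8 points across the base, sufficient for quantification.
`gpf_windows()` tiles a precursor range with contiguous narrow windows
(2 Th default); six 100 m/z gas-phase fractions from 400 to 1000 m/z yield
300 windows with no gaps, the configuration used to build translation
libraries on the targeting instrument itself.

## Matrix-matched background design

Diluting an analyte in buffer flatters linearity because background noise
falls with the analyte. A matrix-matched curve instead holds the background
constant: the same proteome, dimethyl-labeled on every free amine
(N-terminus plus lysines, +28 Da nominal per complete label, 14.01565 Da
per methyl), is used as diluent. `check_background_exclusion()` verifies
the design premise peptide by peptide: even a single residual methyl shifts
the precursor by `14.016/z` Th — at least 1.75 Th at charge 8 — which
clears the 1 Th half-width of a 2 Th isolation window for every tryptic
peptide. Because labeling happens after digestion, site counting on tryptic
peptides is exact. `plan_matrix_curve()` emits mixing tables in which
foreground + background equals the total load at every dilution point, the
constant-matrix property.

## Figures of merit

`fit_lod_loq()` fits the bilinear model behind matrix-matched calibration
curves: a horizontal "maximum line through the noise" (the median of the
plateau) and a straight line through the linear dynamic range. Every
changepoint along the ordered ratios is scored by total squared residual
and the best split wins; the **LoD** is the intersection abscissa of the
two lines, the **LoQ** the abscissa where the linear fit crosses the noise
level plus three noise SDs, which guarantees LoQ ≥ LoD whenever both exist.

Numerical choices, made once and documented here:

* Fitting axes are log10(ratio) vs log10(intensity) by default, matching
  decade-spaced dilution designs; a linear-axes option exists. A
  proportional (through-origin) response is exactly linear on log axes.
* Replicates are averaged within a ratio for segment fitting; all plateau
  replicates contribute to the noise SD.
* The linear fit is unweighted least squares.
* An LoQ is assigned only when the linear segment has ≥ 3 points, a
  positive slope distinguishable from zero (t-test at 0.05, or an exact
  fit), **and** climbs at least three noise SDs above the plateau. The last
  condition makes the background-only outcome ("not assignable")
  deterministic instead of an accident of the slope test's 5% false-positive
  rate. Curves with fewer than 4 distinct ratios cannot support two
  segments and are rejected outright.

`percent_cv()` (100 × SD/mean) and `all_pairs_log2fc()` (every replicate of
one condition against every replicate of the other; two triplicates give 9
ratios) summarise replicate precision and between-condition effect spread.
`classify_vs_fom()` places a measured ratio relative to the fitted LoD/LoQ
interval.

## What the synthetic generators emulate — and what they do not

The generators (`synth_library()`, `synth_rt_anchors()`,
`synth_calibration_curve()`) exist so every module is testable without
instrument data. They draw from per-generator streams derived from
(seed, generator name), so outputs are bit-for-bit reproducible and adding
a generator never perturbs another's fixtures; the caller's RNG state is
restored afterwards.

* Libraries: random tryptic peptides (ending K/R, no internal cleavage
  sites), charges 2–3 with m/z from monoisotopic residue masses, uniform
  retention times over a 60-minute gradient, 3–12 fragments with log-normal
  intensities.
* Anchors: a chosen drift (identity, affine, or a logistic column-aging
  warp) plus Gaussian noise (0.1 min default) and a configurable fraction
  of gross outliers displaced by 5–15 min.
* Curves: `max(plateau, slope × ratio)` plus Gaussian replicate noise, with
  the analytic intersection recorded as truth.

They do **not** simulate isotope envelopes, chromatographic peak shapes,
interference between co-isolated peptides, intensity-dependent RT errors,
or heteroscedastic noise. Passing recovery tests therefore demonstrates the
estimators' correctness under clean, known generative conditions — not
performance on real chromatograms, where anchor quality and background
interference dominate.

Test problem sizes are the package's own defaults: 100-anchor calibrations,
scheduling instances up to 500 candidates, 500 simulated calibration
curves. These are the scales at which the estimators' behaviour stabilises
while the whole suite stays fast enough to run habitually.

## Known limitations

* The scheduler is single-pass greedy; it does not re-sort remaining
  candidates after each acceptance and does not backtrack, so it can leave
  density unused that a re-ordering would exploit. This matches the
  one-workday design goal: determinism and transparency over optimality.
* Density monotonicity across tiers is a strong tendency, not a guarantee
  (see above).
* The bilinear LoD/LoQ objective (changepoint + least squares on log axes)
  is this package's definition, validated by simulation; other curve-fitting
  tools may place changepoints slightly differently on noisy data.
* Fragment-level collisions between labeled background and foreground
  transitions are not checked; the background-exclusion argument is made at
  the precursor isolation level.
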