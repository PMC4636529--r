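---
title: "Windowed error correction for beat-to-beat heart-rate data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed error correction for beat-to-beat heart-rate data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avechr)
```

## The problem

Chest-belt heart-rate monitors (the Polar RS800CX and its relatives) record
instantaneous heart rate beat by beat, between 15 and 240 bpm. Used on dogs,
the recordings combine two things that are individually manageable and
jointly awkward:

* **Large genuine variability.** Canine heart rate is dominated by
  respiratory sinus arrhythmia (RSA): rate swings of tens of bpm locked to
  the breathing cycle. Global outlier rules — anything that compares a beat
  with the distribution of the whole recording — will flag healthy beats
  wholesale.
* **Transmission artifacts.** Movement of the belt, wet-contact loss and
  electromagnetic interference produce isolated spikes towards the edges of
  the recordable range, missed beats (two true intervals fused into one
  roughly doubled RR interval) and spurious extra beats (one interval split
  into two halves).

Time-domain heart-rate-variability (HRV) statistics are exquisitely
sensitive to both kinds of event, so the correction method determines the
analysis. `avechr` implements a *local* criterion: each beat is judged only
against its immediate neighbours, which is what makes the method usable on
series whose global variance is dominated by RSA.

## The outlier criterion

A candidate beat $x_g$ is compared with the $n$ values surrounding it
(default: 20 on each side, so $n = 40$; the 41-value string spans roughly
30 s at canine rates). With $\bar{x}$ and $s$ the mean and sample standard
deviation of the window *excluding* the candidate, $x_g$ is an error when

$$|x_g - \bar{x}| > k\,|s|.$$

The multiplier $k$ is derived from a confidence level $P$ through the
two-sided standard-normal band mass

$$\operatorname{Erf}\!\left(\frac{\lambda}{\sqrt{2}}\right) =
\frac{1}{\sqrt{2\pi}} \int_{-\lambda}^{+\lambda} e^{-t^2/2}\,dt = P,$$

and the Graf–Henning correction for the fact that $\bar{x}$ and $s$ are
estimated from a finite window rather than known:

$$k = \frac{2(n-1)}{2(n-1)-\lambda_b^2}\left[\lambda_a +
\lambda_b\sqrt{\frac{n\lambda_a^2 + 2(n-1) - \lambda_b^2}{2n(n-1)}}\right].$$

With $\lambda_b = 0$ this collapses to $k = \lambda_a$, and $k \downarrow
\lambda_a$ as $n \to \infty$ at rate $O(n^{-1/2})$ — the correction terms
are exactly the finite-window inflation.

```{r k-values}
lambda <- solve_lambda(0.75)
lambda
compute_k(lambda, lambda, n = 40)
```

**Resolving $\lambda_a$ and $\lambda_b$.** The historical presentation
defines $\lambda_a$ and $\lambda_b$ as solutions of a pair of equations
tied to the confidence level; the accessible sources do not reproduce the
pair explicitly. The package's default (`lambda_mode = "equal"`) takes
$\lambda_a = \lambda_b = \lambda_P$ with
$\operatorname{Erf}(\lambda_P/\sqrt2) = P$, which keeps the printed $k$
formula intact and isolates the one under-determined constant; users with
access to the original tabulations can supply the pair directly
(`lambda_mode = "explicit"`). This default is a documented stand-in, not a
claim about the original source.

**Choice of $P$.** The default $P = 0.75$ is deliberate: a lower $P$
shrinks $k$ and flags more readily, preferring the deletion of an
occasional genuine beat over a missed artifact — the right trade-off for
HRV work, where one surviving artifact distorts RMSSD far more than one
missing beat. At $P = 0.75$, $n = 40$, the threshold is $k \approx 1.41$
window standard deviations.

**Why base R's normal functions.** The band mass and its inverse are exact
compositions of `pnorm()`/`qnorm()`; the package computes them that way
rather than through bespoke quadrature. Independence of the validation is
preserved in the test suite, where the same quantities are recomputed with
composite-Simpson quadrature (up to $10^6$ panels) and
bisection-over-quadrature, and the two routes are required to agree to
$10^{-9}$.

## Scanning a series: single pass, most extreme first

`scan_series()` tests every beat with sufficient context against its
surrounding window, always on the **original** data — the single-step
convention: the candidate set is fixed in one pass, never grown by
iterative delete-and-rescan. Two refinements:

* **Boundaries.** A beat needs at least `min_half_window` (default 10)
  neighbours on *each* side to be testable; closer to an edge it is
  reported `untested`, which is deliberately distinguishable from "tested
  and clean". Between 10 and 20 beats from an end, a truncated window is
  used and $k$ is recomputed for the actual window size.
* **Overlapping candidates.** When several flagged beats share windows,
  `resolve_overlaps()` plans the most extreme one (largest
  $|x_g-\bar{x}|/s$) first, then re-tests the remaining candidates of the
  group against the re-formed window — the surviving values joined across
  the gap, exactly as a split series is recombined after deletion — and
  drops candidates that a more extreme neighbour fully explains. The
  candidate set never grows here; it can only shrink.

One consequence worth understanding: a *moderate* artifact adjacent to an
*extreme* one is often invisible to the single-pass criterion, because the
extreme value inflates the moderate one's window SD. A 238-bpm spike
followed by a 102-bpm drop on a 120-bpm baseline leaves the drop unflagged
($|102 - 122.95| = 20.95 < k s = 26.3$). This masking is structural, not a
bug, and it is precisely why the method is *algorithm-supported visual*
correction rather than a fully automatic filter: such pairs are obvious to
the eye in a 200-beat block plot and enter the pipeline as manual
deletions (`read_manual_edits()` + `correct_series()`), applied before the
algorithmic scan.

```{r masking}
vals <- rep(120, 120)
vals[61:62] <- c(238, 102)
scan_series(beat_series(vals, "bpm"))$flagged_indices # only the 238
```

### Calibration on null data

On i.i.d. normal windows with no true outliers, the statistic
$(x_g-\bar{x})/s$ has the exact law $\sqrt{1+1/n}\;t_{n-1}$, so the null
flag rate at threshold $k$ is $2\,[1 - F_{t_{39}}(k/\sqrt{1+1/40})]
\approx 0.172$ at the defaults, slightly above the asymptotic normal tail
$2\,[1-\Phi(k)] \approx 0.159$; the gap ($\approx 0.013$) is the
finite-window $t$ correction and vanishes as the window grows. The test
suite pins the empirical rate to the exact $t$ law. Note what this
implies: at $P = 0.75$ the criterion flags roughly a sixth of *perfectly
clean uncorrelated* data. On real recordings the flag rate is far lower,
because genuine physiological windows are smooth and wide — their SD
absorbs the local swings — and flagged fractions below 1 % are typical. The
criterion is a decision aid under human review, not an unattended filter,
and the 5 % exclusion rule applies to the reviewed error count.

## Correction and its contracts

Two strategies, both logged beat by beat in a `correction_log`:

* **delete** — flagged beats are removed and the split series is joined;
* **replace_mean** — each flagged beat is replaced by the mean of the 5
  preceding and 5 subsequent *surviving* values (minimum 3 per side near a
  boundary).

Neither strategy can insert a value or reorder survivors, so the corrected
series is always at most as long as the original and every surviving value
keeps its original beat index — there is no time shift, by construction.
`replay_log()` reproduces the corrected series exactly from the original
plus the log, which is what makes a correction auditable and reversible.

Recordings in which more than 5 % of beats are flagged are excluded from
analysis (`exclusion_check()`); the inequality is strict, so exactly 5 of
100 flagged beats is retained.

## Time-domain HRV

`hrv_summary()` computes, on the series exactly as passed (no detrending
or interpolation):

* SDNN — sample SD of RR (ms);
* RMSSD — root mean square of successive RR differences (ms);
* pNN50 — percentage of successive differences strictly exceeding 50 ms,
  out of the $n-1$ pairs;
* mean/median/sample SD of heart rate, in bpm.

HRV is always computed on the ms representation, HR statistics on bpm, and
all denominators are the $n-1$ sample convention. These are the standard
task-force definitions; no vendor-specific preprocessing is emulated, so
numeric agreement with any particular HRV program's output is only
expected when that program's own preprocessing is switched off.

## The perturbation experiment

`perturbation_experiment()` quantifies how each correction strategy
distorts an artifact-free series: for fractions of 1–5 % it draws random
beat positions (avoiding the first and last 5 beats so mean replacement is
always defined), applies each strategy to the same positions, and reports
percent change in every summary. On RSA-dominated series, replacing beats
with a 10-neighbour local mean *smooths* — systematically biasing RMSSD
down — while deletion perturbs both ways with smaller systematic effect;
mean replacement moves RMSSD more in absolute value in the clear majority
of replicates. That asymmetry is the quantitative argument for deletion as
the default strategy.

## The synthetic generator

Real canine recordings cannot ship with the package, so validation runs on
a generator that reproduces the features the pipeline's contracts depend
on:

$$\mathrm{hr}_i = \text{baseline} + A \sin(2\pi f\, t_i + \varphi) +
\varepsilon_i, \qquad \varepsilon_i \sim N(0, \sigma^2),$$

with $t_i$ the *cumulative RR time* — breathing happens in real time, not
in beat count — and values clipped to the device range. Defaults:
baseline 90 bpm, $A = 15$ bpm, $f = 0.4$ Hz (resting-dog respiratory
band), $\sigma = 3$ bpm, 600 beats ($\approx$ 6–7 min, the order of a
staged-test segment plus recovery). At these settings a breathing cycle
spans only $\sim$4 beats, so consecutive beats differ by tens of bpm —
exactly the high short-term variability that defeats global filters.

Two quirks of the model are worth knowing. First, because beats sample the
sinusoid in proportion to the instantaneous rate, the *beat-averaged* mean
sits about $A^2/(2\cdot\text{baseline}) \approx 1$ bpm above the baseline;
this is a property of beat-domain averaging, not a bug. Second, in the
beat-index domain the oscillation appears at $f \cdot \overline{RR}
\approx 0.27$ cycles/beat, which is where the periodogram check looks for
it.

`inject_artifacts()` adds labelled spikes (bpm domain), missed beats and
extra beats (ms domain, merging or splitting intervals), at seeded Binomial
counts on disjoint, non-adjacent positions. The default spike magnitude is
80 bpm from baseline: transmission spikes in real recordings shoot towards
the edges of the recordable range (a 238-bpm excursion on a 120-bpm
baseline is typical), not a few noise SDs. Detection sensitivity is
assessed over spikes at *tested* positions — a spike within 10 beats of
the series end is reported untested, which the workflow surfaces to the
reviewer rather than silently passing.

What the generator does **not** emulate: non-stationary baselines (stress
onsets, pacification), breathing-rate drift, breed differences, genuine
arrhythmic events, or correlated burst noise. Passing the synthetic
validation therefore shows that the machinery honours its contracts under
realistic variability; it does not certify performance on any particular
real recording, which is why the visual pass remains part of the method.

## Numerical and design choices

* Window SD uses the sample ($n-1$) denominator; the `n` entering the $k$
  formula is the number of values actually used (candidate excluded;
  `n_convention = "include_candidate"` is available).
* A zero-variance window is handled by reading the criterion literally:
  any nonzero deviation exceeds $k \cdot 0$; an exactly equal value does
  not flag.
* Priority ordering uses $|x_g-\bar{x}|/\max(s, 10^{-12})$, so
  zero-variance windows sort first, as they should.
* Detection defaults to bpm (artifacts present as sharp rate excursions);
  HRV always works in ms. The two representations are exact reciprocals
  (`hr = 60000/rr`), and conversion round-trips to $<10^{-12}$ relative.
* CSV I/O formats doubles with 17 significant digits and parses them with
  R's own reader, making write-read cycles bit-exact. HRM files store
  integer milliseconds, matching the format and the device's ±1 ms
  accuracy.
* Beat indices are 0-based everywhere on disk and in logs; plots label
  1-based beat numbers, the convention used when reading figures.
* Problem sizes in the validation suite — $10^5$ null windows, 50 seeded
  recordings of 600 beats for spike recovery, 100 perturbation replicates,
  1000 random plans/series for the contract and HRV checks — are the
  package's chosen validation scale.

## Limitations

The method requires an experienced reviewer and is practical for minutes,
not hours, of data. The equal-$\lambda$ default is a stand-in for the
original paired defining equations (see above). Frequency-domain and
nonlinear HRV are out of scope, as is any emulation of proprietary vendor
filters; the package characterises only its own behaviour.
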