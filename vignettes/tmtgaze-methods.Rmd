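---
title: "Methods: scoring and test-retest reliability of an eye-tracked Trail Making Test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and test-retest reliability of an eye-tracked Trail Making Test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmtgaze)
```

## The task and its measures

The computerized Trail Making Test (TMT) asks a participant to click, with a
mouse, through 25 circular targets in sequence: numbers 1--25 in part A, or
alternating numbers and letters (1, A, 2, B, ..., 13) in part B. Targets sit
one per cell of a 5 x 5 grid of 4.32 degree cells; each circle has a 1.35
degree diameter and neighbouring target centres are at least 1.35 degrees
apart. Before each trial the participant is instructed to emphasise either
speed or accuracy (clicking as centrally as possible). The design crosses two
sessions x two parts x two instructions, with two scored trials per cell, and
gaze is recorded monocularly at 1000 Hz.

Nine scores are computed per trial:

1. **Completion time** (s): from the trial-initiating click on the central
   fixation cross to the first *correct* click on the last target. We read
   "first click on the last target" as the first correct one -- a miss does
   not land *on* the target -- and expose this as a toggle.
2. **Speed-accuracy slope**: per-target click accuracy (1 at the target
   centre, 0 at the circumcircle, linear in between) is clipped to
   `[eps, 1 - eps]` (`eps = 0.01`), transformed to log-odds and regressed on
   the per-target reaction time (interval between consecutive correct clicks;
   error clicks do not reset the clock). Accuracy is the response and
   reaction time the predictor; the slope is in log-odds per ms.
3. **Median fixation duration** (ms) and 4.--6. **numbers of all / guiding /
   searching fixations**: a fixation within 3.25 degrees of at least one
   target centre is assigned to the nearest such target, ties going to the
   lower sequence index; it is *guiding* if that target is the current
   (lowest un-hit) target at fixation onset and *searching* otherwise.
   Fixations farther than 3.25 degrees from every target count only in the
   total.
7. **Median saccade amplitude** (degrees).
8. **Eye-hand span** (ms): per target, the correct click time minus the onset
   of the first fixation on that target within its episode -- the window from
   the previous correct click to 200 ms after the target's own correct click.
   The trial value is the median across targets. The grace window makes
   negative spans (the hand arriving before the eyes) representable, which a
   strict "current target at onset" labelling cannot, and the first-vs-last
   anchor is a parameter. The per-trial aggregation (median) is our choice;
   the mean is one `apply` away from the per-target spans.
9. **Scanpath length** (degrees): summed distance between consecutive
   fixation centroids, approximately the sum of saccade amplitudes.

## Event detection

Raw gaze samples are converted from pixels to degrees with the screen
geometry (1024 x 768 px = 36 x 27 cm at 71 cm by default; origin at the
screen centre, per-axis angle `atan(offset_cm / distance)`). Detection then
follows the velocity/acceleration scheme of research-grade trackers:

* positions are smoothed with a 5-sample moving average; velocity and
  acceleration come from central finite differences;
* samples at or above 30 deg/s or 8000 deg/s^2 form saccade cores;
* each core is extended outward while the velocity decreases monotonically
  and stays above a floor of 10 deg/s. The extension recovers the whole ramp
  of a smooth saccade profile rather than only its suprathreshold middle;
  without it, adjacent fixation durations are systematically inflated by
  about two samples, which would defeat sample-accurate round-trip checks
  against planted ground truth;
* the complementary runs are fixations (centroid = mean of member samples);
* runs of invalid samples of at least 10 ms are blinks; shorter dropouts are
  treated as tracker noise and linearly interpolated. Fixations and saccades
  overlapping any blink window extended by 50 ms on both sides are removed.
  Blink exclusion runs *before* the duration/amplitude filters, so a short
  fixation fragment bordering a blink is excluded for the blink, not kept by
  the filter;
* the standard filters then drop fixations shorter than 50 ms and saccades
  smaller than 0.1 degrees (microsaccades). Boundary values stay (a 50 ms
  fixation and a 0.10 degree saccade are retained).

Degenerate traces (no valid samples) produce empty event lists with a
warning; traces shorter than the smoothing window are an error.

## Reliability statistics

Per score and condition, trials are averaged within subject and session,
giving an n x 2 table. Subjects missing a cell are dropped from that table
(listwise deletion with a message); the reliability functions require
complete tables.

**ICC(A,2).** With mean squares from the two-way subjects x sessions
decomposition (`MS_R` rows, `MS_C` columns, `MS_E` error),

$$\mathrm{ICC}(A,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n}, \qquad k = 2.$$

The 95% CI uses the mixed-effects F-based construction for absolute
agreement: bounds for the single-measures coefficient, stepped up to average
measures through the Spearman-Brown relation \(r_k = kr/(1+(k-1)r)\). That
relation has a pole at \(r = -1/(k-1)\); single-measures bounds at or below
it map to \(-1\), and the interval is forced to contain the point estimate,
so strongly negative sample ICCs cannot produce bounds outside the parameter
space. A perfect-agreement table returns exactly 1 with a point interval; a
constant table is an error. Estimates are classified excellent (> 0.80),
good (> 0.60), moderate (> 0.40) or poor otherwise; because the conventional
printed bounds overlap at 0.40/0.60/0.80, boundary values go to the lower
class, consistent with "excellent" being strictly above 0.80.

**Bland-Altman.** For differences `d = session1 - session2` (positive =
larger in session one): bias = mean(d) with a t-based CI; limits of agreement
bias +/- 1.96 sd(d) with the classical standard-error approximation
`sd(d) * sqrt(3/n)` (other conventions exist; the multiplier and the SE
formula are isolated for swapping); and the proportional-bias slope from
regressing `d` on the per-subject means, with its two-sided p-value and
stars at 0.05/0.01/0.001, unadjusted for multiplicity.

## The precision simulation

To know what CI widths a given sample size can deliver, the package
simulates a population of 100,000 individuals whose paired session scores
are bivariate normal with equal means and variances and correlation equal to
the predefined ICC, draws repeated subsamples of size n without replacement,
computes the F-based 95% CI of ICC(A,2) on each, and averages the lower and
upper bounds across replicates (10,000 by default; mean-of-bounds is the
default aggregation, with median bounds and percentile-of-estimates
available because the aggregation is a genuine design choice). Degenerate
subsamples are redrawn and counted.

Two parameterisation notes. First, the population quantity is set through
the *pair correlation*: a correlation of rho implies a population
single-measures ICC of rho and an average-measures ICC of
\(2\rho/(1+\rho)\). Setting the correlation directly (rather than inverting
the Spearman-Brown relation) is what reproduces the published precision grid
for this design, which we verified numerically both ways before fixing the
choice. Second, for the same reason, coverage checks of the ICC(A,2)
interval must target \(2\rho/(1+\rho)\): at n = 31 the interval covers that
value at almost exactly the nominal 95% rate (and would cover rho itself at
only ~65% for rho = 0.8).

## The synthetic-data generator

No raw participant data accompany the study this package operationalises, so
the generator is a first-class module that emulates the design with known
ground truth:

* **Layouts**: one target per grid cell, uniform within the cell inset by
  the target radius, rejection-sampled per cell until the 1.35 degree
  centre-to-centre minimum holds (degree-space check; the budget-exhausted
  case is an error). We enforce the minimum centre distance exactly as
  conventionally stated even though 1.35 degrees equals one target diameter,
  and expose the threshold. Sequence labels are assigned to cells at random;
  layouts are reused across sessions, mirroring a retest with identical
  arrangements.
* **Cohorts**: each latent trait (mean fixation duration, searching rate per
  target, eye-hand lag, click dispersion) is bivariate normal across
  sessions with correlation equal to its configured ICC, floored at a
  physical bound at least ~3 SD below the mean. Defaults (175 +/- 15 ms,
  4.9 +/- 1.1 per target, 1000 +/- 250 ms, 0.25 +/- 0.06 deg) match the
  order of magnitude of published descriptives for healthy adults.
* **Trials**: per target, a Poisson number of searching fixations on other
  targets and one guiding fixation near the current target (Gamma durations,
  shape 8 -- positive, right-skewed, two-parameter families; nothing in the
  design dictates the family), then a click at the guiding onset plus the
  subject's lag plus Gaussian noise, positioned with the subject's
  dispersion; misses are recorded and retried with shrinking dispersion, so
  error clicks arise naturally. The accuracy instruction halves dispersion
  and multiplies the lag by 1.5. Saccade durations follow the main-sequence
  approximation `2.2 ms/deg x amplitude + 21 ms`.
* **Raw traces**: fixations render as centroid plus isotropic jitter,
  inter-fixation gaps as raised-cosine ramps (any smooth profile exceeding
  the 30 deg/s threshold for amplitudes of ~0.5 degrees and above would do),
  blinks as invalid samples. Training trials (8 targets) are not simulated;
  they contribute no scores.

What the generator does *not* emulate -- smooth pursuit, drift and
calibration error, pupil dynamics, asymmetric or correlated click errors,
tracking loss (the study design reports none) -- bounds what passing tests
show: they establish that the pipeline recovers known structure from data
obeying its assumptions, not that those assumptions hold for any particular
tracker or population.

## Numerical choices and problem sizes

Exact round-trip tests use noise-free configurations (zero lag noise, zero
or near-zero dispersion and jitter), where planted counts, lags, scanpaths
and completion times are recovered exactly and planted event timings to
within one sample at 1000 Hz. The test suite runs the precision grid at
1,000 replicates per cell, trait-recovery coverage at 1,000 cohorts per ICC
level, and the end-to-end reliability pipeline at 4--16 subjects; the
acceptance script uses 2,000 replicates per cell on the full 100,000-person
population. These sizes keep the Monte-Carlo standard error of every checked
quantity an order of magnitude below its tolerance. All randomness flows
from a single master seed through tagged child streams, so every artifact is
bit-reproducible.

## Known limitations

* The detector is a threshold classifier; it does not model smooth pursuit
  and will label slow drift as fixation. Saccades below ~0.5 degrees at
  main-sequence durations fall under the velocity threshold and merge into
  their neighbouring fixations -- the 0.1 degree amplitude filter is only
  meaningful for saccades the thresholds can see.
* The ICC confidence interval is the F-based approximation; it is not exact
  for unbalanced or strongly non-normal tables.
* The Bland-Altman LOA standard error is the classical large-sample
  approximation.
* `eye_hand_span`'s episode window (200 ms grace) is a convention; spans for
  targets refixated much later than their click are not captured.
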