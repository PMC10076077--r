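---
title: "Model and methods behind gazehmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind gazehmm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The classification problem

Eye-tracking research routinely needs raw gaze samples segmented into
oculomotor events — fixations, saccades, post-saccadic oscillations
(PSOs) and smooth pursuits — before any substantive analysis.
Threshold-based detectors require the analyst to hand-pick cutoffs per
recording; gazehmm instead fits a generative hidden Markov model to each
recording, so the event-specific feature distributions are *estimated*
from the data and the only substantive user choice is how many event
classes to model (2 = fixations/saccades, 3 adds PSOs, 4 adds pursuit).
The package assumes a fixed head (chin-rest), a stationary screen-mounted
tracker, and positions already calibrated to degrees of visual angle.

## Features

Three per-sample features feed the model:

* **velocity** (deg/s) and **acceleration** (deg/s²): Euclidean norms of
  the first and second Savitzky–Golay-filtered derivatives of the (x, y)
  position. The filter's settings are not dictated by the model; the
  package defaults to polynomial order 2 and a ~20 ms window rounded to
  an odd number of samples (minimum 5), the canonical configuration of
  velocity-based event detection at 250–1000 Hz. Both are configurable
  (`sg_window_ms`, `sg_polyorder`). Acceleration is the norm of the
  second-derivative vector — guaranteed non-negative, matching the gamma
  support — rather than the signed derivative of speed.
* **sample-to-sample angle** (radians): the signed planar angle between
  the displacement vectors entering and leaving a sample,
  counter-clockwise positive, wrapped to [0, 2π) by adding 2π to
  negative values. Angles are undefined at the series boundary and at
  zero-length displacements; such samples are treated as missing, never
  imputed.

Samples within 50 ms of a blink (`blink_pad_ms`) are flagged missing
before fitting, because trackers often record spuriously fast samples
while losing the pupil. Velocity and acceleration are divided by
`scale_factor` (100 for classification, 10 in the simulation defaults)
before fitting; gammas are a scale family, so this only moves the scale
parameters (reported back on the raw scale by `coef(fit, scale = "raw")`)
and improves the conditioning of the fits. Near-zero feature values are
clamped at 1e-6 (post-scaling) before density evaluation, since the gamma
density is degenerate at 0 for shapes below 1; the clamp is orders of
magnitude below any physiologically meaningful velocity and does not
move the estimates.

## The generative model

A hidden state $S_t \in \{1, \dots, k\}$, $k \le 5$, evolves as a
first-order Markov chain with initial probabilities $\rho$ and transition
matrix $A$. Given the state, the three features are conditionally
independent:

* velocity and acceleration are gamma with state-specific shape and
  scale,
* the angle is circular-uniform for state 1 (fixation drift has no
  preferred direction) and von Mises (mean $\mu$, concentration
  $\kappa$) for states 2+ — saccades cluster near 0 (direction is
  maintained), PSOs near $\pi$ (direction reversals), pursuit near 0.

Conditional independence of velocity and acceleration is knowingly
approximate (the two are physically correlated); it keeps the model
simple and identifiable. Event semantics are attached by the starting
values, not enforced: after fitting, `sanity_check()` warns if state 1
does not have the lowest or state 2 the highest mean velocity, and never
silently permutes states. A fifth state is supported for exploratory
model comparison only and carries no event name.

Missing samples are integrated out: their emission density is exactly
one, so they influence the fit only through the transition structure.

## Estimation

Parameters are estimated by EM. The E-step is the scaled
forward–backward recursion (implemented in C++, with per-row maxima of
the emission log-densities factored out so extreme likelihood ratios
cannot underflow). The M-step is exact: $\rho$ and $A$ update in closed
form from expected counts, and each state's emission parameters maximize
the expected complete-data log-likelihood directly — Newton iteration on
the profile equation $\log\alpha - \psi(\alpha) = \log \bar y_w -
\overline{\log y}_w$ for the gammas, closed-form mean direction plus
Newton inversion of the Bessel ratio $A_1(\kappa) = I_1/I_0$ for the von
Mises. This replaces generic quasi-Newton optimization on a transformed
scale: the maximizer is the same, but the update is deterministic and
fast, which is what makes the recovery study cheap enough to re-run
routinely.

Convergence is declared when the relative log-likelihood change drops
below `tol` (1e-8) or after `max_iter` (500) iterations; the
log-likelihood trace is stored and must be non-decreasing up to 1e-8
relative tolerance. Degenerate inputs (a feature that is constant under
some state's posterior weight) raise an error naming the offending
component rather than returning a spurious fit.

State sequences are decoded with the Viterbi algorithm (ties toward the
lower state index); per-sample posterior argmax decoding is available via
`posterior_decode()` but the MAP sequence is the default, as the joint
path respects the transition structure on missing stretches.

Model comparison across $k$ uses BIC and ICL, converted to weights
$w_m \propto \exp(-\Delta_m/2)$. The free-parameter count is
$(k-1) + k(k-1) + 4k + 2(k_{vM})$ with $k_{vM} = k - 1$ von Mises
states — exactly the estimated quantities; the uniform angle component
contributes none. Missing samples count toward the BIC sample size by
default (they do enter the likelihood, trivially); `hmm_control(bic_n =
"observed")` reproduces the other convention.

## Starting values

Deterministic classification starts: $\rho_i = 1/k$, transition diagonal
0.9 with the remaining 0.1 spread evenly across the row (rows must sum
to one), and the emission table of `default_emission_table()` divided by
the feature scale factor. The table encodes the qualitative event
signatures (raw scale): fixation ≈ 6 deg/s and 210 deg/s², saccade ≈
150 deg/s and 6000 deg/s² with κ = 5 around 0, PSO ≈ 45 deg/s and 4500
deg/s² with κ = 5 around π, pursuit ≈ 21 deg/s with fixation-level
acceleration and κ = 5 around 0. The fifth state starts at low velocity
with a weak direction preference so it can split an existing event into
sub-events if the data demand it.

The recovery study instead uses *randomized* starts: every positive
parameter is drawn from a gamma with shape 3 and scale $\theta/2$, whose
mode is the true value $\theta$ — positive, moderately skewed, centred
on the truth in mode; von Mises means start at their true values and all
probabilities start uniform at $1/k$.

## The simulation study

`simulate_hmm()` samples directly on the feature level — states from
$\rho$ and $A$, features from the state's emission distributions. This
is the model's own sampling space; the study checks whether estimation
recovers the data-generating process, not whether the features resemble
any particular tracker. Consequences of that scope: the simulated data
never contain the saccade–PSO ordering constraint (the generative model
does not enforce it), no missing samples unless requested, and no
position-level artefacts (quantization, filtering correlation). Passing
recovery tests therefore validates the *statistical machinery*, not
classification accuracy on real recordings.

The parameter-variation design (`part1_design()`) manipulates one
parameter at a time over an equidistant grid while all others keep their
defaults: the transition diagonal jointly over [0.6, 0.95] (off-diagonal
mass rebalanced evenly), every gamma shape over [1, 5] (above 5 the
distribution is nearly symmetric, so that range spans the skewness that
matters), every gamma scale over [default/2, 2×default], and every von
Mises concentration over the inverse scale $1/\kappa \in [0.1, 1]$.
That yields q = 10/15/20 manipulated parameters for k = 2/3/4 — one
transition manipulation, four gamma parameters per state, one
concentration per von Mises state. Default generating values are the
emission table scaled by 10. Where a published design value was not
recoverable, the values above were fixed once on the criterion that the
simulated features land in realistic oculomotor ranges, and they are
recorded in `part1_design()`/`default_emission_table()` for audit.

The noise design (`part2_design()`) keeps defaults and sweeps sample
size $N \in \{500, 2500, 10000\}$ and a joint noise grid: each velocity
and acceleration value $y$ is replaced by a gamma(shape 3, scale
$(y/2)\tau$) draw with $\tau \in [1, 5]$, and von Mises(0,
$\kappa_{noise}$) white noise with $1/\kappa_{noise} \in [0.1, 10]$ is
added to the angles, both increasing jointly in equidistant steps. Note
the replacement distribution has mode $y\tau$, equal to the original
value only at $\tau = 1$; the formula is implemented exactly as stated
in the study design it follows, and the growing multiplicative bias is
precisely why gamma *scale* parameters degrade first under noise.

Desk-scale replication: the harness defaults to 10 datasets per cell
with $N = 2500$ (the full design used 100), which keeps the complete
four-model study under five minutes on one core while leaving the
medians stable. `run_recovery_study()` logs failed fits and excludes
them from summaries rather than aborting.

## Recovery metrics

RMdSPD is $\sqrt{\mathrm{median}((\hat\theta_i - \theta_i)^2 /
\theta_i^2)}$ across simulated datasets $i$; below 0.1 is read as good,
0.1–0.5 moderate, above 0.5 bad. Two conventions need care:

* Zero truths (von Mises means at 0) are replaced by $2\pi$ before
  division. A raw difference is discontinuous at the wrap point — an
  estimate of $2\pi - 0.01 \equiv -0.01$ would score as a full-circle
  error — so recovery summaries score $\mu$ parameters with deviations
  wrapped to $(-\pi, \pi]$ (`rmdspd(..., circular = TRUE)`).
* `recovery_rmdspd()` pools each estimated parameter across **all**
  datasets of a study by default, which is the defining median over
  simulations and is stable at 10 replicates per cell; the per-cell
  breakdown (`by = "varied"`), the grid drawn in recovery figures, needs
  the full 100-replicate design for its medians to settle.

Initial-state probabilities are recorded but excluded from RMdSPD
summaries by default: a single sequence identifies $\rho$ only through
its first sample, so $\hat\rho$ sits at a vertex of the simplex and its
"deviation" is pure noise.

State recovery is multi-category Cohen's kappa between true and decoded
sequences, computed per dataset with no permutation correction — label
switching is visible as kappa outliers near 0 (and $-1/3$ for k = 3),
and `best_permutation_match()` resolves it explicitly by brute-force
search over all state permutations when diagnosis is wanted.

## Postprocessing

The decoded sequence is cleaned by three relabeling rules applied left to
right over maximal runs: one-sample fixations and pursuits, saccades
shorter than 10 ms (strictly below; run length over fs), and PSOs not
preceded by a saccade are relabeled to the previous event's type. A
leading offending run merges forward; noise runs are transparent when
looking up the "previous event". Merges coalesce immediately and the
procedure is idempotent (verified property). Afterwards, missing samples
become `noise` labels, and maximal runs become events with durations
$\mathrm{Dur}(e) = \max(t_e) - \max(t_{e-1})$ (the first event uses its
own span), so durations telescope to the recording span.

The event-level agreement report compares two labelings by per-type
mean/SD duration and count, aggregated into an RMSD after dividing each
deviation by the reference value (the three quantities live on different
scales; `normalize = "raw"` disables this, and the choice is a
documented convention of this package), a column-normalized confusion
matrix, per-event one-vs-rest kappa, and the overall disagreement rate.

## Numerical choices and limitations

* Forward–backward uses per-sample normalization plus row-max factoring;
  Viterbi runs in log space. Enumeration oracles verify both on toy
  problems (k ≤ 3, N ≤ 8) in the test suite.
* Von Mises sampling uses the Best–Fisher (1979) rejection method;
  κ is capped at 1e5 when inverting the Bessel ratio.
* The gamma Newton solver refuses (near-)constant features rather than
  chasing a divergent shape, surfacing degenerate inputs as errors.
* EM converges to a local optimum; randomized starts occasionally land
  on label-switched or inferior modes (visible as kappa outliers in the
  4-state study). The classifier's deterministic starts avoid this in
  practice but offer no global guarantee.
* The model has no duration structure (geometric state dwell times) and
  no saccade→PSO ordering constraint; the postprocessing rules exist
  precisely to patch those gaps at the label level.
* Simulation validity is at the feature level only; results on real
  recordings additionally depend on calibration quality, the
  Savitzky–Golay settings and the tracker's noise characteristics.
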