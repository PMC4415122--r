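---
title: "Moment-by-moment choice decoding and change-of-mind detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment-by-moment choice decoding and change-of-mind detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

comdecode provides a single-trial, moment-by-moment readout of an upcoming
reach choice from simultaneously recorded premotor (PMd) and primary motor
(M1) cortical populations, and a conservative detector for covert "changes
of mind" — trials on which the neural state first encoded one choice and
later the other. This vignette documents the models, their assumptions, the
tunable parameters, and the design decisions taken where the procedure left
genuine freedom. All times are in milliseconds relative to maze onset
(target/barrier appearance); the Go cue falls at `delay`; reaction time
(RT) is movement onset minus Go.

## The task structure being modeled

A delayed-reach maze task with two targets whose difficulty can be `easy`,
`hard`, or `blocked` per side. Trials fall into behavioral classes derived
purely from the barrier configuration, the optional mid-trial barrier
change, and the eventual choice (`derive_trial_class()`): forced (one
target blocked throughout), free (both open), free-to-forced (a change
blocks one side), encouraged switch (a change opens the blocked side;
"taken" when the newly available target is chosen), and biasing change
(free throughout, the hard side becomes easy; "likely change" when the
initially-hard side is chosen). Instructed delays follow a truncated
exponential (tau = 500 ms, cap 1000 ms); barrier-change latencies an
independent truncated exponential (tau = 500 ms, cap 1200 ms). A separate
configured fraction of trials has zero delay (Go at maze onset); these
probe immediate choices and carry the indecision analysis. Zero-delay
trials are drawn as their own class because a continuous truncated
exponential puts no mass at exactly zero, while the task protocol includes
Go-at-onset trials.

## Latent-trajectory model

Spike trains are binned at 20 ms into half-open, left-closed bins anchored
at −300 ms; each trial's epoch ends at the last full bin before
`move_onset − 200 ms` (the trailing partial bin is dropped, so binned
counts conserve the in-window spike count; movement-epoch activity is
excluded so its large rate changes cannot dominate the latent space). The
counts `y_t` (square-root transformed by default, a variance-stabilizing
choice exposed as `sqrt_transform`) follow a Gaussian-process factor model

    y_t = C x_t + d + e_t,   e_t ~ N(0, R),  R diagonal
    x_i(.) ~ GP with K_i(t, u) = (1 - s_n^2) exp(-(t-u)^2 / (2 tau_i^2)) + s_n^2 d(t,u)

with 12 latent dimensions by default. `C`, `d`, `R` and the per-latent
timescales `tau_i` are estimated by EM on all successful trials of a
session together; the E-step is exact (per-trial joint-Gaussian
conditioning, computed once per unique trial length), the `(C, d, R)`
M-step is closed form, and the timescales are updated by a guarded 1-D
maximization of the expected complete-data log-likelihood — so the marginal
log-likelihood is provably non-decreasing, which the test suite asserts
across random restarts. Initialization is a static factor analysis (its own
small EM); convergence is declared at a relative log-likelihood change
below `1e-8` or at the iteration cap (500 by default; analyses in the test
suite and acceptance script cap earlier because the decoded traces are
insensitive to late EM refinement at the problem sizes used there, stated
below). Variable-length trials are handled by per-length kernel matrices on
the shared grid, never by padding.

Whether to orthonormalize the loading columns is moot for decoding: the
decoder is linear in the latents, so any invertible linear change of latent
basis changes the fitted weights but not the decoded values.
`orthonormalize_gpfa()` is provided for display only.

## Time-invariant choice decoder

A linear-kernel soft-margin SVM (cost 1, no feature rescaling — the latents
already share a scale) is trained on the pooled `(trial x bin)` latent
states of successful forced-choice trials with no barrier change and delay
≥ 300 ms, using only bins at or after +80 ms; each eligible bin of each
trial enters as one training point with the trial's eventual choice as its
label. The same weight vector applies at every time point — the decoder's
time invariance is what makes a change in the decoded value attributable to
changing neural activity rather than a changing readout. The graded decoded
choice is the signed distance from the hyperplane, normalized by the 90th
percentile of the absolute decoded values over all session trials and time
points. The percentile is taken over absolute values by default
(`norm_signed = FALSE`): the normalization is a scale, and an unsigned
scale keeps the left/right convention symmetric; the signed variant is
available. Positive values mean rightward — the convention is asserted at
training time by checking the rightward-labeled training points.

Forced-trial performance is assessed by leave-one-out cross-validation;
each fold retains its decoder, its normalization constant (computed over
all trials except the held-out one), and its class-conditional models, so
downstream event detection on a cross-validated trial uses strictly that
fold's models. Accuracy as a function of time assigns each trial to a 60 ms
bin by the time of its *last* decoded point: because the epoch ends a fixed
offset before movement onset, short-delay trials probe early time points.
The chance-level p-value for an observed accuracy is Monte-Carlo: a null
decoder guesses left/right with the class prevalence, giving per-trial
match probability `p^2 + (1-p)^2`; the estimate uses the add-one
(Davison–Hinkley) correction. The protocol-scale default is 10^7 runs;
the test suite and acceptance script use 10^5, which resolves p-values to
10^-5 — ample for the checks made of it.

## Change-of-mind detector

For each time bin from +80 ms to +600 ms, and one pooled bin for all later
times (late bins are sparse because long-delay trials are rare), Gaussians
are fit to the forced-left and forced-right decoded values (unbiased SD,
floored at `sigma_floor = 1e-3` normalized units to guard degenerate bins;
bins with fewer than two values per class inherit the nearest earlier bin,
with a warning). A trial with delay ≥ 300 ms is called a change of mind
when, among time points ≥ 160 ms (movement preparation takes roughly
150 ms; rounded up to the bin grid), all three of the following hold, each
allowed at its own time point: (1) the decoded sign changes; (2) some value
is ≥ 10 times as likely under the forced-left as under the forced-right
distribution; (3) some value is ≥ 10 times as likely under forced-right as
under forced-left. Reading the three criteria at possibly different time
points is the literal reading of the procedure and is what makes the
detector demand a swing from "strongly left" to "strongly right" rather
than a mere wobble about zero. Exact zeros take the sign of the previous
bin, and a sign change between two bins is timed at their midpoint. The
detector is monotone: raising the likelihood-ratio threshold can only
shrink the event set (asserted as a property test).

## Synthetic sessions and ground truth

No public recording accompanies the procedure, so the generator is the
test bed: it must carry every phenomenon the pipeline claims to detect,
with ground-truth labels. Each trial receives a piecewise-constant covert
*intention* (`none`, then a plan, with at most one reversal): the plan
forms 100–200 ms after maze onset; free trials vacillate (plan the opposite
side first, reversing at a uniform time in `[260, delay - 80]` ms, on
eligible trials with delay ≥ 400 ms) with probability 0.13; trials whose
barrier change forces or invites a re-plan switch at
`change_time + replan latency` (100–200 ms); untaken-switch trials keep
their plan but pay a hesitation RT penalty (25 ms); zero-delay free trials
draw a plan latency from 40–300 ms coupled to RT (gain 0.8 ms per ms), so
the slowest plans produce reaction times a few hundred milliseconds beyond
the base — matching the long right tail such indecisive trials show. The
vacillation window bounds keep the reversal inside the decodable epoch with
enough settled time on both sides for the likelihood criteria to be
satisfiable at all — reversals outside the epoch are exactly the
"last-moment changes the decoder cannot see". The RT model is
`RT = 340 + N(0, 40) + penalties` (floor 180 ms). The indecision latency
range and gain were set so that the zero-delay free-vs-forced median RT
difference lands near the tens-of-milliseconds scale reported for such
effects and the early decoded value varies visibly across trials; they are
a design choice of this package's generator, not a claimed mechanism.

Units (default 101, split across PMd and M1 labels) fire as inhomogeneous
Poisson processes (thinning sampler): each unit has a baseline rate
(5–15 spikes/s), a preferred side whose target rate adds 8–20 spikes/s
(the non-preferred side loses half the modulation — this asymmetry also
means the pre-maze baseline state is *not* the midpoint of the two plan
states, mirroring the observation that baseline activity tends to decode
to one side), an onset latency jitter (0–30 ms) and an exponential ramp
time constant (30–70 ms). A `forced_free_gain` multiplier (default 1)
weakens free-trial selectivity when desired. Every random draw flows from
the master seed through named substreams (schedule, tuning, spikes, ...),
so a fixed seed reproduces a session bit for bit while regenerating one
stage leaves the others unchanged.

What the generator does *not* emulate: correlated (shared, non-Poisson)
noise, non-stationary tuning, movement-epoch dynamics, eye position, or
kinematics. Passing the recovery tests therefore shows the pipeline is
correct and calibrated under Poisson population coding with the task's
trial structure — not that real cortical data meet those assumptions.

## Downstream analyses

* **Forced/free response similarity** — PSTHs are single-trial rates
  smoothed with a 30 ms-SD Gaussian (edge-corrected so each spike keeps
  unit mass), averaged per condition over −200..+300 ms; trials with delay
  ≥ 350 ms; free-trial averages first exclude any trial whose decoded sign
  ever disagrees with the eventual choice after +160 ms. Per unit, Pearson
  r between concatenated [forced-L, forced-R] and [free-L, free-R]
  vectors; units gated at SNR ≥ 4 where SNR = range of the concatenated
  vector over its largest SEM (SEM computed across trials of the smoothed
  single-trial rates); a sign test (exact binomial, one-sided r > 0)
  across included units.
* **Preference consistency** — the tuning test is unspecified in the
  source procedure; this package uses a two-sided Wilcoxon rank-sum on
  delay-epoch (+80 ms to Go) mean rates at alpha = 0.05, uncorrected, and
  reports the count of tuned units whose free-trial preference sign
  matches, without claiming equivalence to any other operationalization.
* **Baseline distance** — the baseline state is the mean latent state over
  −300..−40 ms across successful trials; change-of-mind trials contribute
  the two latent states flanking their last decoded sign change; reference
  distributions are all baseline-window points and all points ≥ 160 ms.
* **Crossing-window firing rates** — per unit, the rate in a 200 ms window
  centered on each event trial's last crossing, against the same unit's
  mean rate in the same absolute window on non-event left- and
  right-choice comparison trials; categories lower/between/higher with
  ties counted as "between" (conservative toward the null); lower vs
  higher proportions compared by a pooled two-proportion Z test.
* **RT contrasts** — Mann–Whitney U, exact when both groups have at most
  20 observations and no ties, otherwise the tie-corrected normal
  approximation without continuity correction. The near-Go free-to-forced
  split operationalizes "initially prepared a reach to the now-blocked
  side" as the decoded sign at the bin containing the barrier-change time,
  with "near Go" meaning within 50 ms of the Go cue.
* **Indecision regression** — zero-delay free trials with RT ≥ 300 ms; OLS
  of RT on the choice-aligned decoded value at the bin containing +100 ms
  (sign flipped on leftward choices); 95% CI from the standard
  linear-model formula.
* **Split-array agreement** — the latent model and decoder are refit per
  array (latent count reduced with a warning if an array has fewer units
  than latents); agreement between two decoders is the per-trial fraction
  of bins ≥ 160 ms with equal decoded sign, averaged over trials, for all
  eligible trials and for free choices alone.

## Numerical choices and degenerate inputs

Observation-noise variances are floored at 1e-6; class-conditional SDs at
`sigma_floor`. The GP kernel keeps a fixed diagonal term `s_n^2 = 1e-3`,
so all kernel matrices are well-conditioned without ad hoc jitter. A
single-class training fold is skipped with a warning (and reported); a
trial whose short epoch contributes no eligible training bins is tolerated
but a fully single-class pooled training set is an error. Quantiles use
R's default (type 7) definition. Empty performance bins are reported as
missing rather than zero; empty contrast categories yield `NA` statistics
rather than errors.

## Problem sizes used by the tests and the acceptance script

The generator's scientific defaults (timing distributions, rates, event
probabilities, RT model) are held fixed everywhere; what varies is only
problem size. The test suite uses sessions of 14–420 trials and 8–96
units with 3–12 latent dimensions and EM capped at 3–40 iterations,
chosen so the full suite runs in a few minutes on one core. The
indecision analyses use 96-unit sessions because a single-bin readout at
+100 ms is only as reliable as the population is large — with two dozen
units the probe's noise (~0.25 normalized units) swamps the latency
signal, which is itself a faithful reflection of why the original
recordings used ~100–200 electrodes. The acceptance script runs a
400-trial, 48-unit session with 12 latents and EM capped at 8 iterations.

## Known limitations

The decoded value near a trial's epoch edge is shrunk toward zero: the
Gaussian-process posterior has less corroborating data within its
smoothing reach there. Because the epoch ends a fixed offset before
movement onset, the indecision probe (a single early bin) inherits a small
*mechanical* positive association with reaction time — slower trials have
longer epochs, hence less-shrunk, larger probe values. On coupled
sessions this bias opposes the true negative slope (the reported effect
is, if anything, conservative); on no-coupling control sessions it means
the null regression is not exactly unbiased, and a confidence interval
will eventually exclude zero as the trial count grows without bound. The
no-effect control is therefore assessed at the scale of one recording
day's zero-delay trials (a few dozen qualifying trials), which is also the
scale at which such control comparisons are reported; the bias is small
against the coupled effect (tens vs. minus one-to-two hundred ms per
normalized unit).

The EM timescale update is a guarded coordinate maximization, not a full
joint optimization; with few iterations the timescales stay near their
100 ms initialization. The detector inherits the grid: crossings are timed
to bin midpoints (10 ms resolution). The generator's single-reversal
intention model cannot produce multi-reversal vacillation, and the
category frequencies it yields depend on its configured class mix — the
package reports frequencies and contrasts, and the tests assert recovery
and calibration, not any particular published rate.
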