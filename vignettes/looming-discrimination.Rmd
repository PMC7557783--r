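---
title: "Modelling speed and speed-change discrimination for looming stimuli"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling speed and speed-change discrimination for looming stimuli}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loomdiscrim)
```

## The problem

When an object of fixed physical size approaches an observer, its retinal
image expands — *looming* — and because retinal position is inversely
proportional to distance, constant world speed produces accelerating
retinal expansion. This package models a 2IFC psychophysics design built
on that stimulus: one task asks which of two intervals contains a step
change in approach speed (with total duration and distance equated so only
the speed profile is informative); two companion tasks ask which interval
is faster when either duration or distance covaries with speed. The
analysis chain asks what decision strategy observers use, and whether
"speed discrimination" is really done on speed.

## Stimulus geometry

Two horizontal lines separated by $S = 2$ cm are viewed at distance $d$;
their angular separation is $\theta(d) = 2\,\mathrm{atan}\!\big((S/2)/d\big)$
and under approach at world speed $v$ the expansion rate is the exact
derivative

$$\dot\theta = \frac{S\,v}{d^{2} + (S/2)^{2}} \quad [\mathrm{rad/s}],$$

converted to arcmin with $1\,\mathrm{rad} = (180/\pi)\cdot 60 =
3437.7468$ arcmin. We use the exact form rather than the small-angle
approximation $Sv/d^2$ because it is well defined at every distance; at
viewing distances of 50 cm and beyond the two agree to better than 0.05%,
and both reproduce the landmark values the design is anchored to (20.1,
5.02, 38.4 and 29.2 arcmin/s) at three significant figures. Two published
interval-end values (46.3 and 80.9 arcmin/s) compute to 46.38 and 81.16
under either formula; the rounding convention behind those two entries is
unknown and we do not force agreement.

### Frames, durations and the three conditions

All schedules are realized as integer frame counts at 85 Hz:
$n = \mathrm{round}(T \cdot 85)$ with half-counts rounded away from zero,
realized duration $n/85$. This convention uniquely reproduces the printed
durations 0.412 s (35 frames) and 0.506 s (43 frames). The one printed
value it does not reproduce exactly is the 0.717 s standard of the
duration condition, which quantizes to 61 frames = 0.7176 s; we keep the
quantized value. Distance advances $v/85$ cm per frame, so the step change
"after 500 ms of motion" lands on the 42.5-frame boundary; the tie is
broken away from zero (43 frames slow, 42 frames fast). A side effect is
that test and standard intervals match in distance only up to the
half-frame remainder (at most $0.5(v_{fast}-v_{slow})/85 \le 0.35$ cm),
while duration matches exactly — the analysis code asserts exactly these
tolerances.

The three conditions are built by `build_condition()`:

* **speed change** — start 117 cm, 250 ms stationary hold, 1 s of motion;
  standard 40 cm/s; seven test levels from (40, 40) to (10, 70) cm/s in
  5 cm/s steps around the standard.
* **duration** — start 97 cm; every level covers 28.7 cm, so speed
  (40–70 cm/s) trades against duration; each level's distance agrees with
  28.7 cm within one frame's displacement.
* **distance** — start 97 cm; every level lasts 43 frames (0.506 s), so
  speed trades against distance.
* **catch interval** (both speed-discrimination conditions) — 40 cm/s for
  a nominal 1.070 s (91 frames), covering 42.8 cm.

Stationary holds are represented as zero-speed segments so traces contain
them; they contribute no motion cues and `extract_cues()` excludes them.

## Observer models

Observers read *world-speed* cues (cm/s), not retinal arcmin/s: the d′
algebra of the design is stated in interval speed units and the levels are
defined in world speed. Each cue reading within a trial receives
independent Gaussian noise of standard deviation `noise_sd` (in the cue's
own units), and with probability `lapse_rate` the response is replaced by
a fair coin. Exact ties are broken by a fair coin so identical intervals
yield 50%.

Six strategies are implemented. Three matter for the speed-change task:
the *within-interval change* (double difference $(e_1-s_1)-(e_2-s_2)$:
mean $\Delta$, variance $4\sigma^2$, $d' = \Delta/2\sigma$), and the
*end-* or *start-speed* comparisons (single cross-interval difference:
mean $\Delta/2$, variance $2\sigma^2$, $d' = \Delta/2\sqrt2\sigma$). Three
apply to speed discrimination and catch trials: mean speed, distance, and
duration (each a single between-interval comparison, $d' =
\Delta/\sqrt2\sigma$).

Two decision-rule choices were genuinely open and we resolved them in the
direction that preserves the signal-detection algebra:

* The change strategy compares the *signed* change $e-s$ between
  intervals, not its absolute value. In this design the test change is
  positive and the standard's is zero, so the signed comparison is the
  double difference itself and simulated percent correct equals
  $\Phi(d')$ exactly; an absolute-value rule folds the standard's noise
  distribution and lands measurably below $\Phi(d')$.
* The start-speed observer picks the interval with the *smaller* noisy
  start, because the test interval starts slower than the standard; this
  is the orientation under which the strategy performs at $\Phi(d')$
  rather than below chance.

Whether real observers compare start or end speeds is indistinguishable
in this design; both are provided and neither is privileged.

## Psychometric fitting

Performance per level is fitted with
$p(x) = \gamma + (1-\gamma-\lambda)\,\Phi\!\big((x-\mu)/\sigma\big)$,
guess rate $\gamma = 0.5$ (2IFC), by maximum likelihood under the binomial
likelihood. The lapse rate $\lambda$ is fixed at 0 by default, with an
optional fixed-lapse grid (0–0.06 by 0.01) selected by likelihood; free
continuous lapse estimation on 7-point data is poorly constrained and not
offered. Optimization is L-BFGS-B on $(\mu, \log\sigma)$ with 8 restarts
from coarse-grid seeds and a $10^{-8}$-scale tolerance on the
log-likelihood. The axis is internally rescaled by $\max|x|$ before
fitting, which makes the estimator *exactly* equivariant under rescaling
of $x$ — the property behind the factor-of-2 identity: analysis-I axis
values (within-interval change) are exactly twice analysis-II values
(end-speed difference), hence fitted thresholds double exactly,
participant by participant.

Degenerate data are flagged rather than silently fitted: performance at
ceiling everywhere, never above chance, or perfect-step data that leave
the slope unidentified (every level pinned at an asymptote of the fitted
function, a likelihood ridge on which the optimizer may stop anywhere).
Flagged fits are excluded from group statistics and `threshold()` refuses
them. The 75% threshold is the closed-form inversion
$\mu + \sigma\,\Phi^{-1}\!\big((0.75-\gamma)/(1-\gamma-\lambda)\big)$,
which reduces to $\mu$ when $\lambda = 0$. Standard errors, when wanted,
come from a seeded parametric bootstrap (400 resamples by default).

## Catch-trial classification

The catch analysis is an equal-tail exact binomial test of $p = 0.5$:
$k_{lo}$ is the largest count with $P(X \le k_{lo}) \le \alpha/2$ and
$k_{hi}$ the smallest with $P(X \ge k_{hi}) \le \alpha/2$. At $n = 30$,
$\alpha = 0.05$ this gives (9, 21) — the 30%/70% boundaries. Counts at or
below 9 indicate duration use (the shorter standard preferred), at or
above 21 distance use, otherwise speed. We deliberately did not use
Clopper–Pearson inversion around the observed count or a mid-p variant:
the equal-tail construction on the null is what yields the 9/21 bounds.
At other $n$ the category follows counts, not percentages. The region is
verified against brute-force PMF enumeration for all $n \le 200$, and the
misclassification rate of true speed users matches the region's exact
rejection probability in simulation.

## Statistics layer

Two-sample comparisons use Student's pooled-variance t (df $= n_1+n_2-2$;
the design's group sizes 11 and 7 give df 16, which is only consistent
with pooling, not Welch). The JZS Bayes factor integrates the noncentral-t
likelihood against a Cauchy(0, 0.707) prior on the standardized effect by
adaptive quadrature (relative integration error below $10^{-6}$,
non-convergence raised, never silent), with effective sample size
$n_1 n_2/(n_1+n_2)$ for two-sample designs — the convention of standard
default-Bayes-factor software. The correlation Bayes factor uses a
stretched-beta prior of width 1 with the standard reduced likelihood of
the sample correlation; it is validated only against an internal
quadrature oracle, because published correlation BFs depend on prior
conventions that are rarely stated. All p-values are two-sided;
`bonferroni(0.05, 3)` reports 0.0167.

## What the synthetic generator emulates — and what it does not

The generator's defaults are the study conditions: 11 speed-change
participants and 7 speed-discrimination participants; 7 levels × 30 trials
in 3 blocks per condition; 30 catch trials interleaved uniformly at random
within blocks of the speed-discrimination conditions; fair random interval
order per trial. Speed-change participants default to the end-speed
strategy (the sub-optimal comparison the group data were consistent with);
speed-discrimination participants use speed on main trials with catch cues
mixed 3 distance / 3 speed / 1 duration, kept consistent across the two
conditions by default (`catch_strategy_correlation = 1`), emulating the
observed cross-condition consistency of cue use.

Individual noise is log-normal around 3.5 cm/s (sdlog 0.3) with a 2%
lapse rate. The 3.5 cm/s centre was chosen once so that one 5 cm/s level
step corresponds to roughly $d' \approx 1$ on the between-interval axis —
thresholds then sit a few levels into the 7-level range, as a sensibly
designed constant-stimuli experiment intends. Catch-cue readings are
corrupted with noise rescaled to the cue's units at a constant relative
level, $\sigma_{cue} = \sigma_{speed}\cdot(\text{standard cue
magnitude})/(40\ \mathrm{cm/s})$; the design does not constrain catch-cue
noise in its own units, and the Weber-like scaling keeps catch
discriminability comparable across cue types. A per-trial
`catch_switch_prob` lets catch trials fall back to the main-task cue,
emulating trial-to-trial switching; nothing downstream depends on it.

Passing tests on this generator show that the *analysis chain* recovers
what the generator put in — strategies, catch cues, the factor-2 identity,
calibrated test sizes. They cannot show that human observers behave like
these observers: real data bring serial dependence, learning and fatigue,
non-stationary criteria, and possibly graded cue mixtures, none of which
are modelled. The generator is a test harness with the design's
*statistical structure*, not a model of participants.

## Problem sizes and reproducibility

Every stochastic routine takes a seed and restores the caller's RNG state;
identical seeds give byte-identical trial records, and cohort manifests
carry md5 checksums so a regenerated cohort can be verified. The test
suite exercises calibration at $10^5$ trials per strategy/level,
classifier calibration over $10^4$ simulated participants, parameter
recovery over 200 replicate fits at 500 trials/level, and the full
18-participant pipeline — sizes at which binomial standard errors are
small enough for 2–3-SE assertions while the whole suite stays
interactive.

## Known limitations

* No rendering-level modelling (luminance, pixels, stereoscope optics,
  disparity): the geometry stops at ideal angular quantities.
* Observers read world-speed cues; a retinal-readout variant would need
  its own d′ calculus (retinal speed is nonlinear in distance) and is out
  of scope.
* Only the cumulative-normal family is fitted; no Weibull/logistic
  alternatives, no adaptive staircases.
* No cue-combination or mixture inference: the catch classifier assumes
  one dominant cue per participant per condition, as the design itself
  does.
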