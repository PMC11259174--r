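---
title: "Methods: simulator, beliefs, agents, and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulator, beliefs, agents, and analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
task model and its assumptions, the belief filter, the reinforcement-learning
agents, the analysis battery, and the numerical and design choices made where
the design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The task

An agent starts each trial at the origin of a large ground plane, heading
"straight ahead" (90 degrees), and must steer to a target that is visible
only briefly. The world state is
$s_t = (x, y, \theta, v, \omega, g_x, g_y)$: pose, linear and angular
velocity, and the (fixed) target position. Targets are drawn uniformly *in
two dimensions* over an annular sector 100-400 cm from the origin and within
±35° of straight ahead; uniformity in 2-D requires sampling the squared
radius uniformly, $r = \sqrt{u},\ u \sim U(100^2, 400^2)$.

Dynamics are a discrete-time unicycle with $\Delta t = 0.1$ s:
position and heading advance with the *current* velocities, then the new
velocities are set directly by the joystick action through the gain
$G = (200\ \mathrm{cm/s},\ 90\ \mathrm{°/s})$ (times a gain multiplier $n$
in the "gain task"), plus an optional perturbation velocity, plus Gaussian
process noise applied to the two velocity components only. Because noise
enters the velocities after the position update, it first affects position
one step later — the integration order is taken literally from the model
definition, and the dynamical-consistency tests depend on it.

The observation is low-dimensional rather than visual: the two velocities
(optic flow surrogate) always, and the target position only while visible
($t \le 0.3$ s, boundary inclusive — four observations at 10 Hz counting
$t=0$). Observation noise is Gaussian on the velocities and exactly zero at
$t = 0$. Noise levels are expressed in units of the (multiplied) gain:
$\sigma_a = \alpha_a n G$, $\sigma_o = \alpha_o n G$; the training default is
$\alpha_a = 0.2,\ \alpha_o = 0.1$, i.e. $\sigma_a = (40, 18)$ and
$\sigma_o = (20, 9)$.

A trial ends when the agent *stops* — both joystick components below
$a^* = 0.1$, recognized only after a start latch set the first time a
component exceeded $a^*$ — or at the 3.4 s timeout. Only a stop earns
reward: 10 inside the 65 cm reward zone, otherwise a Gaussian partial reward
with covariance $(65/1.5)^2 I_2$. Timeouts earn nothing, by the stop-criterion
rule. The discount is $\gamma = 0.97$ per step.

Choices the task description leaves open, resolved here once:

* Heading is not wrapped; trials are far too short for overflow, and
  wrapping would corrupt the belief filter's linearization continuity.
* The 70 m arena radius is tracked (episodes flag exits) but not enforced as
  a wall; no collision rule is described.
* Radial target sampling is implemented as $\sqrt{U(100^2, 400^2)}$; the
  alternative reading (uniform radius) contradicts the stated goal of 2-D
  spatial uniformity and fails the chi-square uniformity test the suite runs.
* Post-noise velocities are not clipped to the gain; saturation behavior
  is unspecified and the tests bound velocities only statistically.

## The belief

The state is partially observable (position is never observed after target
offset), so a competent agent maintains a posterior over the state — a
belief. The model-based belief is an extended Kalman filter over the 5-dim
*target-relative* state $(x - g_x,\ y - g_y,\ \theta,\ v,\ \omega)$, with
initial mean $(-g_{x0}, -g_{y0}, 90, 0, 0)$ and covariance
$10^{-8} I_5$.

Two structural facts drive everything downstream, and both are asserted in
tests rather than assumed:

1. The transition Jacobian's velocity rows are identically zero — the
   commanded velocity is the whole prior on the next velocity. Hence the
   predicted velocity variances equal the process-noise variances exactly,
   independent of the prior covariance.
2. Only velocities are observed, so the Kalman gain has nonzero entries only
   in the velocity rows, with the scalar form
   $k = \sigma_a^2 / (\sigma_a^2 + \sigma_o^2)$, *constant for all
   $t \ge 1$*. Observations never correct position directly: position
   uncertainty grows by dead reckoning, as it must without landmarks.

A consequence (derived in `R/train_loop.R` and cross-checked step-for-step
against the generic filter in the tests): the posterior covariance keeps a
zero pose-velocity block and a constant velocity block, so only the 3×3
pose block varies across trials. The vectorized multi-trial rollout engine
propagates exactly that block, which is what makes 10,000-trial evaluations
cheap on one CPU.

Units: means are stored in degrees (the task's convention); Jacobian
trigonometry is in radians, with the degree-radian factor carried in the
$\partial/\partial\theta$ entries so covariances in degree units propagate
correctly. Covariances are symmetrized after each update (float hygiene);
zero noise variances are floored at $10^{-8}$.

The independent oracle is a bootstrap particle filter over the same 5-dim
state (exact stochastic dynamics, Gaussian velocity likelihood, systematic
resampling below half the particle count, degeneracy signaled under an
effective sample size of 10). On low-noise episodes its posterior moments
agree with the EKF; the acceptance suite quantifies this at
$\alpha_a = \alpha_o = 0.05$, where the linearization bias of the EKF is
small relative to the posterior spread.

## Agents

Two TD3 (twin-delayed deterministic policy gradient) variants are
implemented in base R matrix code (no deep-learning framework exists in the
supported stack; BLAS carries the matrix products, and every backward pass
is pinned against central finite differences in the tests).

**Feedforward on EKF beliefs.** Actor and twin critics are two-layer
300-unit rectified MLPs taking the belief mean (5) plus the packed
upper-triangular covariance (15); critics additionally take the action.
Triangular packing avoids the redundancy of the full matrix; the layout is
a documented assumption since only "mean and covariance" is specified.
Inputs are normalized — positions by 400 cm, the heading (centered on 90°)
by 90°, velocities by the gain, covariance entries by the products of the
corresponding scales — an unspecified but necessary choice for stable
training, applied at the interface and recorded here.

**Recurrent.** The architecture family with graded module specialization:
holistic single-module networks (220 gated-recurrent units) and
multi-module variants (128-unit recurrent modules, two-layer 300-unit
feedforward modules), including the modular critic in which the action
enters only the second module so value computation cannot occur before
action injection — a structural constraint enforced by wiring, not by
training. Gating follows the long short-term-memory design; the vanilla
recurrence is deliberately not offered because gateless training is
reported unstable in this setting. Parameter counts across critic variants
agree within 10% by construction (closed-form counts are tested).

**Training.** Off-policy with replay: step tuples (capacity 1.6M, FIFO)
for the feedforward agent, whole equal-length-sampled trajectories
(capacity 100k) for recurrent agents; every item is stored twice — original
and mirror image across the y axis, which is an exact symmetry of the task.
Exploration adds Gaussian noise (SD 0.8/0.5/0.4 by phase) clipped to the
action box, suppressed when the deterministic action is already below the
stop threshold so intended stops survive exploration. Bootstrap targets use
the minimum of two target critics with clipped target-policy smoothing noise
(SD 0.05, clip 0.1); critics update once per 4 environment steps, the actor
and the Polyak targets ($\tau = 0.005$) once per two critic updates. Phases
split at 20% and 80% validation accuracy (300 trials): observation noise is
off in phase 1, and the learning rate anneals from 3e-4 to 5e-5 as a step
change at the phase-3 boundary. The Adam stability constant is 1.5e-4 with
zero weight decay, as specified.

Implementation notes that are choices, not specification:

* Updates due within a trial are applied in a burst at the trial boundary
  (the due-count bookkeeping is exact); with a large buffer and 256-tuple
  batches this is indistinguishable from strictly interleaved updates and
  it keeps the trial loop simple.
* Recurrent training clips gradients at global norm 1.0 (BPTT stability;
  nothing is said about clipping). Feedforward training never clips.
* No updates happen until the buffer holds one batch.
* One integer seed governs weight initialization, environment noise,
  exploration, and buffer sampling.
* Checkpoints are taken every 500 trials (validation shares the cadence);
  selection picks the checkpoint with the highest mean reward rate across
  the task's test sets, ties resolved to the earliest.

## Analyses

*Stopping accuracy.* The psychometric curve counts the fraction of trials
whose stop falls within a hypothetical reward boundary, over 60 log-spaced
radii from 5 to 400 cm (the endpoints "infinitely small/large" are described
qualitatively; the grid is this package's choice). The control curve
recomputes it after permuting targets across trials; plotting true against
shuffled and integrating by the trapezoid rule with (0,0) and (1,1)
appended gives the ROC area: 1 for a perfect stopper, 0.5 at chance.
Trials that never stopped count as unrewarded at every boundary.

*Signed radial error.* Magnitude is the Euclidean stop-target distance;
the sign comes from comparing idealized circular-arc lengths
$L = 2\tilde r \arcsin(\sqrt{x^2+y^2} / 2\tilde r)$,
$\tilde r = (x^2+y^2)/2x$ — overshoot iff the stop's arc strictly exceeds
the target's, ties counting as undershoot. The formula is even in $x$ and
approaches the straight-line limit as $x \to 0$, both handled explicitly
and checked against a dense numeric arc oracle.

*Trajectory geometry.* Length is the sum of segment norms; curvature uses
one-sided differences at the endpoints and central differences inside, with
each trial's steps above its own 95th percentile excluded from the trial
mean (the outlier rule is read as per-trial). Zero-speed steps have
undefined curvature and are dropped with a count attached.

*Test-time TD error.* $|r_t + (1-D_t)\gamma Q_1(i_{t+1}, a_{t+1}) -
Q_1(i_t, a_t)|$ with the trained networks only — no targets, no
exploration — truncated at the terminal step.

*Decoding.* Ridge regression in the printed closed form
$W = (X^\top X + \lambda I)^{-1} X^\top S$, $\lambda$ chosen from
$\{0.1, 1, 10\}$ by 5-fold cross-validation within the 70% training trials
(fold count unspecified; splits are at the trial level so no time step
leaks). No intercept is added because the estimator is given without one.
Decoding error is the trial-mean Euclidean distance, averaged over trials.
For EKF agents, positions decode in target-relative coordinates — the
belief's own frame.

*Spatial tuning.* Activity is gridded at 5 cm (the boxcar width of 40 cm is
specified; the grid is not), interpolated by cell-wise averaging of the
dense sample cloud — the piecewise-constant limit of linear interpolation;
a triangulation-based interpolant is not available in the supported stack —
then smoothed with the 40 cm boxcar. Cells outside the samples' convex hull
are missing.

*Kalman-gain fingerprint.* A frozen agent is evaluated on a 5×5 grid of
test uncertainties $\{+0, +0.2, +0.4, +0.6, +0.8\} G$ above its training
pair, with the belief model (gain and covariance schedule) frozen at the
training values — the agent does not know the test noise. Each cell's AUC
is subtracted from the baseline cell's; the (+0,+0) entry is zero by
construction. Two tables are compared by the Pearson correlation of their
25 entries with a bootstrap confidence interval over entries (the
alternative trial-level bootstrap is noted but not used, since the figure
being reproduced correlates tables).

## The synthetic world, and what a green test establishes

Every input is generated internally; there is no external data. The
generator's defaults are the stated task conditions (target geometry, noise
levels, reward geometry, durations, perturbation ranges). The scripted
controller — a proportional steering rule on the EKF belief that brakes on
approach and stops inside the believed reward zone — exists so that every
analysis stage can be exercised in seconds without RL training; it emulates
competent behavior but not learned behavior: its trajectories are smoother
and its stops better calibrated than a trained agent's. Green analysis
tests built on it establish the correctness of the analysis arithmetic,
not any claim about learning. Claims about learning are carried only by the
acceptance tests that train agents.

Desk-scale defaults follow the same logic: evaluations use hundreds of
trials where the full protocol uses thousands, and the acceptance suite
trains one agent per uncertainty pair with an early stop once the
validation criterion is comfortably exceeded, instead of eight seeds of
10^4-10^5 trials. What is reproduced is therefore directional structure
(learning reaches the stated accuracy; the fingerprint's axis asymmetry and
its transposition between over-observer and over-predictor references), not
figure-scale point estimates, which are out of scope.

## Known limitations

* Training at desk scale is seed-sensitive, as small-sample deep RL always
  is; the acceptance run fixes the seed and budget and reports what that
  world produces.
* The recurrent trainer is exercised structurally (gradient checks, contract
  tests, tiny end-to-end runs); full recurrent training to criterion is
  outside the test-time budget and is offered through the same
  `train_agent()` interface and the architecture-comparison script instead.
* The particle-filter oracle shares the environment's dynamics code; it is
  independent in its inference (no linearization, no Gaussian closure) but
  not an independent re-implementation of the physics — the physics itself
  is pinned by closed-form unit tests.
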