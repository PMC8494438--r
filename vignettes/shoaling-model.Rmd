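---
title: "Two visual reflexes and a leaky integrator: modelling emergent shoaling in larval zebrafish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two visual reflexes and a leaky integrator: modelling emergent shoaling in larval zebrafish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shoalmodel)
```

## The scientific problem

Larval zebrafish swim in discrete bouts and, as they mature from 7 to 21 days
post fertilization (dpf), their groups change from dispersed to tightly
shoaling and weakly schooling. `shoalmodel` implements a complete modelling
chain for the hypothesis that two *individual* visuomotor reflexes suffice to
explain this *collective* change:

1. a **retinal clutter response** — larvae turn away from (7 dpf) or toward
   (21 dpf) the more cluttered visual hemifield, and
2. a **global motion response** — larvae integrate coherent visual motion over
   time and turn along it (the optomotor response probed with
   limited-lifetime coherent dot stimuli, cdOMR).

Both signals feed a single leaky drift-diffusion decision process whose
threshold crossings trigger discrete turns. The package provides the
trajectory metrics, the decision model and its evolutionary multiobjective
fit, the agent-based group simulator, randomization/bootstrap inference, and
synthetic data generators with known ground truth, so that every stage is
testable without access to experimental recordings.

## The decision model

The motion evidence $X(t)$ of each fish follows the leaky stochastic
integrator

$$\tau \frac{dX}{dt} = C(t) - X(t) + \mathcal{N}(0, \sigma),$$

solved by forward Euler at a fixed $dt = 0.01$ s:
$X \leftarrow X + (C - X + \mathcal{N}(0,\sigma))\,dt/\tau$. Two conventions
matter:

* **$\sigma$ is applied per Euler step without $\sqrt{dt}$ scaling.** This is
  deliberate (it mirrors the source model exactly); consequently $\sigma$ must
  be interpreted at $dt = 0.01$ and the two are never configurable
  independently. The stationary SD of the integrator is
  $\sigma\sqrt{dt/2\tau}$, so behaviourally relevant noise values are of order
  5–10, not 0–1. This is also why the fitting bounds admit $\sigma \in [0, 20]$:
  with $\sigma \le 2$ the integrator is effectively noiseless relative to the
  coherence drive $C \in [0,1]$, the psychometric curve jumps from chance to
  its ceiling already at 25% coherence, and no parameter set can reproduce the
  gradual accuracy rise seen in the motion assay.
* **One symmetric threshold pair $\pm T$ on a single integrator.** While
  $|X| < T$ a forward bout is emitted with per-step probability $p_{below}$
  (heading change $\mathcal{N}(0°, 5°)$); while $|X| \ge T$ a turn toward
  $\mathrm{sign}(X)$ is emitted with probability $p_{above}$ (heading change
  $\mathcal{N}(\pm 22°, 25°)$, right turns positive). Turn *direction* labels
  come from the realized heading change, as in experiments, so accuracy
  saturates near 0.8–0.87 even for a perfect integrator — the
  $\mathcal{N}(\pm22°,25°)$ draw crosses zero with ~19% probability.

The five parameters $(\tau, \sigma, T, p_{below}, p_{above})$ cannot be read
off behaviour directly; they are recovered by the multiobjective fit below.

### Default ("hand-tuned-like") parameters

`default_ddm_params()` returns $\tau = 0.65$ s, $\sigma = 8$, $T = 0.5$,
$p_{below} = 0.005$, $p_{above} = 0.011$. They were chosen once, against the
qualitative wild-type cdOMR phenomenology: accuracy rising gradually
(~0.5, ~0.66, ~0.77, ~0.85 at 0/25/50/100% coherence), interbout intervals
near 1.2 s at rest and shorter under stimulation, roughly 40% of spontaneous
bouts being turns, and same-direction persistence decaying over about a
second. They are the ground truth of the surrogate generator, not a fit to
any collective statistic.

### Stimulus protocol

`stimulus_protocol()` mirrors the motion assay: 5 s of 0% coherence baseline,
then 10 s of coherent motion (25, 50 or 100%; leftward or rightward), for
each combination, repeated (default twice). The direction order alternates
between blocks so that the direction of the epoch *preceding* each baseline
is balanced against the baseline's own label; the integrator carries evidence
for roughly $\tau$ seconds into the baseline, and an unbalanced order would
bias the 0%-coherence "accuracy" far away from chance. Baselines are labelled
with the direction of the upcoming epoch so that a probability correct is
defined (and ≈ 0.5) at 0%.

## The five behavioural features and their distances

`extract_features()` computes, per bout table: (i) probability of turning in
the correct direction per coherence; (ii) mean interbout interval per
coherence; (iii) probability that consecutive spontaneous turns at 0%
coherence share a direction, in six 0.25 s delay bins centred 0.125–1.375 s;
(iv) probability correct as a function of time within the coherent epoch
(default 2.5 s bins; the fit uses 1.25 s bins, which sharpen the rise-time
information that identifies $\tau$); and (v) the weights of a three-Gaussian
mixture over heading changes with fixed components
$\mathcal{N}(-22°,25°), \mathcal{N}(0°,5°), \mathcal{N}(+22°,25°)$, estimated
by a weights-only EM (deterministic; the component shapes are part of the
model, only the "peak heights" are compared). Turns are bouts with
$|\Delta\mathrm{heading}| > 10°$; the threshold sits between the forward mode
$\mathcal{N}(0°,5°)$ and the turn modes $\mathcal{N}(\pm22°,25°)$ at roughly
equal standardized distance.

`feature_distances()` scores a model against a target with one MSE per
feature (a mean squared logarithmic error variant is available and behaves
comparably); empty bins are excluded. `compromise_error()` normalizes each
distance by the 75th percentile of its distribution over the random initial
population — frozen thereafter, so compromise values remain comparable across
generations — and sums them with weight 3 on the interbout-interval distance
and 1 elsewhere.

## The multiobjective fit

`fit_ddm()` is an NSGA-II-style evolutionary loop: nondominated sorting,
binary tournaments, simulated binary crossover ($\eta_c = 15$, rate 0.9) and
polynomial mutation ($\eta_m = 20$, per-gene rate 0.2) on unit-interval
genes, log-scaled for $\tau$, $T$ and the event probabilities. Survival is
elitist ($\mu + \lambda$), with the compromise-minimal individual explicitly
retained; the reported convergence history is the running minimum of the
population compromise error, which is non-increasing by construction.

One choice departs from textbook NSGA-II and matters at small scale: with
five objectives and a population of ~100, almost every individual is
nondominated ("dominance resistance"), so rank alone exerts no selection
pressure and the population cannot converge within a few dozen generations.
Rank ties in tournaments are therefore broken by the compromise error — the
very scalarization by which the procedure ultimately picks its best
individual — and survival keeps one quarter of the slots by crowding distance
(preserving spread along the front) and fills the rest by compromise order.

Three further choices address the stochasticity of the objectives:

* each new individual is evaluated on a fixed simulation budget
  (`n_fish_eval` fish) with a fresh deterministic child seed — controlled
  variance, reproducible fits;
* the ten current leaders are re-evaluated every generation and their
  objectives kept as running means, so long-lived individuals carry honest
  scores and a single lucky draw cannot anchor the population in its basin;
* at the end, the leading candidates of the whole run (final leaders plus the
  per-generation archive) are re-scored on fresh, larger budgets — cheap
  relative to the evolutionary loop — and the best is chosen by that
  near-noiseless averaged compromise, followed by a greedy coordinate polish.
  The reported best is always a member of the final population.

Parameter recovery from surrogate data with known ground truth is the primary
validation: `surrogate_recovery_report()` repeats
generate-surrogate → fit → compare. Identifiability is the binding
constraint: compensating parameter combinations (larger $\tau$ with smaller
$T$, rescaled probabilities and noise) produce nearly identical *stationary*
bout statistics, and only transient features — the accuracy rise time within
an epoch and the same-direction persistence decay — separate them. Desk-scale
practice therefore uses data-rich surrogate targets (150 fish on a
six-repetition protocol, roughly the data volume of the real assay), a
population of 100 for 30 generations at 24 fish per evaluation, and three
independent optimization repeats with the best chosen by re-evaluated
compromise (`n_repeats`, mirroring the source procedure's repeated runs).
Under those settings $\tau$ and $T$ are recovered to within about a quarter
of their true values; $\sigma$ and the event probabilities remain more
loosely determined. The full published scale (population 800, 80
generations, 12 repeats) is available through the same interface.

## Trajectory metrics

* **Kinematics**: central differences over one frame,
  $v(t) = (x(t+dt) - x(t-dt))/2dt$ with $dt = 0.025$ s at 40 frames/s;
  direction undefined at zero speed.
* **Aggregation** $= -\log(NN_1 / NN_1^{shuffled})$, with $NN_1$ the mean
  nearest-neighbour distance and the shuffled baseline computed from control
  groups taking fish slot $j$ from a distinct real group each (slot-preserving,
  so trivially identical groups give exactly 0). Requires at least as many
  groups as fish per group.
* **Alignment** (polarization) $= |\sum_i \vec d_i| / N \in [0, 1]$ from
  direction-of-motion unit vectors; chance level for five independent fish is
  the expected resultant of five uniform unit vectors, ≈ 0.40 (the asymptotic
  $\sqrt{\pi N}/2N$ value is 0.396).
* **Ray-cast visual occupancy**: 1000 rays per eye spanning 165° from the
  heading backwards (30° rear blind zone; resolution 0.165°/ray), neighbours
  rendered as body-length line segments along their heading (the simplest
  shape preserving the angular-size law; the tracked pixel silhouettes behind
  the original analysis are not reconstructable), eyes co-located at the
  centroid, nearest fish claiming each ray. Agreement with the
  $2\arctan(L/2d)$ oracle is within two ray resolutions for isolated
  broadside neighbours.
* **Clutter-difference turning curves**: turning bouts (detected from speed
  peaks) paired with the right-minus-left occupancy at bout onset, binned at
  5°, with normal-approximation binomial CIs. The symmetrized AUC sums
  $\mathrm{sign}(\text{bin}) (p_{right} - 0.5)$ per 5° bin: positive =
  attraction, negative = repulsion. Its absolute scale is a package
  convention; only ratios between conditions are meaningful, which is also
  all the collective model consumes (the genotype factors are ratios).

## The collective model

`simulate_group()` simulates five agents in a 1024 px circular arena
(fishsize = 20 px) for 600 s at $dt = 0.01$ s. Per agent and step:

$$\text{evidence}_j = w_{clutter} f_{clutter} \sum_{i \ne j} \pm 2\arctan\!\frac{\text{fishsize}}{2 d_{ij}} \; + \; w_{motion} \sum_{i \ne j} -\dot\beta_{ij} \cos\beta_{ij},$$

where the clutter sum signs right-hemifield neighbours $+$ and left $-$ (no
blind zone here — the data-analysis ray cast has one, the model formula does
not), and $\dot\beta_{ij}$ is the angular velocity of neighbour $i$'s bearing
$\beta_{ij}$ as seen by fish $j$, computed from the relative velocity
$v_i - v_j$ and scaled by $1/d$.

The motion term deserves its design notes, because the retinal weighting is
constrained only by four stated properties (no looming response, smooth
front/back transition, no response to parallel swimming, distance
attenuation):

* Using the **relative** velocity makes the radial and parallel nulls exact:
  a looming or receding neighbour has no bearing rate, and two fish
  translating with the same velocity vector keep their bearing exactly.
* The signed gain $\cos\beta$ *is* the back-hemifield sign inversion in
  smooth form: positive ahead, negative behind, and — unlike a strictly
  positive eccentricity weight combined with a hard sign flip at ±90° — it is
  continuous when a neighbour crosses the lateral boundary, which a hard
  inversion violates for tangentially moving neighbours. The gain function is
  an argument of `perceived_motion()` and can be swapped.
* Sign convention: positive evidence = rightward drift = right turn, matching
  the clutter sign and the threshold rule (above $+T$ → right turn).

Decisions use the same integrator and bout rules as the cdOMR model; executed
bouts cover 20 px (forward *and* turning bouts) with the heading change
applied through a first-order low-pass with a 100 ms time constant, yielding
bout-and-glide kinematics. An agent reaching the wall is clamped to the
boundary circle and receives a fresh uniformly random orientation (no
reflection or wrapping); its pending bout motion is cleared, as a wall
contact interrupts the bout. Trajectories are exported at 40 frames/s in the
same format as experimental recordings, so `aggregation_index()` and
`alignment_index()` consume them unchanged.

The genotype- and age-specific clutter factors are anchored at $-1$ for the
7-dpf wild type and scaled by the measured clutter-response ratios:
`genotype_factors()` tabulates 7 dpf $(-1, -2, -1, -1.5, -2, -1.5)$ and
21 dpf $(+3, +3, +3, +2, +1, +2)$ for the scn1lab (two alleles) and disc1
lines and their sibling controls. The published source lists
"scn1lab_allele1^+/+^" twice per age; the second entry of each pair is read
as the heterozygous mutant. Decision parameters are shared between ages
("the same cdOMR variables"), and $w_{clutter} = w_{motion} = 1$ unless a rule
is deliberately disabled.

## Synthetic data

Three generators provide ground-truth-bearing inputs:

* `gen_independent_walkers()` — reflected, mutually independent random walks;
  by construction aggregation ≈ 0 and alignment at the uniform-resultant
  chance level. Used as the null for metric validation. Walks mix over a few
  arena-crossing times; validation recordings should be long relative to
  that, or the per-group nearest-neighbour means are dominated by the initial
  configuration.
* `gen_structured_group()` — fish around a drifting centroid with a
  restoring drift (gain speed/cohesion_scale) and von Mises heading offsets
  with concentration `polarization_kappa`, redrawn every ~0.5 s: a single
  knob each for cohesion and polarization, with uniform (κ = 0) and
  point-mass (κ → ∞) limits. This generator is phenomenological — it
  validates metrics, not mechanism.
* `gen_surrogate_cdomr()` — bout tables from the decision model with the
  generating parameters attached as a sidecar attribute.

What passing tests on these data do **not** show: real recordings contain
tracking noise, identity swaps, wall-following, and non-stationary arousal;
none are emulated. The experimental statistics of the source study (its
measured aggregation values, turning-curve sAUCs, mutant feature curves) are
therefore covered only qualitatively, through the simulator.

## Inference toolkit

Group comparisons use the Fisher randomization test of the sharp null with
Welch's $t$ as statistic: exact enumeration whenever the number of
allocations fits the permutation budget (default 100,000), otherwise Monte
Carlo including the observed allocation (add-one convention, so $p > 0$ and
the test is exact-level). Bootstrap 95% intervals are percentile intervals of
the resampled mean with $p$ by interval inversion. Cohen's $d$ uses the
pooled-SD two-sample and one-sample forms. Regression bands are pointwise
$t_{0.95, n-2}$ bands around the OLS fit using the residual standard
deviation (a collinear dataset yields a zero-width band). No multiple-testing
adjustment is applied anywhere, matching the source analyses.

## Numerical choices and degenerate inputs

* Distances between coincident agents are floored at 1 px before the clutter
  and motion kernels.
* Orientations are wrapped to $(-\pi, \pi]$ everywhere; boundary angles map
  to $+\pi$.
* Zero-variance inputs: the Welch statistic is defined as 0 when both groups
  are constant and equal (randomization $p = 1$); Cohen's $d$ errors on zero
  pooled SD with unequal means; constant-x regression errors.
* A single root seed drives every stochastic component through deterministic
  child seeds (`child_seed()`), including per-individual evaluation seeds
  inside the fit, so whole analyses replay bit-identically.

## Problem sizes used by the tests and the acceptance script

Surrogate targets use 60 fish on the two-repetition protocol; desk-scale fits
use population 100 for 30 generations at 48 fish per evaluation; collective
runs use the full published geometry (12 runs × 600 s × 5 agents). These
sizes were chosen as the smallest at which the recovery and reproduction
claims are stable across seeds; the published-scale settings (population 800,
80 generations, 12 repeats) remain available through the same arguments.

## Known limitations

* The retinal motion projection is one admissible member of the family
  constrained by the four stated properties; its absolute scale (and hence
  the balance of the two rules at $w = 1$) is a modelling convention.
* The symmetrized AUC scale is a package convention; compare ratios only.
* The bout detector (speed peaks + 10° threshold) is a reconstruction; the
  original tracker may have used tail-angle criteria.
* $\sigma$ and the event probabilities are only weakly identified at desk
  scale (compensating-parameter ridges); $\tau$ and $T$ are the reliably
  recovered pair.
* The 0%-coherence accuracy point depends on the protocol's direction-order
  balance; with strongly unbalanced orders it is biased by integrator
  carryover.
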