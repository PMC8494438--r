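# shoalmodel

Modelling tools for a question in developmental collective behaviour: do two
simple visual reflexes of individual larval zebrafish — the **retinal clutter
response** (turning away from or toward the more cluttered visual hemifield)
and **global motion integration** (the optomotor response to coherent visual
motion) — suffice to explain how groups of five fish go from dispersed at
7 days post fertilization (dpf) to tightly shoaling and aligned at 21 dpf?

The package is written for behavioural and computational ethologists. It
implements the full modelling chain:

* **Trajectory metrics** — central-difference kinematics; the aggregation
  index `-log(NN1 / NN1_shuffled)` against cross-group shuffled controls; the
  alignment (polarization) index `|Σ d_i| / N`; ray-cast visual occupancy
  (1000 rays per eye over 165°, 30° rear blind zone); clutter-difference
  turning curves in 5° bins with binomial CIs; a symmetrized area under the
  curve (attraction positive, repulsion negative).
* **A leaky drift-diffusion bout model** for coherent-dot optomotor data:
  `τ dX/dt = C(t) − X + N(0, σ)`, Euler-integrated at dt = 0.01 s, forward
  swims below the threshold (heading change N(0°, 5°), probability `p_below`
  per step) and turns toward sign(X) above it (N(±22°, 25°), `p_above`).
* **An evolutionary multiobjective fit** (NSGA-II-style) of the five latent
  parameters (τ, σ, T, p_below, p_above) against five behavioural feature
  curves, with 75th-percentile normalization and a compromise error weighting
  the interbout-interval distance ×3.
* **An agent-based collective simulator** — five virtual fish in a 1024 px
  circular arena driven by `evidence = w_c f_c · clutter + w_m · motion`
  through the same decision model, with genotype/age clutter factors, 20 px
  bouts through a 100 ms low-pass, and wall re-orientation.
* **Synthetic data generators** with known ground truth, and the
  **inference toolkit** (Fisher randomization tests with Welch's statistic,
  percentile bootstrap intervals, Cohen's d, regression CI bands).

See `vignettes/shoaling-model.Rmd` for the model assumptions, parameter
conventions and design choices.

## Worked example

Simulate wild-type groups at both ages with the hand-tuned-like decision
parameters and compare their group statistics:

```r
library(shoalmodel)

p <- default_ddm_params()        # tau 0.65 s, sigma 8, T 0.5, p_below 0.005, p_above 0.011

sim7  <- simulate_group(collective_config(ddm_params = p, f_clutter = -1),
                        n_runs = 12, seed = 1)
sim21 <- simulate_group(collective_config(ddm_params = p, f_clutter = +3),
                        n_runs = 12, seed = 2)

aggregation_index(sim7,  shuffle_seed = 3)
#> <group_metrics: 12 groups, mean aggregation -0.105 (nn1_shuffled 266)>
aggregation_index(sim21, shuffle_seed = 4)
#> <group_metrics: 12 groups, mean aggregation 0.926 (nn1_shuffled 219)>

mean(sapply(sim7,  function(r) alignment_index(r)$mean))
#> [1] 0.413672
mean(sapply(sim21, function(r) alignment_index(r)$mean))
#> [1] 0.4145974
```

The 7-dpf factor (−1, repulsion) produces slight dispersal (negative
aggregation: groups are looser than shuffled controls), the 21-dpf factor
(+3, attraction) strong aggregation; alignment sits above the N = 5 chance
level of ≈ 0.40 whenever the motion rule is active. A randomization test
makes the age contrast explicit:

```r
a7  <- aggregation_index(sim7,  shuffle_seed = 3)$aggregation
a21 <- aggregation_index(sim21, shuffle_seed = 4)$aggregation
randomization_test(a7, a21)
#> T_Welch = -28.66, P_Fisher (two-sided) = 1e-05  [100000 allocations]
```

To study the single-fish assay, generate surrogate coherent-dot data and
recover its parameters:

```r
pr <- stimulus_protocol(reps = 2)
bouts <- gen_surrogate_cdomr(p, pr, seed = 7, n_fish = 40)
extract_features(bouts, pr)
#> <behavioral_features from 6065 bouts>
#>   p(correct) vs coherence:  0.491 0.634 0.754 0.851
#>   interbout interval (s):   0.884 1.09 0.995 0.94
#>   same-direction vs delay:  0.771 0.682 0.651 0.627 0.5 0.523
#>   turn-angle GMM weights:   0.372 0.276 0.353

fit <- fit_ddm(extract_features(bouts, pr), pr, pop_size = 100,
               generations = 30, n_fish_eval = 24, seed = 11)
```

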