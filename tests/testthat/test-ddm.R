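test_that("the noiseless integrator crosses the threshold at -tau log(1 - T)", {
  # sigma = 0, constant drive C = 1 from the epoch start, p_above = 1: the
  # first turn marks the threshold crossing of X(t) = 1 - exp(-t / tau)
  tau <- 0.65; T0 <- 0.5
  p <- ddm_params(tau = tau, sigma = 0, threshold = T0, p_below = 0, p_above = 1)
  pr <- stimulus_protocol(coherences = 100, directions = 1, reps = 1)
  b <- simulate_ddm(p, pr, n_fish = 1, seed = 1)
  t_cross <- min(b$t_s) - pr$baseline_s
  expect_equal(t_cross, -tau * log(1 - T0), tolerance = 0.03)  # Euler O(dt)
  expect_true(all(b$dheading_deg[b$t_s == min(b$t_s)] != 0))
})

test_that("without noise and below threshold all bouts are forward swims", {
  p <- ddm_params(tau = 0.65, sigma = 0, threshold = 1.99,
                  p_below = 0.01, p_above = 1)
  b <- simulate_ddm(p, stimulus_protocol(reps = 1), n_fish = 5, seed = 2)
  expect_gt(nrow(b), 200)
  expect_lt(mean(abs(b$dheading_deg) > 10), 0.10)
  expect_equal(sd(b$dheading_deg), 5, tolerance = 1)
})

test_that("accuracy is ~0.5 at 0% coherence and increases with coherence", {
  pr <- stimulus_protocol(reps = 2)
  f <- extract_features(simulate_ddm(default_ddm_params(), pr, n_fish = 25,
                                     seed = 31), pr)
  acc <- f$acc_vs_coherence
  expect_equal(unname(acc["c0"]), 0.5, tolerance = 0.08)
  # non-decreasing in coherence up to Monte-Carlo error, over a parameter grid
  grid <- list(default_ddm_params(),
               ddm_params(1.2, 5, 0.35, 0.006, 0.012),
               ddm_params(0.4, 10, 0.7, 0.008, 0.02))
  for (k in seq_along(grid)) {
    fk <- extract_features(simulate_ddm(grid[[k]], pr, n_fish = 15,
                                        seed = 40 + k), pr)
    a <- fk$acc_vs_coherence
    expect_true(all(diff(a) > -0.06))
    expect_gt(a["c100"], a["c0"] + 0.1)
  }
})

test_that("turn-angle mixture weights recover generating mixtures", {
  set.seed(5)
  w_fwd <- gmm3_weights(rnorm(10000, 0, 5))
  expect_gt(w_fwd["forward"], 0.9)
  thirds <- c(rnorm(4000, -22, 25), rnorm(4000, 0, 5), rnorm(4000, 22, 25))
  w3 <- gmm3_weights(thirds)
  expect_equal(unname(w3), rep(1 / 3, 3), tolerance = 0.05)
  expect_equal(sum(w3), 1, tolerance = 1e-9)
  expect_error(gmm3_weights(rnorm(10)), "at least 50")
})

test_that("simulation and feature extraction are deterministic under a fixed seed", {
  pr <- stimulus_protocol(reps = 1)
  b1 <- simulate_ddm(default_ddm_params(), pr, n_fish = 3, seed = 77)
  b2 <- simulate_ddm(default_ddm_params(), pr, n_fish = 3, seed = 77)
  expect_equal(as.data.frame(b1), as.data.frame(b2))
  f1 <- extract_features(b1, pr); f2 <- extract_features(b2, pr)
  expect_equal(f1$acc_vs_coherence, f2$acc_vs_coherence)
  expect_equal(f1$gmm_weights, f2$gmm_weights)
})

test_that("hand-built bout tables yield the expected feature values", {
  pr <- stimulus_protocol(coherences = 25, directions = 1, reps = 1,
                          baseline_s = 5, stim_s = 10)
  # strict left/right alternation of turns during the baseline: same-direction
  # probability 0 at every populated delay
  t0 <- seq(0.2, 4.8, by = 0.2)
  alt <- data.frame(fish_id = "f1", t_s = t0,
                    dheading_deg = rep(c(30, -30), length.out = length(t0)),
                    coherence_pct = 0, stim_dir = 1)
  class(alt) <- c("bout_table", "data.frame")
  f <- extract_features(alt, pr)
  populated <- is.finite(f$same_dir_vs_delay)
  expect_true(any(populated))
  expect_true(all(f$same_dir_vs_delay[populated] == 0))
  # all turns in the stimulus direction: accuracy 1 at that coherence
  stim <- data.frame(fish_id = "f1", t_s = seq(5.2, 14.8, by = 0.2),
                     dheading_deg = 30, coherence_pct = 25, stim_dir = 1)
  class(stim) <- c("bout_table", "data.frame")
  f2 <- extract_features(stim, pr)
  expect_equal(unname(f2$acc_vs_coherence["c25"]), 1)
  expect_true(all(f2$acc_vs_time["c25", ] == 1))
  # interbout interval equals the construction spacing
  expect_equal(unname(f2$ibi_vs_coherence["c25"]), 0.2, tolerance = 1e-9)
})
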