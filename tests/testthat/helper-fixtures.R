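# small programmatic fixtures shared across test files

# straight-line recording: every fish moves east at `speed`
straight_rec <- function(n_frames = 20, n_fish = 3, speed = 1, frame_rate = 40,
                         arena_diameter = 50) {
  dt <- 1 / frame_rate
  pos <- array(NA_real_, c(n_frames, n_fish, 2))
  for (i in seq_len(n_fish)) {
    pos[, i, 1] <- -5 + speed * dt * (seq_len(n_frames) - 1)
    pos[, i, 2] <- (i - (n_fish + 1) / 2) * 2
  }
  ori <- matrix(0, n_frames, n_fish)
  group_recording(pos, ori, frame_rate, arena_diameter, group_id = "line")
}

# recording with prescribed constant headings; fish move along them slowly
heading_rec <- function(headings_rad, n_frames = 10, frame_rate = 40,
                        arena_diameter = 60) {
  k <- length(headings_rad)
  dt <- 1 / frame_rate
  pos <- array(NA_real_, c(n_frames, k, 2))
  for (i in seq_len(k)) {
    base <- c(cos(2 * pi * i / k), sin(2 * pi * i / k)) * 5
    step <- 0.5 * dt * c(cos(headings_rad[i]), sin(headings_rad[i]))
    pos[, i, 1] <- base[1] + step[1] * (seq_len(n_frames) - 1)
    pos[, i, 2] <- base[2] + step[2] * (seq_len(n_frames) - 1)
  }
  ori <- matrix(rep(headings_rad, each = n_frames), n_frames, k)
  group_recording(pos, ori, frame_rate, arena_diameter, group_id = "head")
}

# one-frame scene for ray casting / clutter: focal at origin heading 0
scene <- function(neighbour_xy, neighbour_heading = pi / 2) {
  positions <- rbind(c(0, 0), matrix(neighbour_xy, ncol = 2, byrow = TRUE))
  headings <- c(0, rep(neighbour_heading, nrow(positions) - 1))
  list(positions = positions, headings = headings)
}

# --- memoized heavy acceptance fixture -------------------------------------
# One surrogate target + one desk-scale fit + the 2 x 12 collective runs are
# shared by several acceptance checks; computed once per test session.
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_fixture <- function() {
  if (!is.null(.acceptance_cache$fx)) return(.acceptance_cache$fx)
  root_seed <- 773L
  pr_target <- stimulus_protocol(reps = 6)   # data-rich surrogate sessions
  pr <- stimulus_protocol(reps = 2)          # evaluation protocol
  true_params <- default_ddm_params()
  target_bouts <- gen_surrogate_cdomr(true_params, pr_target,
                                      seed = child_seed(root_seed, "target"),
                                      n_fish = 150L)
  target <- extract_features(target_bouts, pr_target, acc_time_bin_s = 1.25)
  fit <- fit_ddm(target, pr, pop_size = 100L, generations = 30L,
                 n_fish_eval = 24L, seed = child_seed(root_seed, "fit"),
                 acc_time_bin_s = 1.25)
  sims7 <- simulate_group(
    collective_config(ddm_params = fit$best, f_clutter = -1),
    n_runs = 12L, seed = child_seed(root_seed, "sim7"))
  sims21 <- simulate_group(
    collective_config(ddm_params = fit$best, f_clutter = +3),
    n_runs = 12L, seed = child_seed(root_seed, "sim21"))
  fx <- list(
    protocol = pr, true_params = true_params, target = target, fit = fit,
    sims7 = sims7, sims21 = sims21,
    agg7 = aggregation_index(sims7, shuffle_seed = child_seed(root_seed, "sh7")),
    agg21 = aggregation_index(sims21, shuffle_seed = child_seed(root_seed, "sh21")),
    align7 = vapply(sims7, function(r) alignment_index(r)$mean, 1.0),
    align21 = vapply(sims21, function(r) alignment_index(r)$mean, 1.0))
  .acceptance_cache$fx <- fx
  fx
}

# Monte-Carlo oracle: expected resultant length of n iid uniform unit vectors
chance_alignment <- function(n = 5, draws = 200000, seed = 99) {
  set.seed(seed)
  th <- matrix(runif(n * draws, -pi, pi), draws, n)
  mean(sqrt(rowSums(cos(th))^2 + rowSums(sin(th))^2) / n)
}
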