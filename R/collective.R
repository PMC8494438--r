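#' Genotype- and age-dependent clutter response factors
#'
#' The clutter response factor f_clutter scales (and signs) the clutter term of
#' the sensory evidence for each genotype and age, anchored at -1 for the
#' 7-dpf scn1lab_allele2 wild type and scaled by the measured tendency to turn
#' toward clutter. Negative values produce repulsion (dispersal), positive
#' values attraction (aggregation).
#'
#' @return data frame with columns `genotype`, `age_dpf`, `f_clutter`.
#' @export
genotype_factors <- function() {
  data.frame(
    genotype = rep(c("scn1lab_allele2_+/+", "scn1lab_allele2_+/-",
                     "scn1lab_allele1_+/+", "scn1lab_allele1_+/-",
                     "disc1_+/+", "disc1_-/-"), 2),
    age_dpf = rep(c(7L, 21L), each = 6),
    f_clutter = c(-1, -2, -1, -1.5, -2, -1.5,
                  +3, +3, +3, +2, +1, +2))
}

#' @rdname genotype_factors
#' @param genotype genotype label, e.g. `"scn1lab_allele2_+/+"` (the wild type
#'   used for the wild-type simulations) or `"disc1_-/-"`.
#' @param age_dpf age in days post fertilization, 7 or 21.
#' @return `genotype_factor` returns the scalar factor.
#' @export
genotype_factor <- function(genotype, age_dpf) {
  tab <- genotype_factors()
  hit <- tab$genotype == genotype & tab$age_dpf == age_dpf
  if (!any(hit))
    stopf("unknown genotype/age combination: %s at %s dpf (known genotypes: %s)",
          genotype, age_dpf, paste(unique(tab$genotype), collapse = ", "))
  tab$f_clutter[hit]
}

#' Configuration of the collective behaviour simulator
#'
#' @param ddm_params the decision-model parameters (a [ddm_params()]), shared
#'   by all ages ("the same cdOMR variables" are used for 7- and 21-dpf runs).
#' @param f_clutter clutter response factor (see [genotype_factor()]).
#' @param w_clutter,w_motion rule weights; both 1 in the full model, set one to
#'   0 to test a rule in isolation.
#' @param n_fish agents per group (default 5).
#' @param arena_diameter_px arena diameter (default 1024 px).
#' @param fishsize_px rendered body length (default 20 px; also the per-bout
#'   displacement).
#' @param dt Euler step, fixed 0.01 s (sigma interpretation).
#' @param duration_s simulated duration (default 600 s).
#' @param frame_rate export frame rate for the trajectory recordings (default
#'   40 frames/s so the analysis-side dt is 0.025 s).
#' @param lowpass_tau_s time constant of the bout-execution low-pass (0.1 s).
#' @return an object of class `collective_config`.
#' @export
collective_config <- function(ddm_params = default_ddm_params(),
                              f_clutter = -1, w_clutter = 1, w_motion = 1,
                              n_fish = 5L, arena_diameter_px = 1024,
                              fishsize_px = 20, dt = 0.01, duration_s = 600,
                              frame_rate = 40, lowpass_tau_s = 0.1) {
  stopifnot(inherits(ddm_params, "ddm_params"), n_fish >= 1L,
            arena_diameter_px > 0, fishsize_px > 0, dt > 0, duration_s > 0)
  structure(list(ddm_params = ddm_params, f_clutter = f_clutter,
                 w_clutter = w_clutter, w_motion = w_motion,
                 n_fish = as.integer(n_fish),
                 arena_diameter_px = arena_diameter_px,
                 fishsize_px = fishsize_px, dt = dt, duration_s = duration_s,
                 frame_rate = frame_rate, lowpass_tau_s = lowpass_tau_s),
            class = "collective_config")
}

#' @export
print.collective_config <- function(x, ...) {
  cat(sprintf(paste0("<collective_config: %d fish, arena %g px, f_clutter %g, ",
                     "w_clutter %g, w_motion %g, %g s @ dt %g>\n"),
              x$n_fish, x$arena_diameter_px, x$f_clutter, x$w_clutter,
              x$w_motion, x$duration_s, x$dt))
  invisible(x)
}

bearing_angle <- function(heading, dx, dy) {
  # bearing of (dx, dy) in the focal frame, CCW positive (left), 0 = ahead
  wrap_angle(atan2(dy, dx) - heading)
}

#' Perceived visual clutter
#'
#' Sum over neighbours of +/- 2 atan(fishsize / (2 d)), signed +1 for
#' neighbours in the right visual hemifield and -1 for the left, so the sign
#' and amplitude reflect the interocular asymmetry. Distances are floored at
#' 1 px for coincident fish.
#'
#' @param positions `n x 2` matrix of agent positions.
#' @param headings length-`n` headings (radians, CCW).
#' @param focal focal agent index.
#' @param fishsize rendered body length (px).
#' @return signed scalar (radians); positive = more clutter on the right.
#' @export
perceived_clutter <- function(positions, headings, focal, fishsize = 20) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2L) return(0)
  others <- setdiff(seq_len(n), focal)
  dx <- positions[others, 1] - positions[focal, 1]
  dy <- positions[others, 2] - positions[focal, 2]
  d <- pmax(sqrt(dx^2 + dy^2), 1)
  phi <- bearing_angle(headings[focal], dx, dy)
  hemi <- ifelse(phi < 0, 1, -1)   # right hemifield positive
  sum(hemi * 2 * atan(fishsize / (2 * d)))
}

#' Perceived motion
#'
#' Signed angular velocity of each neighbour's bearing as seen by the focal
#' fish (the retinal slip of its image, computed from the relative velocity,
#' hence zero for radial approach/recession and for parallel swimming),
#' multiplied by a smooth signed retinal gain of the bearing eccentricity and
#' summed; positive values are evidence for a right turn. The default gain
#' `cos(phi)` is positive ahead and negative behind, which folds the
#' back-hemifield sign inversion into a function continuous everywhere, so the
#' motion force has no jump when a neighbour crosses the front/back boundary.
#'
#' @param positions `n x 2` matrix of agent positions.
#' @param headings length-`n` headings (radians).
#' @param velocities `n x 2` matrix of agent velocities (px/s).
#' @param focal focal agent index.
#' @param retinal_gain signed gain as a function of bearing (radians);
#'   default `cos`.
#' @return signed scalar; positive = rightward drift evidence.
#' @export
perceived_motion <- function(positions, headings, velocities, focal,
                             retinal_gain = cos) {
  positions <- as.matrix(positions)
  velocities <- as.matrix(velocities)
  n <- nrow(positions)
  if (n < 2L) return(0)
  others <- setdiff(seq_len(n), focal)
  dx <- positions[others, 1] - positions[focal, 1]
  dy <- positions[others, 2] - positions[focal, 2]
  d <- pmax(sqrt(dx^2 + dy^2), 1)
  rvx <- velocities[others, 1] - velocities[focal, 1]
  rvy <- velocities[others, 2] - velocities[focal, 2]
  omega <- (dx * rvy - dy * rvx) / d^2   # bearing rate, CCW positive (rad/s)
  phi <- bearing_angle(headings[focal], dx, dy)
  sum(-omega * retinal_gain(phi))
}

#' Total sensory evidence of a focal agent
#'
#' `w_clutter * f_clutter * perceived_clutter + w_motion * perceived_motion`.
#'
#' @inheritParams perceived_motion
#' @param config a [collective_config()].
#' @return signed scalar drive fed to the decision integrator.
#' @export
sensory_evidence <- function(positions, headings, velocities, focal, config) {
  stopifnot(inherits(config, "collective_config"))
  config$w_clutter * config$f_clutter *
    perceived_clutter(positions, headings, focal, config$fishsize_px) +
    config$w_motion *
    perceived_motion(positions, headings, velocities, focal)
}

#' Agent state for step-wise simulation
#'
#' @param positions `n x 2` matrix (px, arena-centred).
#' @param headings length-`n` radians.
#' @return an `agent_state` list also carrying velocities, integrator values
#'   and pending low-pass bout motion (all zero initially).
#' @export
agent_state <- function(positions, headings) {
  n <- nrow(as.matrix(positions))
  structure(list(positions = as.matrix(positions), headings = wrap_angle(headings),
                 velocities = matrix(0, n, 2), x = numeric(n),
                 pending_dist = numeric(n), pending_turn = numeric(n)),
            class = "agent_state")
}

#' Advance the agent-based model by one Euler step
#'
#' Reference (R) implementation of the simulator step: per agent, integrate
#' the sensory evidence through the leaky decision integrator, emit a forward
#' bout (p_below, heading change N(0, 5) deg) or a turn toward the integrator
#' sign (p_above, N(+/-22, 25) deg, right positive), execute 20 px of bout
#' displacement and the heading change through a 100 ms first-order low-pass,
#' and re-randomize the orientation of (and clamp) any agent reaching the
#' arena border. The compiled simulator in [simulate_group()] implements the
#' same update.
#'
#' @param state an [agent_state()].
#' @param config a [collective_config()].
#' @return the updated `agent_state`.
#' @export
step_agents <- function(state, config) {
  stopifnot(inherits(state, "agent_state"), inherits(config, "collective_config"))
  p <- config$ddm_params
  n <- nrow(state$positions)
  dt <- config$dt
  R <- config$arena_diameter_px / 2
  old_pos <- state$positions
  # evidence for every agent from the same (pre-step) state
  ev <- if (n >= 2) vapply(seq_len(n), function(j)
    sensory_evidence(old_pos, state$headings, state$velocities, j, config),
    1.0) else numeric(n)
  for (j in seq_len(n)) {
    state$x[j] <- state$x[j] +
      (ev[j] - state$x[j] + rnorm(1, 0, p$sigma)) * dt / p$tau
    if (abs(state$x[j]) < p$threshold) {
      if (runif(1) < p$p_below) {
        dh <- rnorm(1, 0, 5)
        state$pending_turn[j] <- state$pending_turn[j] - deg2rad(dh)
        state$pending_dist[j] <- state$pending_dist[j] + config$fishsize_px
      }
    } else if (runif(1) < p$p_above) {
      dh <- rnorm(1, sign(state$x[j]) * 22, 25)   # right positive
      state$pending_turn[j] <- state$pending_turn[j] - deg2rad(dh)
      state$pending_dist[j] <- state$pending_dist[j] + config$fishsize_px
    }
    frac <- dt / config$lowpass_tau_s
    dturn <- state$pending_turn[j] * frac
    state$headings[j] <- wrap_angle(state$headings[j] + dturn)
    state$pending_turn[j] <- state$pending_turn[j] - dturn
    dd <- state$pending_dist[j] * frac
    state$positions[j, ] <- state$positions[j, ] +
      dd * c(cos(state$headings[j]), sin(state$headings[j]))
    state$pending_dist[j] <- state$pending_dist[j] - dd
    r <- sqrt(sum(state$positions[j, ]^2))
    if (r >= R) {
      state$positions[j, ] <- state$positions[j, ] * (R * (1 - 1e-9) / r)
      state$headings[j] <- runif(1, -pi, pi)
      state$pending_dist[j] <- 0
      state$pending_turn[j] <- 0
    }
  }
  state$velocities <- (state$positions - old_pos) / dt
  state
}

#' Simulate groups of virtual fish
#'
#' Runs the agent-based model (compiled): `n_runs` independent simulations of
#' `config$n_fish` agents for `config$duration_s` seconds at dt = 0.01 s, with
#' random initial positions and orientations, trajectories exported as
#' [group_recording()] objects at the analysis frame rate so they feed directly
#' into [aggregation_index()] and [alignment_index()].
#'
#' @param config a [collective_config()].
#' @param n_runs number of independent runs (12 in the reference protocol).
#' @param seed integer root seed.
#' @param return_bouts also attach each run's bout event log as attribute
#'   `bouts`.
#' @return list of `group_recording`s (one per run).
#' @export
simulate_group <- function(config, n_runs = 12L, seed = 1L,
                           return_bouts = FALSE) {
  stopifnot(inherits(config, "collective_config"))
  p <- config$ddm_params
  lapply(seq_len(n_runs), function(run) {
    res <- with_seed(child_seed(seed, paste0("run", run)), {
      collective_sim_cpp(config$n_fish, config$arena_diameter_px,
                         config$fishsize_px, config$dt, config$duration_s,
                         1 / config$frame_rate,
                         p$tau, p$sigma, p$threshold, p$p_below, p$p_above,
                         config$f_clutter, config$w_clutter, config$w_motion,
                         config$fishsize_px, config$lowpass_tau_s)
    })
    nf <- length(res$t)
    pos <- array(NA_real_, c(nf, config$n_fish, 2))
    pos[, , 1] <- res$x; pos[, , 2] <- res$y
    rec <- group_recording(pos, res$heading, config$frame_rate,
                           config$arena_diameter_px,
                           group_id = sprintf("sim%02d", run), t = res$t)
    if (return_bouts)
      attr(rec, "bouts") <- data.frame(fish = res$bout_fish + 1L,
                                       t_s = res$bout_t,
                                       dheading_deg = res$bout_dh,
                                       is_turn = res$bout_is_turn > 0)
    rec
  })
}
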