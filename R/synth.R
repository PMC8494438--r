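#' Specification for synthetic group trajectories
#'
#' Describes the synthetic trajectory generators: groups of `n_fish` in a
#' circular arena, with a single knob for cohesion (target spatial dispersion
#' around the group centroid) and a single von Mises concentration knob for
#' polarization (kappa = 0 gives uniform, independent headings; large kappa a
#' common heading).
#'
#' @param n_groups number of groups to generate (>= 2 so that cross-group
#'   shuffled controls are constructible downstream).
#' @param n_fish fish per group (default 5, as in the group assay).
#' @param n_frames frames per recording.
#' @param frame_rate frames per second.
#' @param arena_diameter arena diameter (length units).
#' @param cohesion_scale target dispersion of fish around the group centroid
#'   (same units as the arena); only used by [gen_structured_group()].
#' @param polarization_kappa von Mises concentration of headings around the
#'   group heading; only used by [gen_structured_group()].
#' @param speed swim speed (length units / s).
#' @param seed integer seed.
#' @return an object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(n_groups = 10L, n_fish = 5L, n_frames = 400L,
                            frame_rate = 40, arena_diameter = 12,
                            cohesion_scale = 2, polarization_kappa = 0,
                            speed = 0.6, seed = 1L) {
  if (cohesion_scale <= 0) stopf("cohesion_scale must be > 0")
  if (polarization_kappa < 0) stopf("polarization_kappa must be >= 0")
  structure(list(n_groups = as.integer(n_groups), n_fish = as.integer(n_fish),
                 n_frames = as.integer(n_frames), frame_rate = frame_rate,
                 arena_diameter = arena_diameter,
                 cohesion_scale = cohesion_scale,
                 polarization_kappa = polarization_kappa,
                 speed = speed, seed = as.integer(seed)),
            class = "trajectory_spec")
}

check_spec <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  if (spec$n_groups < 2L) stopf("need n_groups >= 2 for downstream shuffles")
  # crude packing check: fish start on a ring well inside the arena
  if (spec$arena_diameter / 2 < spec$n_fish * 1e-3 * spec$arena_diameter)
    stopf("arena too small to hold %d fish", spec$n_fish)
  invisible(spec)
}

# reflect a coordinate vector into [-r, r]
reflect_into <- function(x, r) {
  x <- (x + r) %% (4 * r)
  x <- ifelse(x > 2 * r, 4 * r - x, x)
  x - r
}

#' Independent random walkers (null model)
#'
#' Generates groups of mutually independent, reflected correlated random walks
#' in a circular arena. Because fish are independent between and within groups,
#' real and shuffled nearest-neighbour distances have the same distribution
#' (aggregation index ~ 0) and mean alignment sits at the chance resultant
#' length for `n_fish` uniform unit vectors (~0.396 for N = 5).
#'
#' @param spec a [trajectory_spec()].
#' @return list of [group_recording()] with a `ground_truth` attribute.
#' @export
gen_independent_walkers <- function(spec) {
  check_spec(spec)
  with_seed(spec$seed, {
    dt <- 1 / spec$frame_rate
    R <- spec$arena_diameter / 2
    turn_sd <- 1.2 * sqrt(dt)  # rad, heading diffusion
    recs <- lapply(seq_len(spec$n_groups), function(g) {
      pos <- array(NA_real_, c(spec$n_frames, spec$n_fish, 2))
      ori <- matrix(NA_real_, spec$n_frames, spec$n_fish)
      for (i in seq_len(spec$n_fish)) {
        h <- cumsum(c(runif(1, -pi, pi),
                      rnorm(spec$n_frames - 1, 0, turn_sd)))
        r0 <- 0.8 * R * sqrt(runif(1)); a0 <- runif(1, -pi, pi)
        x <- r0 * cos(a0) + cumsum(c(0, spec$speed * dt * cos(h[-1])))
        y <- r0 * sin(a0) + cumsum(c(0, spec$speed * dt * sin(h[-1])))
        # reflect into the inscribed square, then radially clamp: keeps walks
        # inside the circular arena while preserving independence
        s <- R / sqrt(2)
        x <- reflect_into(x, s); y <- reflect_into(y, s)
        pos[, i, ] <- cbind(x, y)
        ori[, i] <- wrap_angle(h)
      }
      group_recording(pos, ori, spec$frame_rate, spec$arena_diameter,
                      group_id = sprintf("walk%02d", g))
    })
    attr(recs, "ground_truth") <- list(kind = "independent_walkers", spec = spec)
    recs
  })
}

#' Structured groups with controllable cohesion and polarization
#'
#' Fish swim around a drifting group centroid. Each fish's heading is the group
#' heading plus a von Mises offset with concentration `polarization_kappa`
#' (redrawn every ~0.5 s), and a restoring drift toward the centroid with gain
#' `speed / cohesion_scale` keeps the group dispersion near `cohesion_scale`.
#' In the `cohesion_scale -> 0` limit groups are much tighter than shuffled
#' controls (aggregation >> 0); in the `kappa -> Inf` limit all headings agree
#' (alignment -> 1).
#'
#' @param spec a [trajectory_spec()].
#' @return list of [group_recording()] with a `ground_truth` attribute.
#' @export
gen_structured_group <- function(spec) {
  check_spec(spec)
  with_seed(spec$seed, {
    dt <- 1 / spec$frame_rate
    R <- spec$arena_diameter / 2
    redraw <- max(1L, round(0.5 / dt))   # heading offsets persist ~0.5 s
    lambda <- spec$speed / spec$cohesion_scale
    recs <- lapply(seq_len(spec$n_groups), function(g) {
      pos <- array(NA_real_, c(spec$n_frames, spec$n_fish, 2))
      ori <- matrix(NA_real_, spec$n_frames, spec$n_fish)
      gh <- runif(1, -pi, pi)                      # group heading
      cen <- 0.4 * R * c(cos(runif(1, -pi, pi)), sin(runif(1, -pi, pi)))
      p <- sweep(matrix(rnorm(spec$n_fish * 2, 0, spec$cohesion_scale),
                        spec$n_fish, 2), 2, cen, "+")
      off <- rvonmises(spec$n_fish, 0, spec$polarization_kappa)
      for (f in seq_len(spec$n_frames)) {
        if (f %% redraw == 0L)
          off <- rvonmises(spec$n_fish, 0, spec$polarization_kappa)
        h <- wrap_angle(gh + off)
        v <- spec$speed * cbind(cos(h), sin(h)) +
          lambda * sweep(-p, 2, cen, "+")
        p <- p + v * dt
        # keep everything inside the arena
        rr <- sqrt(rowSums(p^2))
        out <- rr > 0.98 * R
        if (any(out)) p[out, ] <- p[out, ] * (0.98 * R / rr[out])
        pos[f, , ] <- p
        ori[f, ] <- atan2(v[, 2], v[, 1])
        gh <- wrap_angle(gh + rnorm(1, 0, 0.8 * sqrt(dt)))
        cen <- cen + spec$speed * dt * c(cos(gh), sin(gh))
        if (sqrt(sum(cen^2)) > 0.7 * R) {          # steer centroid back inside
          gh <- atan2(-cen[2], -cen[1]) + rnorm(1, 0, 0.3)
          cen <- cen * 0.7 * R / sqrt(sum(cen^2))
        }
      }
      group_recording(pos, ori, spec$frame_rate, spec$arena_diameter,
                      group_id = sprintf("struct%02d", g))
    })
    attr(recs, "ground_truth") <- list(kind = "structured_group", spec = spec)
    recs
  })
}

#' Surrogate coherent-dot optomotor bout data with known ground truth
#'
#' Simulates the drift-diffusion bout model under a coherent-dot stimulus
#' protocol and returns the resulting bout table labelled with coherence and
#' stimulus direction, together with the generating parameters as a sidecar
#' attribute (`ground_truth`) for parameter-recovery studies.
#'
#' @param params a [ddm_params()] object.
#' @param protocol a [stimulus_protocol()].
#' @param seed integer seed.
#' @param n_fish number of simulated fish.
#' @return a `bout_table` with attribute `ground_truth`.
#' @export
gen_surrogate_cdomr <- function(params, protocol = stimulus_protocol(),
                                seed = 1L, n_fish = 40L) {
  bouts <- simulate_ddm(params, protocol, n_fish = n_fish, seed = seed)
  attr(bouts, "ground_truth") <- list(params = params, protocol = protocol,
                                      seed = seed, n_fish = n_fish)
  bouts
}
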