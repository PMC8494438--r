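#' Drift-diffusion bout model parameters
#'
#' The five latent parameters of the leaky-integrator decision model: leak time
#' constant `tau` (s), per-step perceptual noise SD `sigma` (dimensionless,
#' interpreted at the fixed Euler step dt = 0.01 s and deliberately *not*
#' rescaled by sqrt(dt)), decision threshold `threshold`, and the per-timestep
#' probabilities `p_below` (forward swim while |X| < T) and `p_above` (turn
#' while |X| >= T).
#'
#' @param tau leak time constant, s (> 0).
#' @param sigma noise SD (>= 0).
#' @param threshold decision threshold (> 0).
#' @param p_below,p_above per-timestep event probabilities in \[0, 1\].
#' @return an object of class `ddm_params`.
#' @export
ddm_params <- function(tau, sigma, threshold, p_below, p_above) {
  if (tau <= 0) stopf("tau must be > 0")
  if (sigma < 0) stopf("sigma must be >= 0")
  if (threshold <= 0) stopf("threshold must be > 0")
  for (p in c(p_below, p_above))
    if (p < 0 || p > 1) stopf("probabilities must lie in [0, 1]")
  structure(list(tau = tau, sigma = sigma, threshold = threshold,
                 p_below = p_below, p_above = p_above),
            class = "ddm_params")
}

#' @export
coef.ddm_params <- function(object, ...) {
  unlist(object[c("tau", "sigma", "threshold", "p_below", "p_above")])
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("<ddm_params>\n")
  print(signif(coef(x), 4))
  invisible(x)
}

#' Hand-tuned-like wild-type parameter set
#'
#' The default ground truth of the surrogate generator: chosen to reproduce the
#' qualitative wild-type coherent-dot features at dt = 0.01 s - a gradually
#' rising psychometric curve (~0.5 at 0% coherence through ~0.65 at 25% toward
#' the ~0.8 plateau imposed by the N(+/-22, 25) turn-angle draw), interbout
#' intervals near 1.2 s at rest shortening under coherent motion, plentiful
#' spontaneous turns at 0% coherence, and same-direction persistence decaying
#' on the sub-second timescale of the leak. Note that sigma is interpreted at
#' dt = 0.01 without sqrt(dt) scaling, so values well above 1 are the
#' behaviourally relevant regime (the stationary integrator SD is
#' sigma * sqrt(dt / 2 tau) ~ 0.7 here, comparable to the threshold).
#'
#' @return a [ddm_params()] object.
#' @export
default_ddm_params <- function() {
  ddm_params(tau = 0.65, sigma = 8, threshold = 0.5,
             p_below = 0.005, p_above = 0.011)
}

#' Coherent-dot stimulus protocol
#'
#' A sequence of epochs mirroring the motion assay: 0% coherence baseline for
#' `baseline_s` seconds, then coherent motion at each tested coherence for
#' `stim_s` seconds, in each direction, repeated `reps` times. Baseline epochs
#' are labelled with the direction of the *upcoming* coherent epoch, so that
#' "probability correct" is defined (and ~0.5) at 0% coherence.
#'
#' @param coherences coherence levels in percent (default 25, 50, 100).
#' @param directions stimulus directions, +1 rightward / -1 leftward.
#' @param baseline_s,stim_s epoch durations in seconds.
#' @param reps repetitions of the full block.
#' @param dt Euler time step, fixed at 0.01 s (the sigma convention depends on
#'   it).
#' @return an object of class `stimulus_protocol` with an `epochs` data frame.
#' @export
stimulus_protocol <- function(coherences = c(25, 50, 100), directions = c(1, -1),
                              baseline_s = 5, stim_s = 10, reps = 2L,
                              dt = 0.01) {
  stopifnot(all(coherences %in% c(25, 50, 100)), all(directions %in% c(-1, 1)),
            baseline_s > 0, stim_s > 0, reps >= 1)
  rows <- list()
  for (r in seq_len(reps)) for (ci in seq_along(coherences)) {
    # alternate the direction order between blocks so that the direction of
    # the epoch preceding each baseline is (nearly) balanced against the
    # baseline's own label; otherwise integrator carryover from the previous
    # coherent epoch biases the 0%-coherence accuracy away from 0.5
    dirs <- if ((r + ci) %% 2L == 0L) directions else rev(directions)
    for (dir in dirs) {
      rows[[length(rows) + 1L]] <-
        data.frame(duration_s = baseline_s, coherence_pct = 0, direction = dir)
      rows[[length(rows) + 1L]] <-
        data.frame(duration_s = stim_s, coherence_pct = coherences[ci],
                   direction = dir)
    }
  }
  epochs <- do.call(rbind, rows)
  epochs$epoch <- seq_len(nrow(epochs))
  epochs$start_s <- cumsum(c(0, epochs$duration_s))[seq_len(nrow(epochs))]
  structure(list(epochs = epochs, dt = dt,
                 baseline_s = baseline_s, stim_s = stim_s),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol: %d epochs, %.3g s total, dt = %g s>\n",
              nrow(x$epochs), sum(x$epochs$duration_s), x$dt))
  invisible(x)
}

# expand a protocol into per-step drive and labels
protocol_steps <- function(protocol) {
  ep <- protocol$epochs
  n_steps <- round(ep$duration_s / protocol$dt)
  idx <- rep(seq_len(nrow(ep)), n_steps)
  list(drive = ep$coherence_pct[idx] / 100 * ep$direction[idx],
       epoch = idx,
       coherence_pct = ep$coherence_pct[idx],
       stim_dir = ep$direction[idx],
       t = (seq_along(idx) - 1) * protocol$dt)
}

#' Simulate the drift-diffusion bout model
#'
#' Euler integration of `tau dX/dt = C(t) - X + N(0, sigma)` at dt = 0.01 s:
#' `X <- X + (C - X + N(0, sigma)) dt / tau`. At each step, if |X| < T a
#' forward bout is emitted with probability `p_below` (heading change drawn
#' from N(0, 5) degrees); if |X| >= T a turn toward sign(X) is emitted with
#' probability `p_above` (heading change from N(+/-22, 25) degrees, right
#' positive).
#'
#' @param params a [ddm_params()].
#' @param protocol a [stimulus_protocol()].
#' @param n_fish number of independent simulated fish.
#' @param seed integer seed.
#' @return a `bout_table` data frame (`fish_id`, `t_s`, `dheading_deg`,
#'   `coherence_pct`, `stim_dir`) with attribute `protocol`.
#' @export
simulate_ddm <- function(params, protocol = stimulus_protocol(), n_fish = 1L,
                         seed = NULL) {
  stopifnot(inherits(params, "ddm_params"), inherits(protocol, "stimulus_protocol"))
  st <- protocol_steps(protocol)
  res <- with_seed(seed, {
    ddm_sim_cpp(params$tau, params$sigma, params$threshold,
                params$p_below, params$p_above, st$drive, protocol$dt,
                as.integer(n_fish))
  })
  step <- res$step + 1L   # C++ is 0-based
  bouts <- data.frame(
    fish_id = sprintf("f%03d", res$fish + 1L),
    t_s = st$t[step],
    dheading_deg = res$dheading_deg,
    coherence_pct = st$coherence_pct[step],
    stim_dir = st$stim_dir[step])
  bouts <- bouts[order(bouts$fish_id, bouts$t_s), ]
  rownames(bouts) <- NULL
  class(bouts) <- c("bout_table", "data.frame")
  attr(bouts, "protocol") <- protocol
  bouts
}

#' @export
simulate.ddm_params <- function(object, nsim = 1L, seed = NULL,
                                protocol = stimulus_protocol(), ...) {
  simulate_ddm(object, protocol = protocol, n_fish = nsim, seed = seed)
}

#' Turn-angle mixture weights
#'
#' Fits the heading-change distribution with three fixed-shape Gaussian
#' components - left turns N(-22, 25), forward swims N(0, 5), right turns
#' N(+22, 25) (degrees) - estimating only the mixture weights ("peak heights")
#' by EM. Weights are normalized to sum to 1.
#'
#' @param heading_changes heading changes in degrees (>= 50 values).
#' @param means,sds component means and SDs (fixed during the fit).
#' @param max_iter,tol EM iteration cap and convergence tolerance.
#' @return named numeric vector `c(left, forward, right)` summing to 1.
#' @export
gmm3_weights <- function(heading_changes, means = c(-22, 0, 22),
                         sds = c(25, 5, 25), max_iter = 1000L, tol = 1e-10) {
  x <- heading_changes[is.finite(heading_changes)]
  if (length(x) < 50L) stopf("need at least 50 bouts for the mixture fit")
  dens <- vapply(1:3, function(k) dnorm(x, means[k], sds[k]), numeric(length(x)))
  w <- rep(1 / 3, 3)
  for (it in seq_len(max_iter)) {
    resp <- sweep(dens, 2, w, "*")
    rs <- rowSums(resp)
    if (any(rs == 0)) rs[rs == 0] <- .Machine$double.xmin
    resp <- resp / rs
    w_new <- colMeans(resp)
    if (max(abs(w_new - w)) < tol) {
      w <- w_new
      return(setNames(w, c("left", "forward", "right")))
    }
    w <- w_new
  }
  if (max(abs(colMeans(sweep(dens, 2, w, "*") / rowSums(sweep(dens, 2, w, "*"))) - w)) > 1e-6)
    stopf("mixture weight EM failed to converge after %d iterations (weights %s)",
          max_iter, paste(signif(w, 3), collapse = ", "))
  setNames(w, c("left", "forward", "right"))
}

#' Extract the five behavioural feature curves from a bout table
#'
#' Computes the five fitting objectives of the coherent-dot assay: (i)
#' probability to turn in the correct direction per coherence, (ii) mean
#' interbout interval per coherence, (iii) probability of consecutive turns in
#' the same direction at delays 0.125-1.375 s during 0% coherence, (iv) binned
#' probability correct as a function of time within the coherent epoch per
#' coherence, and (v) the three turn-angle mixture weights. Cells without data
#' are `NaN` and are excluded from fitting distances.
#'
#' @param bouts a `bout_table` (e.g. from [simulate_ddm()]).
#' @param protocol the [stimulus_protocol()] the bouts were recorded under
#'   (defaults to the table's `protocol` attribute).
#' @param turn_threshold_deg classification threshold, degrees (default 10).
#' @param acc_time_bin_s width of the within-epoch time bins (default 2.5 s).
#' @return an object of class `behavioral_features`.
#' @export
extract_features <- function(bouts, protocol = attr(bouts, "protocol"),
                             turn_threshold_deg = 10, acc_time_bin_s = 2.5) {
  if (is.null(protocol)) stopf("a stimulus_protocol is required")
  ep <- protocol$epochs
  bt <- as.data.frame(bouts)
  bt$epoch <- findInterval(bt$t_s + 1e-9, ep$start_s)
  bt$t_in_epoch <- bt$t_s - ep$start_s[bt$epoch]
  bt$is_turn <- abs(bt$dheading_deg) > turn_threshold_deg
  bt$correct <- sign(bt$dheading_deg) == bt$stim_dir
  cohs <- c(0, 25, 50, 100)
  prob_or_nan <- function(x) if (length(x)) mean(x) else NaN

  bt <- bt[order(bt$fish_id, bt$t_s), ]
  acc <- vapply(cohs, function(cc)
    prob_or_nan(bt$correct[bt$is_turn & bt$coherence_pct == cc]), 1.0)

  # interbout intervals: consecutive bouts of the same fish in the same epoch
  nb <- nrow(bt)
  ibi <- rep(NaN, length(cohs))
  if (nb > 1L) {
    i <- seq_len(nb - 1L)
    pair <- bt$fish_id[i] == bt$fish_id[i + 1L] & bt$epoch[i] == bt$epoch[i + 1L]
    d <- (bt$t_s[i + 1L] - bt$t_s[i])[pair]
    dcoh <- bt$coherence_pct[i][pair]
    ibi <- vapply(cohs, function(cc) prob_or_nan(d[dcoh == cc]), 1.0)
  }

  centers <- seq(0.125, 1.375, by = 0.25)
  same_dir <- rep(NaN, length(centers))
  b0 <- bt[bt$coherence_pct == 0 & bt$is_turn, ]
  if (nrow(b0) > 1L) {
    i <- seq_len(nrow(b0) - 1L)
    pair <- b0$fish_id[i] == b0$fish_id[i + 1L] & b0$epoch[i] == b0$epoch[i + 1L]
    delay <- (b0$t_s[i + 1L] - b0$t_s[i])[pair]
    same <- (sign(b0$dheading_deg[i + 1L]) == sign(b0$dheading_deg[i]))[pair]
    bin <- findInterval(delay, centers - 0.125)
    ok <- bin >= 1 & bin <= length(centers)
    for (b in seq_along(centers))
      same_dir[b] <- prob_or_nan(same[ok & bin == b])
  }

  stim_cohs <- sort(unique(ep$coherence_pct[ep$coherence_pct > 0]))
  tbreaks <- seq(0, protocol$stim_s, by = acc_time_bin_s)
  n_tbin <- length(tbreaks) - 1L
  acc_time <- matrix(NaN, length(stim_cohs), n_tbin,
                     dimnames = list(paste0("c", stim_cohs),
                                     paste0("t", tbreaks[-1])))
  bc <- bt[bt$coherence_pct > 0 & bt$is_turn, ]
  if (nrow(bc)) {
    bin <- pmin(pmax(ceiling(bc$t_in_epoch / acc_time_bin_s), 1L), n_tbin)
    for (ci in seq_along(stim_cohs)) for (b in seq_len(n_tbin)) {
      sel <- bc$coherence_pct == stim_cohs[ci] & bin == b
      if (any(sel)) acc_time[ci, b] <- mean(bc$correct[sel])
    }
  }

  gmm <- if (sum(is.finite(bt$dheading_deg)) >= 50L)
    gmm3_weights(bt$dheading_deg) else setNames(rep(NaN, 3), c("left", "forward", "right"))

  structure(list(
    acc_vs_coherence = setNames(acc, paste0("c", cohs)),
    ibi_vs_coherence = setNames(ibi, paste0("c", cohs)),
    same_dir_vs_delay = setNames(same_dir, paste0("d", centers)),
    acc_vs_time = acc_time,
    gmm_weights = gmm,
    n_bouts = nrow(bt), turn_threshold_deg = turn_threshold_deg),
    class = "behavioral_features")
}

#' @export
print.behavioral_features <- function(x, ...) {
  cat(sprintf("<behavioral_features from %d bouts>\n", x$n_bouts))
  cat("  p(correct) vs coherence: ",
      paste(signif(x$acc_vs_coherence, 3), collapse = " "), "\n")
  cat("  interbout interval (s):  ",
      paste(signif(x$ibi_vs_coherence, 3), collapse = " "), "\n")
  cat("  same-direction vs delay: ",
      paste(signif(x$same_dir_vs_delay, 3), collapse = " "), "\n")
  cat("  turn-angle GMM weights:  ",
      paste(signif(x$gmm_weights, 3), collapse = " "), "\n")
  invisible(x)
}
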