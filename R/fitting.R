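#' Default parameter bounds for the multiobjective fit
#'
#' Brackets behaviourally plausible larval bout statistics at dt = 0.01 s:
#' leak time constants from a tenth of a second to five seconds (the measured
#' same-direction persistence decays within ~1.5 s), thresholds on the scale
#' of the coherence drive (0-1), per-step event probabilities giving bout
#' rates between ~0.1 and ~5 per second, and per-step noise up to 20 -
#' remember sigma is unscaled by sqrt(dt), so the stationary integrator SD is
#' sigma * sqrt(dt / 2 tau) and sigma of order 5-10 is the regime in which
#' the psychometric curve rises gradually rather than saturating. Keeping the
#' bounds behaviourally tight also keeps the 75th-percentile objective
#' normalizers meaningful: bounds admitting 100 s interbout intervals inflate
#' the interbout normalizer until that objective loses all influence.
#'
#' @return named list of `c(lower, upper)` bounds for the five parameters.
#' @export
default_ddm_bounds <- function() {
  list(tau = c(0.1, 5), sigma = c(0, 20), threshold = c(0.01, 2),
       p_below = c(1e-3, 0.05), p_above = c(1e-3, 0.05))
}

ddm_param_names <- c("tau", "sigma", "threshold", "p_below", "p_above")
log_scaled <- c(tau = TRUE, sigma = FALSE, threshold = TRUE,
                p_below = TRUE, p_above = TRUE)

params_from_unit <- function(u, bounds) {
  x <- numeric(5)
  for (k in seq_len(5)) {
    b <- bounds[[ddm_param_names[k]]]
    x[k] <- if (log_scaled[k]) exp(log(b[1]) + u[k] * (log(b[2]) - log(b[1])))
            else b[1] + u[k] * (b[2] - b[1])
  }
  ddm_params(x[1], x[2], x[3], x[4], x[5])
}

feature_curves <- function(f) {
  list(acc = f$acc_vs_coherence, ibi = f$ibi_vs_coherence,
       samedir = f$same_dir_vs_delay, acc_time = as.vector(f$acc_vs_time),
       gmm = f$gmm_weights)
}

#' Distances between two behavioural feature sets
#'
#' One distance per objective: the mean squared error between the model and
#' target curves for accuracy-vs-coherence, interbout interval, same-direction
#' persistence and accuracy-vs-time, and the MSE between the three turn-angle
#' mixture weights. Bins missing (NaN) on either side are excluded; a curve
#' with no shared bins yields `Inf`. `metric = "msle"` uses the mean squared
#' logarithmic error instead, which gives comparable fits.
#'
#' @param model,target [extract_features()] results with matching bin
#'   structures.
#' @param metric "mse" (default) or "msle".
#' @return named numeric vector `c(d_acc, d_ibi, d_samedir, d_acc_time, d_gmm)`.
#' @export
feature_distances <- function(model, target, metric = c("mse", "msle")) {
  metric <- match.arg(metric)
  stopifnot(inherits(model, "behavioral_features"),
            inherits(target, "behavioral_features"))
  cm <- feature_curves(model); ct <- feature_curves(target)
  d <- vapply(names(cm), function(nm) {
    a <- cm[[nm]]; b <- ct[[nm]]
    if (length(a) != length(b))
      stopf("bin structure mismatch in feature '%s' (%d vs %d bins)",
            nm, length(a), length(b))
    ok <- is.finite(a) & is.finite(b)
    if (!any(ok)) return(Inf)
    if (metric == "msle") mean((log1p(a[ok]) - log1p(b[ok]))^2)
    else mean((a[ok] - b[ok])^2)
  }, 1.0)
  setNames(d, c("d_acc", "d_ibi", "d_samedir", "d_acc_time", "d_gmm"))
}

#' Compromise error
#'
#' Weighted sum of the five objective distances after normalization by the
#' 75th percentile of the initial error distribution, with weight 3 on the
#' interbout-interval distance and 1 on the others.
#'
#' @param d distance vector (see [feature_distances()]).
#' @param norms positive normalizers, one per objective.
#' @param weights objective weights (default `c(1, 3, 1, 1, 1)` for acc, ibi,
#'   samedir, acc_time, gmm).
#' @return scalar compromise error.
#' @export
compromise_error <- function(d, norms, weights = c(1, 3, 1, 1, 1)) {
  stopifnot(length(d) == length(norms), length(d) == length(weights))
  if (any(norms <= 0)) stopf("normalizers must be > 0")
  sum(weights * d / norms)
}

# i dominates j: no worse in every objective, strictly better in one
domination_matrix <- function(M) {
  n <- nrow(M)
  le <- matrix(0L, n, n); lt <- matrix(0L, n, n)
  for (k in seq_len(ncol(M))) {
    le <- le + outer(M[, k], M[, k], "<=")
    lt <- lt + outer(M[, k], M[, k], "<")
  }
  (le == ncol(M)) & (lt > 0L)
}

nds_rank <- function(M) {
  n <- nrow(M)
  D <- domination_matrix(M)
  rank <- rep(NA_integer_, n)
  remaining <- rep(TRUE, n)
  r <- 1L
  while (any(remaining)) {
    ndom <- remaining & (colSums(D[remaining, , drop = FALSE]) == 0L)
    if (!any(ndom)) ndom <- remaining   # safety for degenerate ties
    rank[ndom] <- r
    remaining[ndom] <- FALSE
    D[ndom, ] <- FALSE
    r <- r + 1L
  }
  rank
}

crowding_distance <- function(M) {
  n <- nrow(M)
  if (n <= 2L) return(rep(Inf, n))
  cd <- numeric(n)
  for (k in seq_len(ncol(M))) {
    v <- M[, k]
    v[!is.finite(v)] <- max(v[is.finite(v)], 0) + 1
    o <- order(v)
    rng <- v[o[n]] - v[o[1]]
    cd[o[c(1, n)]] <- Inf
    if (rng > 0)
      cd[o[2:(n - 1)]] <- cd[o[2:(n - 1)]] + (v[o[3:n]] - v[o[1:(n - 2)]]) / rng
  }
  cd
}

sbx_crossover <- function(p1, p2, eta = 15) {
  u <- runif(length(p1))
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  c1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
  c2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
  list(pmin(pmax(c1, 0), 1), pmin(pmax(c2, 0), 1))
}

poly_mutate <- function(x, pm = 0.2, eta = 20) {
  hit <- runif(length(x)) < pm
  if (any(hit)) {
    u <- runif(sum(hit))
    delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta + 1)) - 1,
                    1 - (2 * (1 - u))^(1 / (eta + 1)))
    x[hit] <- pmin(pmax(x[hit] + delta, 0), 1)
  }
  x
}

#' Fit the drift-diffusion model to behavioural features
#'
#' Evolutionary multiobjective (NSGA-II-style) recovery of the five latent
#' model parameters from the five feature curves. A random initial population
#' of parameter sets is evaluated by simulating the model (a fixed
#' per-individual budget of `n_fish_eval` fish, fresh child seed per
#' individual) and computing the five [feature_distances()] to the target; the
#' 75th percentile of each initial error distribution is frozen as its
#' normalizer. Selection uses nondominated rank and crowding distance, with
#' simulated binary crossover and polynomial mutation on log-scaled parameters,
#' elitist (mu + lambda) survival, and explicit retention of the
#' compromise-minimal individual. The returned best individual is the
#' compromise-minimal member of the final population.
#'
#' @param target a [behavioral_features()] target (e.g. from
#'   [gen_surrogate_cdomr()] + [extract_features()]).
#' @param protocol the [stimulus_protocol()] used for evaluation simulations.
#' @param pop_size population size (default 800; 100 is a practical
#'   desk-scale setting).
#' @param generations number of generations (default 80; 30 at desk scale).
#' @param bounds parameter bounds, see [default_ddm_bounds()].
#' @param n_fish_eval simulated fish per objective evaluation.
#' @param seed integer root seed; the fit is deterministic given it.
#' @param metric distance metric, "mse" or "msle".
#' @param acc_time_bin_s time-bin width for the accuracy-vs-time feature
#'   (passed to [extract_features()]; must match the target's binning).
#' @param n_repeats number of independent optimization repeats; the repeat
#'   whose best individual has the smallest re-evaluated compromise error
#'   (under the first repeat's normalizers) is returned. Repeating the
#'   optimization and comparing bests is the procedure's own consistency
#'   check.
#' @param verbose print per-generation progress.
#' @return an object of class `ddm_fit`.
#' @export
fit_ddm <- function(target, protocol = stimulus_protocol(), pop_size = 800L,
                    generations = 80L, bounds = default_ddm_bounds(),
                    n_fish_eval = 12L, seed = 1L, metric = c("mse", "msle"),
                    acc_time_bin_s = 2.5, n_repeats = 1L, verbose = FALSE) {
  metric <- match.arg(metric)
  stopifnot(inherits(target, "behavioral_features"), pop_size >= 4L)
  if (n_repeats > 1L) {
    fits <- lapply(seq_len(n_repeats), function(r)
      fit_ddm(target, protocol, pop_size, generations, bounds, n_fish_eval,
              seed = child_seed(seed, paste0("repeat", r)), metric = metric,
              acc_time_bin_s = acc_time_bin_s, n_repeats = 1L,
              verbose = verbose))
    norms <- fits[[1]]$norms
    scores <- vapply(seq_along(fits), function(r) {
      d <- rowMeans(vapply(1:6, function(k) {
        b <- simulate_ddm(fits[[r]]$best, protocol, n_fish = 2L * n_fish_eval,
                          seed = child_seed(seed, paste0("pick", r, "_", k)))
        feature_distances(extract_features(b, protocol,
                                           acc_time_bin_s = acc_time_bin_s),
                          target, metric)
      }, numeric(5)))
      compromise_error(d, norms)
    }, 1.0)
    best <- fits[[which.min(scores)]]
    best$repeat_scores <- scores
    return(best)
  }
  evaluate <- function(u, tag) {
    p <- params_from_unit(u, bounds)
    d <- tryCatch({
      b <- simulate_ddm(p, protocol, n_fish = n_fish_eval,
                        seed = child_seed(seed, tag))
      feature_distances(extract_features(b, protocol,
                                         acc_time_bin_s = acc_time_bin_s),
                        target, metric)
    }, error = function(e) rep(Inf, 5))
    d[!is.finite(d)] <- Inf
    d
  }
  with_seed(child_seed(seed, "nsga"), {
    # Latin hypercube start: one sample per row-stratum and dimension
    U <- vapply(1:5, function(k) (sample(pop_size) - runif(pop_size)) / pop_size,
                numeric(pop_size))
    Dm <- t(vapply(seq_len(pop_size),
                   function(i) evaluate(U[i, ], paste0("g0_", i)), numeric(5)))
    norms <- apply(Dm, 2, function(v) {
      q <- quantile(v[is.finite(v)], 0.75, names = FALSE)
      max(q, 1e-12)
    })
    comp <- apply(Dm, 1, compromise_error, norms = norms)
    n_evals <- rep(1L, pop_size)
    history <- min(comp)
    # archive of per-generation compromise leaders: candidates for the final
    # refinement may come from any point of the run, not just the survivors
    archive <- U[which.min(comp), , drop = FALSE]
    for (gen in seq_len(generations)) {
      # resample the current leaders: objectives are stochastic, and without
      # fresh evaluations a single lucky draw would anchor the population in
      # its basin; running means give long-lived individuals honest scores
      for (i in utils::head(order(comp), 10L)) {
        d_new <- evaluate(U[i, ], paste0("resample", gen, "_", i))
        Dm[i, ] <- (Dm[i, ] * n_evals[i] + d_new) / (n_evals[i] + 1L)
        n_evals[i] <- n_evals[i] + 1L
        comp[i] <- compromise_error(Dm[i, ], norms)
      }
      rk <- nds_rank(Dm)
      # With five objectives most of a small population is nondominated
      # ("dominance resistance"), so rank alone exerts almost no selection
      # pressure; ties are broken by the compromise error, the scalarization
      # the procedure ultimately selects its best individual by.
      pick <- function() {
        ij <- sample.int(pop_size, 2L)
        i <- ij[1]; j <- ij[2]
        if (rk[i] < rk[j] || (rk[i] == rk[j] && comp[i] < comp[j])) i else j
      }
      Uo <- matrix(NA_real_, pop_size, 5)
      i <- 1L
      while (i <= pop_size) {
        pa <- U[pick(), ]; pb <- U[pick(), ]
        kids <- if (runif(1) < 0.9) sbx_crossover(pa, pb) else list(pa, pb)
        Uo[i, ] <- poly_mutate(kids[[1]])
        if (i + 1L <= pop_size) Uo[i + 1L, ] <- poly_mutate(kids[[2]])
        i <- i + 2L
      }
      Do <- t(vapply(seq_len(pop_size),
                     function(i) evaluate(Uo[i, ], paste0("g", gen, "_", i)),
                     numeric(5)))
      Ua <- rbind(U, Uo); Da <- rbind(Dm, Do)
      ca <- apply(Da, 1, compromise_error, norms = norms)
      ra <- nds_rank(Da)
      # survival: nondominated rank first, crowding keeps some spread within
      # the front, compromise decides the remainder of the ordering
      cda <- numeric(nrow(Da))
      for (r in unique(ra)) cda[ra == r] <- crowding_distance(Da[ra == r, , drop = FALSE])
      n_spread <- ceiling(pop_size / 4)
      by_spread <- order(ra, -cda)
      by_comp <- order(ra, ca)
      keep <- unique(c(by_spread[seq_len(n_spread)], by_comp))[seq_len(pop_size)]
      best_all <- which.min(ca)
      if (!(best_all %in% keep)) keep[pop_size] <- best_all
      na <- c(n_evals, rep(1L, pop_size))
      U <- Ua[keep, , drop = FALSE]
      Dm <- Da[keep, , drop = FALSE]
      comp <- ca[keep]
      n_evals <- na[keep]
      archive <- rbind(archive, U[which.min(comp), , drop = FALSE])
      # running minimum: with resampled objectives the raw population minimum
      # can tick upward as lucky draws are averaged out
      history <- c(history, min(history[length(history)], min(comp)))
      if (verbose)
        message(sprintf("generation %3d: min compromise %.4f", gen, min(comp)))
    }
    # Re-evaluate the leading candidates with fresh simulation budgets before
    # picking the single best: objectives are stochastic, a single lucky
    # evaluation would otherwise win the compromise ranking, and a basin
    # visited mid-run can beat every survivor. Re-evaluation is cheap relative
    # to the evolutionary loop, so the refinement is made near-noiseless.
    n_cand <- min(pop_size, 20L)
    cand_u <- unique(rbind(U[order(comp)[seq_len(n_cand)], , drop = FALSE],
                           archive))
    refined <- vapply(seq_len(nrow(cand_u)), function(ci) {
      d6 <- vapply(1:6, function(r) {
        p <- params_from_unit(cand_u[ci, ], bounds)
        d <- tryCatch({
          b <- simulate_ddm(p, protocol, n_fish = 2L * n_fish_eval,
                            seed = child_seed(seed, paste0("refine", ci, "_", r)))
          feature_distances(extract_features(b, protocol,
                                             acc_time_bin_s = acc_time_bin_s),
                            target, metric)
        }, error = function(e) rep(Inf, 5))
        d[!is.finite(d)] <- Inf
        d
      }, numeric(5))
      compromise_error(rowMeans(d6), norms)
    }, 1.0)
    best_u <- cand_u[which.min(refined), ]
    best_score <- min(refined)
    # memetic polish: greedy coordinate steps in the unit parameter space,
    # scored at the same high-precision budget; evolutionary search localizes
    # the basin, this stage walks the remaining offset (typically in the
    # threshold) down
    score_u <- function(u, tag) {
      d6 <- vapply(1:6, function(r) {
        p <- params_from_unit(u, bounds)
        d <- tryCatch({
          b <- simulate_ddm(p, protocol, n_fish = 2L * n_fish_eval,
                            seed = child_seed(seed, paste0(tag, "_", r)))
          feature_distances(extract_features(b, protocol,
                                             acc_time_bin_s = acc_time_bin_s),
                            target, metric)
        }, error = function(e) rep(Inf, 5))
        d[!is.finite(d)] <- Inf
        d
      }, numeric(5))
      compromise_error(rowMeans(d6), norms)
    }
    for (round in 1:3) {
      delta <- c(0.08, 0.04, 0.02)[round]
      for (k in 1:5) for (dir in c(-1, 1)) {
        u_try <- best_u
        u_try[k] <- min(max(u_try[k] + dir * delta, 0), 1)
        if (u_try[k] == best_u[k]) next
        s_try <- score_u(u_try, paste0("polish", round, "_", k, "_", dir))
        if (s_try < best_score) {
          best_u <- u_try; best_score <- s_try
        }
      }
    }
    # the refined winner replaces the worst survivor, keeping the invariant
    # that the reported best is a member of the final population
    worst_i <- which.max(comp)
    U[worst_i, ] <- best_u
    Dm[worst_i, ] <- rowMeans(vapply(1:3, function(r)
      evaluate(best_u, paste0("final", r)), numeric(5)))
    comp[worst_i] <- compromise_error(Dm[worst_i, ], norms)
    best_i <- worst_i
    pop_params <- t(vapply(seq_len(pop_size),
                           function(i) coef(params_from_unit(U[i, ], bounds)),
                           numeric(5)))
    structure(list(
      best = params_from_unit(U[best_i, ], bounds),
      best_distances = setNames(Dm[best_i, ],
                                c("d_acc", "d_ibi", "d_samedir", "d_acc_time", "d_gmm")),
      best_compromise = comp[best_i],
      norms = setNames(norms, c("d_acc", "d_ibi", "d_samedir", "d_acc_time", "d_gmm")),
      population = list(params = pop_params, distances = Dm, compromise = comp),
      history = history, target = target, protocol = protocol,
      bounds = bounds, settings = list(pop_size = pop_size,
                                       generations = generations,
                                       n_fish_eval = n_fish_eval,
                                       metric = metric, seed = seed)),
      class = "ddm_fit")
  })
}

#' @export
coef.ddm_fit <- function(object, ...) coef(object$best)

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("<ddm_fit: pop %d, %d generations, compromise error %.4f>\n",
              x$settings$pop_size, x$settings$generations, x$best_compromise))
  print(signif(coef(x), 4))
  invisible(x)
}

#' @export
summary.ddm_fit <- function(object, ...) {
  cat("Multiobjective drift-diffusion fit\n")
  print(object)
  cat("\nObjective distances of the best individual (raw / normalized):\n")
  print(signif(rbind(raw = object$best_distances,
                     normalized = object$best_distances / object$norms), 4))
  cat(sprintf("\nCompromise error trajectory: %.4f -> %.4f over %d generations\n",
              object$history[1], object$history[length(object$history)],
              length(object$history) - 1))
  invisible(object)
}

#' @export
plot.ddm_fit <- function(x, ...) {
  plot(seq_along(x$history) - 1, x$history, type = "b", pch = 16,
       xlab = "generation", ylab = "minimum compromise error", ...)
  invisible(x)
}

#' @export
simulate.ddm_fit <- function(object, nsim = 1L, seed = NULL, ...) {
  simulate_ddm(object$best, object$protocol, n_fish = nsim, seed = seed)
}

#' Nondominated (Pareto) front of a fit's final population
#'
#' @param fit a [fit_ddm()] result.
#' @return integer indices of the mutually nondominated final individuals.
#' @export
pareto_front <- function(fit) {
  stopifnot(inherits(fit, "ddm_fit"))
  which(nds_rank(fit$population$distances) == 1L)
}

#' Surrogate parameter-recovery report
#'
#' The validation strategy of the fitting machinery: generate surrogate
#' coherent-dot data from known parameters, fit, and tabulate true vs recovered
#' values with relative errors, over `n_repeats` independent repeats.
#'
#' @param true_params the generating [ddm_params()].
#' @param n_repeats number of independent fit repeats.
#' @param protocol stimulus protocol for both surrogate and evaluations.
#' @param n_fish_target fish simulated for the surrogate target.
#' @param seed root seed.
#' @param ... passed to [fit_ddm()] (e.g. `pop_size`, `generations`).
#' @return data frame with one row per repeat x parameter: `repeat_`,
#'   `parameter`, `true`, `recovered`, `rel_error`.
#' @export
surrogate_recovery_report <- function(true_params, n_repeats = 3L,
                                      protocol = stimulus_protocol(),
                                      n_fish_target = 40L, seed = 1L, ...) {
  rows <- list()
  for (r in seq_len(n_repeats)) {
    bouts <- gen_surrogate_cdomr(true_params, protocol,
                                 seed = child_seed(seed, paste0("target", r)),
                                 n_fish = n_fish_target)
    target <- extract_features(bouts, protocol)
    fit <- fit_ddm(target, protocol, seed = child_seed(seed, paste0("fit", r)),
                   ...)
    tv <- coef(true_params); rv <- coef(fit)
    rows[[r]] <- data.frame(repeat_ = r, parameter = names(tv),
                            true = unname(tv), recovered = unname(rv),
                            rel_error = unname(abs(rv - tv) / abs(tv)))
  }
  do.call(rbind, rows)
}
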