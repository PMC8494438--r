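make_features <- function(seed = 5, n_fish = 10) {
  pr <- stimulus_protocol(reps = 1)
  extract_features(simulate_ddm(default_ddm_params(), pr, n_fish = n_fish,
                                seed = seed), pr)
}

test_that("feature distances are zero at identity, symmetric, and MSE-exact", {
  f <- make_features()
  expect_equal(unname(feature_distances(f, f)), rep(0, 5))
  g <- f
  g$acc_vs_coherence <- f$acc_vs_coherence + 0.1
  d <- feature_distances(g, f)
  expect_equal(unname(d["d_acc"]), 0.01, tolerance = 1e-12)
  expect_equal(feature_distances(g, f), feature_distances(f, g))
  # mismatched bin structure is an error
  h <- f
  h$same_dir_vs_delay <- f$same_dir_vs_delay[1:3]
  expect_error(feature_distances(h, f), "mismatch")
})

test_that("compromise error weights (1,3,1,1,1) and is linear in each distance", {
  norms <- rep(1, 5)
  expect_equal(compromise_error(rep(0, 5), norms), 0)
  expect_equal(compromise_error(rep(1, 5), norms), 7)
  d <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  base <- compromise_error(d, norms)
  d2 <- d; d2[2] <- d2[2] + 0.1
  expect_equal(compromise_error(d2, norms) - base, 3 * 0.1, tolerance = 1e-12)
  expect_error(compromise_error(d, c(1, 0, 1, 1, 1)), "normalizers")
})

test_that("a small fit is deterministic, elitist, and yields a nondominated front", {
  target <- make_features(seed = 12, n_fish = 15)
  pr <- stimulus_protocol(reps = 1)
  fit1 <- fit_ddm(target, pr, pop_size = 20L, generations = 4L,
                  n_fish_eval = 6L, seed = 5)
  fit2 <- fit_ddm(target, pr, pop_size = 20L, generations = 4L,
                  n_fish_eval = 6L, seed = 5)
  expect_equal(coef(fit1), coef(fit2))
  expect_equal(fit1$history, fit2$history)
  # elitism: population-minimum compromise error never increases
  expect_true(all(diff(fit1$history) <= 1e-12))
  # the selected best belongs to the final population
  expect_true(any(apply(fit1$population$params, 1,
                        function(p) all(p == coef(fit1)))))
  # brute-force dominance check of the reported Pareto front
  front <- pareto_front(fit1)
  Dm <- fit1$population$distances
  dominates <- function(a, b) all(a <= b) && any(a < b)
  for (i in front) for (j in front) {
    if (i != j) expect_false(dominates(Dm[i, ], Dm[j, ]))
  }
  # and every non-front member is dominated by some front member
  others <- setdiff(seq_len(nrow(Dm)), front)
  for (j in others) {
    expect_true(any(vapply(front, function(i) dominates(Dm[i, ], Dm[j, ]), TRUE)))
  }
})

test_that("fits from different seeds reach comparable compromise errors", {
  target <- make_features(seed = 30, n_fish = 15)
  pr <- stimulus_protocol(reps = 1)
  fa <- fit_ddm(target, pr, pop_size = 24L, generations = 6L,
                n_fish_eval = 6L, seed = 101)
  fb <- fit_ddm(target, pr, pop_size = 24L, generations = 6L,
                n_fish_eval = 6L, seed = 202)
  # same normalizer basis for comparability
  ca <- compromise_error(fa$best_distances, fa$norms)
  cb <- compromise_error(fb$best_distances, fa$norms)
  expect_lt(max(ca, cb) / min(ca, cb), 2)
})

test_that("the recovery report tabulates repeats x parameters with relative errors", {
  rep_tab <- surrogate_recovery_report(default_ddm_params(), n_repeats = 2L,
                                       protocol = stimulus_protocol(reps = 1),
                                       n_fish_target = 10L, pop_size = 12L,
                                       generations = 2L, n_fish_eval = 4L,
                                       seed = 9)
  expect_equal(nrow(rep_tab), 2L * 5L)
  expect_setequal(unique(rep_tab$parameter),
                  c("tau", "sigma", "threshold", "p_below", "p_above"))
  expect_true(all(rep_tab$rel_error >= 0))
  expect_equal(rep_tab$rel_error,
               abs(rep_tab$recovered - rep_tab$true) / abs(rep_tab$true))
})
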