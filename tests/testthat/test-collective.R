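test_that("perceived clutter matches the closed form and its symmetries", {
  # single neighbour straight right at one body length
  pos <- rbind(c(0, 0), c(0, -20))
  expect_equal(perceived_clutter(pos, c(0, 0), 1, fishsize = 20),
               2 * atan(0.5), tolerance = 1e-12)
  # mirror pair cancels exactly
  pos3 <- rbind(c(0, 0), c(10, -30), c(10, 30))
  expect_equal(perceived_clutter(pos3, c(0, 0, 0), 1, fishsize = 20), 0,
               tolerance = 1e-12)
  # vanishes with distance
  far <- function(d) perceived_clutter(rbind(c(0, 0), c(0, -d)), c(0, 0), 1, 20)
  expect_gt(far(50), far(200))
  expect_lt(far(5000), 0.005)
})

test_that("perceived motion nulls (radial, parallel) are exact and transitions smooth", {
  pos <- rbind(c(0, 0), c(80, 0))
  h <- c(0, pi)
  # looming: neighbour approaches the focal fish radially
  expect_equal(perceived_motion(pos, h, rbind(c(0, 0), c(-30, 0)), 1), 0)
  # radial recession
  expect_equal(perceived_motion(pos, h, rbind(c(0, 0), c(30, 0)), 1), 0)
  # parallel swimming (identical velocity vectors)
  v <- rbind(c(12, 7), c(12, 7))
  pos2 <- rbind(c(0, 0), c(40, 55))
  expect_equal(perceived_motion(pos2, c(0.3, 0.3), v, 1), 0)
  # distance monotonicity for identical lateral motion
  lat <- function(d) abs(perceived_motion(rbind(c(0, 0), c(d, 0)), c(0, 0),
                                          rbind(c(0, 0), c(0, 25)), 1))
  expect_gt(lat(50), lat(100))
  expect_gt(lat(100), lat(200))
  # continuity across the lateral (front/back) boundary and straight behind
  m_at <- function(phi) {
    p <- rbind(c(0, 0), 100 * c(cos(phi), sin(phi)))
    perceived_motion(p, c(0, 0), rbind(c(0, 0), c(-10, 18)), 1)
  }
  eps <- 1e-6
  for (b in c(pi / 2, -pi / 2, pi)) {
    expect_lt(abs(m_at(b + eps) - m_at(b - eps)), 1e-4)
  }
})

test_that("sensory evidence is the weighted linear combination with genotype factor", {
  pos <- rbind(c(0, 0), c(30, -40), c(-20, 60))
  h <- c(0.1, -1, 2)
  v <- rbind(c(5, 0), c(-3, 8), c(0, -6))
  cfg1 <- collective_config(f_clutter = -1, w_motion = 0)
  cfg2 <- collective_config(f_clutter = -2, w_motion = 0)
  e1 <- sensory_evidence(pos, h, v, 1, cfg1)
  e2 <- sensory_evidence(pos, h, v, 1, cfg2)
  expect_equal(e1, -perceived_clutter(pos, h, 1, 20), tolerance = 1e-12)
  expect_equal(e2, 2 * e1, tolerance = 1e-12)
  cfg3 <- collective_config(f_clutter = +1, w_motion = 0)
  expect_equal(sensory_evidence(pos, h, v, 1, cfg3), -e1, tolerance = 1e-12)
  # R reference and compiled simulator agree on random states
  set.seed(3)
  for (k in 1:20) {
    pos <- matrix(runif(10, -300, 300), 5, 2)
    h <- runif(5, -pi, pi)
    v <- matrix(rnorm(10, 0, 30), 5, 2)
    cfg <- collective_config(f_clutter = runif(1, -3, 3))
    focal <- sample(5, 1)
    expect_equal(
      sensory_evidence(pos, h, v, focal, cfg),
      shoalmodel:::evidence_cpp(pos, h, v, focal, 20, cfg$f_clutter, 1, 1),
      tolerance = 1e-10)
  }
})

test_that("genotype clutter factors match the published table", {
  expect_equal(genotype_factor("scn1lab_allele2_+/-", 7), -2)
  expect_equal(genotype_factor("disc1_-/-", 21), +2)
  expect_equal(genotype_factor("scn1lab_allele2_+/+", 21), +3)
  expect_equal(genotype_factor("scn1lab_allele2_+/+", 7), -1)
  expect_equal(genotype_factor("disc1_+/+", 21), +1)
  expect_error(genotype_factor("scn1lab_allele3_+/+", 7), "unknown genotype")
  tab <- genotype_factors()
  expect_equal(nrow(tab), 12L)
  expect_true(all(tab$f_clutter[tab$age_dpf == 7] < 0))
  expect_true(all(tab$f_clutter[tab$age_dpf == 21] > 0))
})

test_that("agents never leave the arena and zero probabilities freeze them", {
  cfg <- collective_config(f_clutter = 3, duration_s = 60)
  rec <- simulate_group(cfg, n_runs = 1, seed = 14)[[1]]
  rad <- sqrt(rec$positions[, , 1]^2 + rec$positions[, , 2]^2)
  expect_true(all(rad <= cfg$arena_diameter_px / 2 + 1e-6))
  expect_true(all(rec$orientations > -pi & rec$orientations <= pi))
  frozen_p <- ddm_params(0.65, 8, 0.5, 0, 0)
  cfg0 <- collective_config(ddm_params = frozen_p, duration_s = 5)
  rec0 <- simulate_group(cfg0, n_runs = 1, seed = 3)[[1]]
  expect_equal(rec0$positions[1, , ], rec0$positions[dim(rec0$positions)[1], , ],
               tolerance = 1e-12)
})

test_that("step_agents mirrors the simulator contract on containment and freezing", {
  cfg <- collective_config(duration_s = 1)
  set.seed(6)
  st <- agent_state(matrix(runif(10, -100, 100), 5, 2), runif(5, -pi, pi))
  for (k in 1:200) st <- step_agents(st, cfg)
  expect_true(all(sqrt(rowSums(st$positions^2)) <= cfg$arena_diameter_px / 2))
  expect_true(all(st$headings > -pi & st$headings <= pi))
  cfg0 <- collective_config(ddm_params = ddm_params(0.65, 8, 0.5, 0, 0))
  st0 <- agent_state(matrix(c(10, 20, -30, 5, 0, -12, 40, 8, -9, 3), 5, 2),
                     rep(0.5, 5))
  p0 <- st0$positions
  for (k in 1:50) st0 <- step_agents(st0, cfg0)
  expect_equal(st0$positions, p0, tolerance = 1e-12)
})

test_that("spontaneous bout statistics match the decision model's stationary law", {
  # single agent, both rules off: bout log reflects pure threshold dynamics
  p <- default_ddm_params()
  cfg <- collective_config(ddm_params = p, f_clutter = 0, w_clutter = 0,
                           w_motion = 0, n_fish = 1, duration_s = 2400)
  rec <- simulate_group(cfg, n_runs = 1, seed = 42, return_bouts = TRUE)[[1]]
  bouts <- attr(rec, "bouts")
  expect_gt(nrow(bouts), 1000)
  # exact stationary SD of the AR(1) integrator
  a <- cfg$dt / p$tau
  sd_x <- p$sigma * a / sqrt(1 - (1 - a)^2)
  p_above_frac <- 2 * pnorm(-p$threshold / sd_x)
  turn_rate <- p_above_frac * p$p_above
  fwd_rate <- (1 - p_above_frac) * p$p_below
  expect_equal(mean(bouts$is_turn), turn_rate / (turn_rate + fwd_rate),
               tolerance = 0.05)
  # heading-change draws: N(0,5) forward; N(+/-22,25) turns, left/right balanced
  fwd <- bouts$dheading_deg[!bouts$is_turn]
  trn <- bouts$dheading_deg[bouts$is_turn]
  expect_equal(mean(fwd), 0, tolerance = 0.5)
  expect_equal(sd(fwd), 5, tolerance = 0.5)
  expect_equal(sd(trn[trn > 0] - 0), 25, tolerance = 8)  # loose: mixture tail
  expect_equal(mean(trn > 0), 0.5, tolerance = 0.05)
  w <- gmm3_weights(bouts$dheading_deg)
  # component overlap leaks some forward mass into the turn components, so
  # compare with an absolute margin
  expect_lt(abs(unname(w["forward"]) - fwd_rate / (turn_rate + fwd_rate)), 0.08)
})

test_that("the sign of the clutter factor sets the sign of aggregation", {
  mk <- function(f) {
    cfg <- collective_config(f_clutter = f, duration_s = 240)
    recs <- simulate_group(cfg, n_runs = 12, seed = 31)
    aggregation_index(recs, shuffle_seed = 8)$mean_aggregation
  }
  agg_pos <- mk(+3); agg_neg <- mk(-3)
  expect_gt(agg_pos, 0.3)
  expect_lt(agg_neg, -0.02)
  expect_gt(agg_pos, agg_neg)
})
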