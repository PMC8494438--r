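test_that("ray caster resolution and broadside angles match the geometric oracle", {
  L <- 20
  sc <- scene(c(30, -40))   # irrelevant placement; just to query resolution
  occ <- raycast_occupancy(sc$positions, sc$headings, 1, body_length = L)
  expect_equal(occ$resolution_deg, 165 / 1000)
  for (d in c(30, 60, 120)) {
    # broadside: neighbour straight right (bearing -90), body perpendicular to
    # the line of sight (heading 0)
    sc <- scene(c(0, -d), neighbour_heading = 0)
    occ <- raycast_occupancy(sc$positions, sc$headings, 1, body_length = L,
                             n_rays = 1000)
    oracle <- 2 * atan(L / (2 * d)) * 180 / pi
    expect_lt(abs(occ$right_deg - oracle), 2 * occ$resolution_deg)
    expect_equal(occ$left_deg, 0)
  }
})

test_that("rear blind zone, mirror symmetry and occlusion behave geometrically", {
  # neighbour dead behind, inside the 30 deg blind wedge
  sc <- scene(c(-50, 0), neighbour_heading = pi / 2)
  occ <- raycast_occupancy(sc$positions, sc$headings, 1, body_length = 10)
  expect_equal(occ$right_deg + occ$left_deg, 0)
  # mirror-symmetric pair -> equal eye totals
  sc2 <- scene(c(20, 25, 20, -25), neighbour_heading = 0)
  occ2 <- raycast_occupancy(sc2$positions, sc2$headings, 1, body_length = 10)
  expect_equal(occ2$right_deg, occ2$left_deg)
  expect_gt(occ2$right_deg, 0)
  # occlusion: a second broadside neighbour straight behind the first adds
  # (almost) nothing; each ray is counted once, for the nearer fish
  near <- scene(c(0, -30), neighbour_heading = 0)
  both <- scene(c(0, -30, 0, -60), neighbour_heading = 0)
  occ_near <- raycast_occupancy(near$positions, near$headings, 1, body_length = 20)
  occ_both <- raycast_occupancy(both$positions, both$headings, 1, body_length = 20)
  expect_equal(occ_both$per_neighbour[2, "right"],
               occ_near$per_neighbour[2, "right"])
  expect_lt(occ_both$per_neighbour[3, "right"],
            occ_near$per_neighbour[2, "right"] / 2)
  expect_lt(occ_both$right_deg,
            occ_near$right_deg + occ_both$per_neighbour[3, "right"] + 1e-9)
  # eye totals can never exceed the field span
  expect_lt(occ_both$right_deg, 165 + 1e-9)
})

test_that("turning curve bins, binomial CI and symmetries are correct", {
  ev <- data.frame(
    clutter_diff_deg = c(rep(24, 100), rep(-26, 40)),
    direction = c(rep(c("right", "left"), 50), rep("right", 40)))
  tc <- turning_curve(ev)
  b25 <- tc[tc$bin_center_deg == 25, ]
  expect_equal(b25$p_right, 0.5)
  expect_equal(b25$ci_low, 0.5 - 1.96 * sqrt(0.25 / 100), tolerance = 1e-9)
  expect_equal(b25$ci_high, 0.5 + 1.96 * sqrt(0.25 / 100), tolerance = 1e-9)
  expect_equal(b25$n, 100L)
  bneg <- tc[tc$bin_center_deg == -25, ]
  expect_equal(bneg$p_right, 1)
  expect_equal(bneg$ci_high, 1)        # clamped
  # swapping labels reflects the curve about 0.5
  ev_sw <- ev
  ev_sw$direction <- ifelse(ev$direction == "right", "left", "right")
  tc_sw <- turning_curve(ev_sw)
  expect_equal(tc_sw$p_right, 1 - tc$p_right)
  # invariance under event order permutation
  set.seed(1)
  tc_perm <- turning_curve(ev[sample(nrow(ev)), ])
  expect_equal(tc_perm$p_right, tc$p_right)
  expect_equal(tc_perm$ci_low, tc$ci_low)
})

test_that("symmetrized AUC has the stated sign convention and arithmetic", {
  flat <- data.frame(clutter_diff_deg = seq(-25, 25, 5),
                     direction = "right")
  k <- 4
  mk <- function(p_pos, p_neg) {
    rows <- list()
    for (c0 in seq(5, 5 * k, 5)) {
      for (s in c(1, -1)) {
        p <- if (s > 0) p_pos else p_neg
        n_right <- round(100 * p)
        rows[[length(rows) + 1L]] <- data.frame(
          clutter_diff_deg = rep(s * c0, 100),
          direction = c(rep("right", n_right), rep("left", 100 - n_right)))
      }
    }
    turning_curve(do.call(rbind, rows))
  }
  expect_equal(symmetrized_auc(mk(0.5, 0.5)), 0, tolerance = 1e-12)
  curve <- mk(0.6, 0.4)
  expect_equal(symmetrized_auc(curve), 0.2 * k, tolerance = 1e-12)
  mirrored <- mk(0.4, 0.6)
  expect_equal(symmetrized_auc(mirrored), -0.2 * k, tolerance = 1e-12)
})
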