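test_that("circular mean averages on the circle, not the line", {
  expect_equal(circular_mean(c(0, pi / 2)), pi / 4)
  expect_equal(abs(circular_mean(c(pi - 0.1, -pi + 0.1))), pi)
  expect_true(is.na(circular_mean(c(pi / 2, -pi / 2))))
  expect_error(circular_mean(numeric(0)), "nothing")
  set.seed(51)
  for (i in 1:100) {
    ang <- runif(sample(2:200, 1), -pi, pi)
    expect_equal(circular_mean(ang), oracle_circular_mean(ang),
                 tolerance = 1e-12)
  }
})

test_that("the inferred heatmap recovers the generating rule's sign structure", {
  # slow-speed condition: many steps inside the interaction range, and
  # starts near the bottom wall so near-wall bins get populated
  a <- arena_config(speed = 5, max_lifespan = 400L)
  set.seed(3)
  starts <- cbind(runif(40, 60, 540), runif(40, 15, 120))
  hs <- runif(40, -pi, pi)
  rounds <- lapply(1:40, function(i) {
    run_round(empirical_rule(), a, "explore", starts[i, ], hs[i])
  })
  traj <- bind_trajectories(rounds)
  g <- inferred_rule_heatmap(traj, a, n_angle = 18, n_dist = 15)
  ac <- evosteer:::midpoints(g$angle_edges)
  dc <- evosteer:::midpoints(g$dist_edges)
  pop <- which(g$counts >= 50 & abs(matrix(ac, 18, 15)) > 0.05 &
               outer(rep(TRUE, 18), dc < 60), arr.ind = TRUE)
  expect_gt(nrow(pop), 0)
  for (r in seq_len(nrow(pop))) {
    expect_identical(sign(g$mean_turn[pop[r, 1], pop[r, 2]]),
                     sign(ac[pop[r, 1]]))
  }
})

test_that("heatmap bins hold exactly what was put in them", {
  a <- arena_config()
  one <- scripted_trajectory(100, 300, 0.25, a, heading = pi)
  g <- inferred_rule_heatmap(one, a, n_angle = 18, n_dist = 15)
  expect_identical(sum(g$counts), 1L)
  expect_equal(g$mean_turn[which(g$counts == 1)], 0.25)
  # a straight zero-brain run: every populated bin has zero mean turn
  rz <- run_round(fixture_zero_brain(), a, "explore", c(100, 300), pi / 4)
  gz <- inferred_rule_heatmap(rz, a)
  expect_true(all(gz$mean_turn[gz$counts > 0] == 0))
})

test_that("presence density is a normalized histogram of wall cues", {
  a <- arena_config()
  r <- run_round(fixture_avoider_brain(), a, "explore", c(300, 300), 0.7)
  d <- presence_density(r, a)
  expect_equal(sum(d$density), 1, tolerance = 1e-9)
  # stationary record at the centre: all mass at maximal wall distance
  centre <- scripted_trajectory(rep(300, 20), rep(300, 20), rep(0, 20), a)
  dc <- presence_density(centre, a, n_angle = 12, n_dist = 10)
  expect_equal(sum(dc$density[, 10]), 1)
  # wall-hugging fixture: mass concentrated near the wall
  hug <- scripted_trajectory(seq(30, 570, by = 30), rep(10, 19),
                             rep(0, 19), a)
  dh <- presence_density(hug, a, n_angle = 12, n_dist = 30)
  expect_gte(sum(dh$density[, evosteer:::midpoints(dh$dist_edges) < 50]), 0.8)
})

test_that("signed turns flip with the wall side and normalize to one", {
  a <- arena_config()
  # wall below (theta_w > 0 when heading +x); positive turns = away
  away <- scripted_trajectory(seq(100, 400, by = 50), rep(20, 7),
                              rep(0.4, 7), a)
  d <- signed_turn_distribution(away, "near")
  expect_false(d$empty)
  expect_true(all(d$values > 0))
  expect_equal(sum(d$densities * diff(d$bin_edges)), 1, tolerance = 1e-9)
  # same motion with the wall above: the same turns now count as towards
  toward <- away; toward$y <- 580; toward$theta_w <- -toward$theta_w
  d2 <- signed_turn_distribution(toward, "near")
  expect_true(all(d2$values < 0))
  # facing the wall exactly contributes zero regardless of the turn
  head_on <- scripted_trajectory(300, 10, 0.9, a, heading = -pi / 2)
  d3 <- signed_turn_distribution(head_on, "near")
  expect_identical(d3$values, 0)
  # far regime of a near-wall path is empty, and flagged
  d4 <- signed_turn_distribution(away, "far")
  expect_true(d4$empty)
})

test_that("the Gaussian small-angle fit recovers planted parameters", {
  set.seed(52)
  x <- rnorm(1e4, 0, 10 * pi / 180)
  fit <- gaussian_small_angle_fit(x)
  expect_lt(abs(fit$mean), 0.5 * pi / 180)
  expect_equal(fit$sd, 10 * pi / 180, tolerance = 0.05)
  expect_lt(fit$ks_distance, 0.05)
  expect_false(fit$degenerate)
  z <- gaussian_small_angle_fit(rep(0, 100))
  expect_true(z$degenerate)
  expect_identical(z$sd, 0)
  expect_error(gaussian_small_angle_fit(rnorm(10)), "need")
})

test_that("segment length is the median distance between U-turns", {
  a <- arena_config()
  # one step forward, U-turn, one step back: 50-px oscillation
  osc_x <- rep(c(300, 350), 10)
  osc <- scripted_trajectory(osc_x, rep(300, 20), rep(pi, 20), a,
                             heading = rep(c(0, pi), 10))
  expect_equal(segment_length_estimate(osc), 50)
  # three-step bouts between x = 200 and x = 350: U-turns 150 px apart
  bx <- rep(c(200, 250, 300, 350, 300, 250), 4)[1:20]
  bphi <- rep(0, 20)
  bphi[c(4, 7, 10, 13, 16, 19)] <- pi  # at the 350- and 200-px turnpoints
  bout <- scripted_trajectory(bx, rep(300, 20), bphi, a)
  expect_equal(segment_length_estimate(bout), 150)
  straight <- scripted_trajectory(seq(100, 500, by = 50), rep(300, 9),
                                  rep(0, 9), a)
  expect_true(is.na(segment_length_estimate(straight)))
})

test_that("wall-following fraction is the share of near-wall steps", {
  a <- arena_config()
  hug <- scripted_trajectory(seq(30, 570, by = 30), rep(10, 19), rep(0, 19), a)
  expect_equal(wall_following_fraction(hug, band = 100), 1)
  centre <- scripted_trajectory(rep(300, 5), rep(300, 5), rep(0, 5), a)
  expect_equal(wall_following_fraction(centre, band = 100), 0)
})

test_that("round-trip through trajectory CSV preserves the analysis inputs", {
  a <- tiny_arena()
  r <- run_round(fixture_avoider_brain(), a, "explore", c(250, 300), 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(r, path)
  back <- read_trajectory_csv(path)
  expect_equal(back$x, r$trajectory$x)
  expect_equal(segment_length_estimate(back), segment_length_estimate(r))
})
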