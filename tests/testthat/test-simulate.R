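test_that("a straight-flying agent dies at the wall with the traced score", {
  a <- arena_config(max_lifespan = 1000L)
  r <- run_round(fixture_zero_brain(), a, "survive", c(300, 300), 0)
  # hand trace: x = 350, 400, ..., 600 survive (closed square), 650 kills
  expect_identical(r$score, 6L)
  expect_identical(r$steps_survived, 6L)
  expect_identical(r$death_cause, "wall")
  expect_equal(r$trajectory$x, seq(300, 600, by = 50))
  expect_equal(length(r$turns), 7L)  # the killing step's turn is recorded
  expect_true(all(r$turns == 0))
})

test_that("explore score matches an independent cell enumeration of the path", {
  a <- arena_config(max_lifespan = 1000L)
  r <- run_round(fixture_zero_brain(), a, "explore", c(300, 300), 0)
  expect_identical(r$score,
                   oracle_cells_of_path(r$trajectory$x, r$trajectory$y, a))
  set.seed(12)
  for (i in 1:5) {
    b <- unpack_brain(runif(13, -50, 50))
    rr <- run_round(b, a, "explore", runif(2, 100, 500), runif(1, -pi, pi))
    expect_identical(rr$score,
                     oracle_cells_of_path(rr$trajectory$x, rr$trajectory$y, a))
  }
})

test_that("an empty round scores nothing and a wall-proof agent scores T_max", {
  a0 <- arena_config(max_lifespan = 0L)
  r0 <- run_round(fixture_zero_brain(), a0, "survive", c(300, 300), 0)
  expect_identical(r0$score, 0L)
  expect_identical(r0$steps_survived, 0L)
  # a saturated brain U-turns every step: oscillates in place forever
  a <- arena_config(max_lifespan = 500L)
  sat <- brain_params(matrix(0, 3, 2), rep(0, 3), rep(0, 3), 50)
  r <- run_round(sat, a, "survive", c(300, 300), 0)
  expect_identical(r$score, 500L)
  expect_identical(r$death_cause, "lifespan")
})

test_that("trajectory invariants hold: step lengths s, recorded states inside", {
  a <- tiny_arena()
  set.seed(13)
  for (i in 1:5) {
    b <- unpack_brain(runif(13, -50, 50))
    r <- run_round(b, a, "explore", c(300, 300), runif(1, -pi, pi))
    tr <- r$trajectory
    if (nrow(tr) > 1) {
      steplen <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
      expect_equal(steplen, rep(a$speed, nrow(tr) - 1))
    }
    expect_true(all(tr$x >= 0 & tr$x <= 600 & tr$y >= 0 & tr$y <= 600))
    expect_true(all(abs(r$turns) <= pi))
    expect_equal(r$turn_cost, a$turning_penalty * sum(r$turns^2))
  }
})

test_that("turning cost identity C_t = p_t * sum(dphi^2) holds exactly", {
  a <- arena_config(max_lifespan = 100L, turning_penalty = 0.33)
  set.seed(14)
  b <- unpack_brain(runif(13, -10, 10))
  r <- run_round(b, a, "explore", c(300, 300), 0)
  expect_equal(r$turn_cost, 0.33 * sum(r$turns^2))
  expect_gt(r$turn_cost, 0)
})

test_that("exploration credit is granted once per cell", {
  z <- exploration_credit(integer(0), 0L)
  expect_true(z$credited)
  z2 <- exploration_credit(z$visited, 0L)
  expect_false(z2$credited)
  v <- 0:399
  z3 <- exploration_credit(v, 150L)
  expect_false(z3$credited)
  expect_identical(length(z3$visited), 400L)
})

test_that("the 4+1 protocol sums scored rounds and keeps the fifth apart", {
  a <- arena_config(max_lifespan = 1000L)
  starts <- matrix(rep(c(300, 300), each = 4), 4, 2)
  # symmetric starts: each of the 4 headings gives the zero brain 6 steps
  ev <- evaluate_agent(fixture_zero_brain(), a, "survive", starts)
  expect_equal(ev$total_score, 24)
  expect_equal(ev$penalized_score, ev$total_score)  # p_t = 0
  expect_equal(ev$reference_score, 6)
  expect_equal(vapply(ev$rounds, function(r) r$trajectory$heading[1],
                      numeric(1)), c(0, pi, -pi / 2, pi / 2))
  # with a turning penalty the penalized score subtracts the cost exactly
  ap <- arena_config(max_lifespan = 50L, turning_penalty = 0.33)
  set.seed(15)
  b <- unpack_brain(runif(13, -10, 10))
  evp <- evaluate_agent(b, ap, "explore", starts)
  expect_equal(evp$penalized_score, evp$total_score - evp$total_turn_cost)
  expect_equal(evp$total_turn_cost,
               0.33 * sum(vapply(evp$rounds,
                                 function(r) sum(r$turns^2), numeric(1))))
})

test_that("rounds are deterministic and the population core matches them", {
  a <- tiny_arena()
  set.seed(16)
  P <- matrix(runif(6 * 13, -50, 50), 6, 13)
  starts <- array(runif(6 * 8, 50, 550), dim = c(6L, 4L, 2L))
  ev_vec <- evosteer:::eval_genomes(P, 3L, a, "explore", starts)
  ev_vec2 <- evosteer:::eval_genomes(P, 3L, a, "explore", starts)
  expect_identical(ev_vec, ev_vec2)
  for (i in seq_len(nrow(P))) {
    ev <- evaluate_agent(unpack_brain(P[i, ]), a, "explore", starts[i, , ])
    expect_identical(as.numeric(ev$total_score), ev_vec$total_score[i])
    expect_identical(as.numeric(ev$penalized_score), ev_vec$penalized_score[i])
    expect_identical(as.numeric(ev$reference_score),
                     as.numeric(ev_vec$reference_score[i]))
  }
  sv <- evosteer:::eval_genomes(P, 3L, a, "survive", starts)
  for (i in c(1, 4)) {
    ev <- evaluate_agent(unpack_brain(P[i, ]), a, "survive", starts[i, , ])
    expect_identical(as.numeric(ev$total_score), as.numeric(sv$total_score[i]))
  }
})

test_that("the scripted boustrophedon path covers every cell", {
  a <- arena_config()
  b <- fixture_boustrophedon_path(a)
  expect_identical(trajectory_explore_score(b, a), 400L)
  a2 <- arena_config(grid_cells_per_side = 7)
  expect_identical(trajectory_explore_score(fixture_boustrophedon_path(a2),
                                            a2), 49L)
})

test_that("the empirical rule can drive a round and avoids the wall", {
  # at the slow speed the interaction range spans many steps, so the
  # rule keeps the agent off the wall indefinitely
  a <- arena_config(speed = 5, max_lifespan = 300L)
  r <- run_round(empirical_rule(), a, "explore", c(300, 300), 0.3)
  expect_identical(r$death_cause, "lifespan")
  expect_gt(min(r$trajectory$d_w), 0)
})
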