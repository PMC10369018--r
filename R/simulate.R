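# Round simulation: the perception -> decision -> movement loop, the
# survive/explore scoring, and the 4+1 round evaluation protocol.

# Controller dispatch: a controller is anything that maps a raw percept to a
# turning angle. brain_params go through normalization + forward + steering;
# an empirical_rule applies its closed form to the raw cues.

#' Turning decision of a controller
#'
#' @param controller A [brain_params()] or an [empirical_rule()].
#' @param d_w Raw wall distance in pixels.
#' @param theta_w Raw signed wall angle in radians.
#' @param arena An [arena_config()] (supplies the normalization constants
#'   and the steering increment).
#' @return Turning angle in radians.
#' @export
decide_turn <- function(controller, d_w, theta_w, arena) {
  UseMethod("decide_turn")
}

#' @export
decide_turn.brain_params <- function(controller, d_w, theta_w, arena) {
  dn <- d_w / (arena$side_length / 2)
  an <- (theta_w + pi) / (2 * pi)
  steering_angle(brain_forward(controller, dn, an), arena$steering_increment)
}

#' @export
decide_turn.empirical_rule <- function(controller, d_w, theta_w, arena) {
  empirical_turn(theta_w, d_w, controller)
}

#' Credit a grid cell for exploration
#'
#' An agent scores one exploration point each time it enters a cell it has
#' never visited before; revisits score nothing.
#'
#' @param visited Integer vector of already-visited cell indices.
#' @param cell Cell index of the current position.
#' @return List with the updated `visited` set and a `credited` flag.
#' @export
exploration_credit <- function(visited, cell) {
  credited <- !(cell %in% visited)
  if (credited) visited <- c(visited, cell)
  list(visited = visited, credited = credited)
}

#' Simulate one round of one agent
#'
#' Iterates perceive -> decide -> step from a given start until the agent
#' leaves the closed square (death by `wall`) or `max_lifespan` steps are
#' completed (`lifespan`). Under the `survive` objective the score is the
#' number of steps completed while remaining inside; under `explore` it is
#' the number of distinct grid cells visited, the starting cell included.
#'
#' The returned trajectory has one row per living state (the initial state
#' included): position, heading, the wall cues perceived there, and
#' `delta_phi`, the turn decided at that state (`NA` for the final state of
#' a round that ran out of lifespan). The killing step's turn appears both
#' in the trajectory and in `turns`, and its `p_t * dphi^2` cost is
#' incurred, but the resulting outside position is not recorded.
#'
#' @param controller A [brain_params()] (or [empirical_rule()]).
#' @param arena An [arena_config()].
#' @param objective `"survive"` or `"explore"`.
#' @param start Length-2 numeric start position, inside the arena.
#' @param heading0 Initial heading in radians.
#' @return An object of class `round_result`: list with `trajectory`
#'   (data.frame `time, x, y, heading, d_w, theta_w, delta_phi`), `turns`,
#'   `steps_survived`, `score`, `turn_cost`, `death_cause`.
#' @export
run_round <- function(controller, arena, objective = c("explore", "survive"),
                      start, heading0 = 0) {
  objective <- match.arg(objective)
  L <- arena$side_length
  if (start[1] < 0 || start[1] > L || start[2] < 0 || start[2] > L)
    stop("start position lies outside the arena")
  t_max <- arena$max_lifespan
  p_t <- arena$turning_penalty
  s <- arena$speed

  x <- start[1]; y <- start[2]; h <- wrap_angle(heading0)
  n_rec <- t_max + 1L
  tr_x <- numeric(n_rec); tr_y <- numeric(n_rec); tr_h <- numeric(n_rec)
  tr_d <- numeric(n_rec); tr_a <- numeric(n_rec); tr_phi <- rep(NA_real_, n_rec)
  turns <- numeric(t_max)
  cost <- 0
  score <- 0L
  visited <- integer(0)
  if (objective == "explore") {
    visited <- cell_index_raw(x, y, L, arena$grid_cells_per_side)
    score <- 1L  # the starting cell is discovered at t = 0
  }

  steps <- 0L
  death <- "lifespan"
  repeat {
    cues <- wall_cues_vec(x, y, h, L)
    i <- steps + 1L
    tr_x[i] <- x; tr_y[i] <- y; tr_h[i] <- h
    tr_d[i] <- cues$d_w; tr_a[i] <- cues$theta_w
    if (steps >= t_max) break
    dphi <- decide_turn(controller, cues$d_w, cues$theta_w, arena)
    tr_phi[i] <- dphi
    turns[steps + 1L] <- dphi
    h <- wrap_angle(h + dphi)
    x <- x + s * cos(h)
    y <- y + s * sin(h)
    cost <- cost + p_t * dphi * dphi
    if (x < 0 || x > L || y < 0 || y > L) {
      steps <- steps + 1L  # the killing step was attempted, not survived
      death <- "wall"
      break
    }
    steps <- steps + 1L
    if (objective == "survive") {
      score <- score + 1L
    } else {
      cell <- cell_index_raw(x, y, L, arena$grid_cells_per_side)
      if (!(cell %in% visited)) {
        visited <- c(visited, cell)
        score <- score + 1L
      }
    }
  }

  survived <- if (death == "wall") steps - 1L else steps
  keep <- seq_len(survived + 1L)
  structure(list(
    trajectory = data.frame(time = keep - 1L, x = tr_x[keep], y = tr_y[keep],
                            heading = tr_h[keep], d_w = tr_d[keep],
                            theta_w = tr_a[keep], delta_phi = tr_phi[keep]),
    turns = turns[seq_len(if (death == "wall") survived + 1L else survived)],
    steps_survived = survived,
    score = score,
    turn_cost = cost,
    death_cause = death), class = "round_result")
}

#' @export
print.round_result <- function(x, ...) {
  cat(sprintf("<round_result> %d steps survived, score %d, turn cost %.4g, death: %s\n",
              x$steps_survived, x$score, x$turn_cost, x$death_cause))
  invisible(x)
}

#' Evaluate an agent over the 4+1 round protocol
#'
#' Four scored rounds start from four supplied (normally random) interior
#' positions with initial headings `0, -pi, -pi/2, pi/2` in that fixed
#' order; their scores and turning costs are summed and the penalized score
#' is `S_p = S - C_t`. A fifth monitoring round always starts from the
#' arena centre with heading 0; its score is recorded as
#' `reference_score` so agents can be compared across generations under a
#' constant initial condition, but it never contributes to fitness.
#'
#' @param controller A [brain_params()].
#' @param arena An [arena_config()].
#' @param objective `"survive"` or `"explore"`.
#' @param start_positions 4 x 2 matrix of start positions.
#' @return An object of class `evaluation_result`: `total_score`,
#'   `total_turn_cost`, `penalized_score`, `reference_score`, plus the five
#'   `round_result`s (`rounds`, `reference_round`).
#' @export
evaluate_agent <- function(controller, arena,
                           objective = c("explore", "survive"),
                           start_positions) {
  objective <- match.arg(objective)
  start_positions <- matrix(start_positions, ncol = 2)
  stopifnot(nrow(start_positions) == 4)
  headings <- round_headings()
  rounds <- lapply(1:4, function(r) {
    run_round(controller, arena, objective, start_positions[r, ], headings[r])
  })
  ref <- run_round(controller, arena, objective,
                   rep(arena$side_length / 2, 2), 0)
  total <- sum(vapply(rounds, `[[`, numeric(1), "score"))
  cost <- sum(vapply(rounds, `[[`, numeric(1), "turn_cost"))
  structure(list(total_score = total,
                 total_turn_cost = cost,
                 penalized_score = total - cost,
                 reference_score = ref$score,
                 rounds = rounds,
                 reference_round = ref),
            class = "evaluation_result")
}

# fixed heading-to-round assignment for the four scored rounds
round_headings <- function() c(0, -pi, -pi / 2, pi / 2)

# Vectorized population core -------------------------------------------------

# Simulates one round for every genome in parallel (vectorized across
# agents). P is the n x (4K+1) genome matrix; x0, y0, h0 give each agent's
# start. Operation order matches run_round()/brain_forward() exactly, so the
# two paths agree bit for bit.
sim_round_population <- function(P, n_hidden, arena, objective, x0, y0, h0) {
  n <- nrow(P)
  K <- n_hidden
  L <- arena$side_length
  s <- arena$speed
  isteer <- arena$steering_increment
  p_t <- arena$turning_penalty
  g <- arena$grid_cells_per_side
  t_max <- arena$max_lifespan
  half <- L / 2
  twopi <- 2 * pi

  cols <- lapply(seq_len(4 * K + 1), function(j) P[, j])
  iW1 <- seq(1, 2 * K, by = 2); iW2 <- seq(2, 2 * K, by = 2)
  iB <- 2 * K + seq_len(K); iV <- 3 * K + seq_len(K); iB0 <- 4 * K + 1

  x <- x0; y <- y0; h <- wrap_angle(h0)
  score <- integer(n); cost <- numeric(n); steps <- integer(n)
  act <- seq_len(n)
  explore <- objective == "explore"
  if (explore) {
    visited <- matrix(FALSE, n, g * g)
    visited[cbind(act, cell_index_raw(x, y, L, g) + 1L)] <- TRUE
    score <- score + 1L
  }

  t <- 0L
  while (length(act) && t < t_max) {
    t <- t + 1L
    xa <- x[act]; ya <- y[act]; ha <- h[act]
    dl <- xa; dr <- L - xa; db <- ya; dtp <- L - ya
    dw <- pmin(dl, dr, db, dtp)
    bearing <- ifelse(dl <= dw, pi,
               ifelse(dr <= dw, 0,
               ifelse(db <= dw, -pi / 2, pi / 2)))
    thw <- wrap_angle(ha - bearing)
    dn <- dw / half
    an <- (thw + pi) / twopi
    acc <- cols[[iB0]][act]
    for (k in seq_len(K)) {
      z <- cols[[iB[k]]][act] + cols[[iW1[k]]][act] * dn +
        cols[[iW2[k]]][act] * an
      acc <- acc + cols[[iV[k]]][act] / (1 + exp(-z))
    }
    o1 <- 1 / (1 + exp(-acc))
    dphi <- (o1 - 0.5) * isteer
    ha <- wrap_angle(ha + dphi)
    xa <- xa + s * cos(ha)
    ya <- ya + s * sin(ha)
    cost[act] <- cost[act] + p_t * dphi * dphi
    x[act] <- xa; y[act] <- ya; h[act] <- ha
    ok <- xa >= 0 & xa <= L & ya >= 0 & ya <= L
    surv <- act[ok]
    steps[surv] <- steps[surv] + 1L
    if (length(surv)) {
      if (explore) {
        ij <- cbind(surv, cell_index_raw(xa[ok], ya[ok], L, g) + 1L)
        newc <- !visited[ij]
        visited[ij] <- TRUE
        score[surv] <- score[surv] + as.integer(newc)
      } else {
        score[surv] <- score[surv] + 1L
      }
    }
    act <- surv
  }
  list(score = score, steps = steps, turn_cost = cost)
}

# Full 4+1 protocol for a population. starts is an n x 4 x 2 array (or a
# 4 x 2 matrix shared by all agents). Returns per-agent vectors.
eval_genomes <- function(P, n_hidden, arena, objective, starts) {
  n <- nrow(P)
  headings <- round_headings()
  if (is.matrix(starts)) {
    starts <- aperm(array(starts, dim = c(4, 2, n)), c(3, 1, 2))
  }
  stopifnot(identical(dim(starts), c(n, 4L, 2L)) ||
            identical(dim(starts), as.integer(c(n, 4, 2))))
  total <- numeric(n); cost <- numeric(n)
  for (r in 1:4) {
    res <- sim_round_population(P, n_hidden, arena, objective,
                                starts[, r, 1], starts[, r, 2],
                                rep(headings[r], n))
    total <- total + res$score
    cost <- cost + res$turn_cost
  }
  ref <- sim_round_population(P, n_hidden, arena, objective,
                              rep(arena$side_length / 2, n),
                              rep(arena$side_length / 2, n),
                              rep(0, n))
  list(total_score = total, total_turn_cost = cost,
       penalized_score = total - cost, reference_score = ref$score)
}
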