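#' Arena configuration
#'
#' Describes the bounded square arena and the kinematic constants of the
#' agents that move in it. Defaults are the reference condition: a
#' 600 x 600 pixel square discretized into a 20 x 20 grid (400 cells),
#' speed 50 px per time step, steering increment 2*pi (so a single step can
#' turn anywhere in (-pi, pi]), lifespan cap of 5000 steps and no turning
#' penalty.
#'
#' @param side_length Arena side length in pixels (> 0).
#' @param grid_cells_per_side Number of grid cells along each side (>= 1);
#'   the exploration score is counted on the resulting
#'   `grid_cells_per_side^2` cells.
#' @param speed Displacement per time step in pixels (> 0). The slow
#'   locomotor condition uses 5.
#' @param steering_increment Maximum turning scale `i_steering` in radians,
#'   in `[0, 2*pi]`. The per-step turn is `(o1 - 0.5) * steering_increment`.
#' @param max_lifespan Maximum number of time steps per round (`T_max`).
#' @param turning_penalty Cost coefficient `p_t >= 0` applied as
#'   `p_t * dphi^2` per step. The turning-cost condition uses 0.33.
#' @return An object of class `arena_config` (a named list).
#' @examples
#' arena_config()                 # reference condition
#' arena_config(speed = 5)        # slow-speed condition
#' @export
arena_config <- function(side_length = 600,
                         grid_cells_per_side = 20L,
                         speed = 50,
                         steering_increment = 2 * pi,
                         max_lifespan = 5000L,
                         turning_penalty = 0) {
  # tolerate sub-ulp decimal round-trips of 2*pi from JSON configs
  if (steering_increment > 2 * pi && steering_increment < 2 * pi + 1e-9)
    steering_increment <- 2 * pi
  stopifnot(side_length > 0, grid_cells_per_side >= 1, speed > 0,
            steering_increment >= 0, steering_increment <= 2 * pi,
            max_lifespan >= 0, turning_penalty >= 0)
  structure(list(side_length = side_length,
                 grid_cells_per_side = as.integer(grid_cells_per_side),
                 speed = speed,
                 steering_increment = steering_increment,
                 max_lifespan = as.integer(max_lifespan),
                 turning_penalty = turning_penalty),
            class = "arena_config")
}

#' @export
print.arena_config <- function(x, ...) {
  cat(sprintf(paste0("<arena_config> %g x %g px, %d x %d grid (%d cells), ",
                     "speed %g, i_steering %.4g, T_max %d, p_t %g\n"),
              x$side_length, x$side_length,
              x$grid_cells_per_side, x$grid_cells_per_side,
              x$grid_cells_per_side^2, x$speed, x$steering_increment,
              x$max_lifespan, x$turning_penalty))
  invisible(x)
}

#' Agent state
#'
#' @param x,y Position in pixels, inside the closed square.
#' @param heading Heading in radians; wrapped to `(-pi, pi]`.
#' @param alive Logical flag.
#' @param step_count Steps taken so far.
#' @param visited_cells Integer vector of distinct grid cells entered.
#' @param turn_cost_accum Accumulated `sum(p_t * dphi^2)`.
#' @return An object of class `agent_state`.
#' @export
agent_state <- function(x, y, heading, alive = TRUE, step_count = 0L,
                        visited_cells = integer(0), turn_cost_accum = 0) {
  structure(list(x = x, y = y, heading = wrap_angle(heading), alive = alive,
                 step_count = as.integer(step_count),
                 visited_cells = visited_cells,
                 turn_cost_accum = turn_cost_accum),
            class = "agent_state")
}

#' Wrap an angle to (-pi, pi]
#'
#' @param a Angle(s) in radians.
#' @return Angle(s) wrapped into `(-pi, pi]`. Vectorized.
#' @examples
#' wrap_angle(3 * pi / 2)  # -pi/2
#' wrap_angle(-pi)         # pi
#' @export
wrap_angle <- function(a) {
  w <- ((a + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

#' Closest point on the arena boundary
#'
#' For a point inside the closed square, finds the nearest boundary point.
#' The distance is `min(x, y, L - x, L - y)`. Ties (centre, diagonals) are
#' broken by a fixed wall order: left, right, bottom, top.
#'
#' @param x,y Position in pixels.
#' @param arena An [arena_config()].
#' @return A list with `wall_point` (length-2 numeric) and `wall_distance`.
#' @examples
#' closest_wall(10, 300, arena_config())  # left wall, distance 10
#' @export
closest_wall <- function(x, y, arena) {
  L <- arena$side_length
  if (x < 0 || x > L || y < 0 || y > L)
    stop("point (", x, ", ", y, ") lies outside the arena: agent is dead")
  d <- min(x, L - x, y, L - y)
  wp <- if (x <= d) c(0, y)
        else if (L - x <= d) c(L, y)
        else if (y <= d) c(x, 0)
        else c(x, L)
  list(wall_point = wp, wall_distance = d)
}

#' Perceive the closest wall
#'
#' Computes the agent's perception cues: the distance `d_w` to the closest
#' point on any wall and the signed angle `theta_w` between the heading and
#' the bearing to that point, plus both cues normalized to `[0, 1]`
#' (`d_w / (L/2)` and `(theta_w + pi) / (2*pi)`).
#'
#' Sign convention: `theta_w = wrap(heading - bearing)`; `theta_w = 0` means
#' the agent faces the wall head-on and `theta_w > 0` means the wall lies to
#' the agent's right (clockwise of the heading).
#'
#' @param state An [agent_state()]; must be alive.
#' @param arena An [arena_config()].
#' @return An object of class `percept`: list with `wall_distance`,
#'   `wall_angle`, `wall_distance_norm`, `wall_angle_norm`.
#' @export
perceive <- function(state, arena) {
  if (!state$alive) stop("cannot perceive: agent is dead")
  L <- arena$side_length
  if (state$x < 0 || state$x > L || state$y < 0 || state$y > L)
    stop("cannot perceive: agent is outside the arena")
  cues <- wall_cues_vec(state$x, state$y, state$heading, L)
  theta_w <- cues$theta_w
  structure(list(wall_distance = cues$d_w,
                 wall_angle = theta_w,
                 wall_distance_norm = cues$d_w / (arena$side_length / 2),
                 wall_angle_norm = (theta_w + pi) / (2 * pi)),
            class = "percept")
}

#' Advance an agent by one time step
#'
#' The heading is updated first, then the position moves by `speed` along
#' the new heading. An agent whose new position falls outside the closed
#' square dies; death is a valid outcome, not an error. The turning cost
#' `p_t * turn^2` accrues on every step, including the killing one.
#'
#' @param state An [agent_state()]; must be alive.
#' @param turn Turning angle in radians, `|turn| <= pi`.
#' @param arena An [arena_config()].
#' @return The updated `agent_state`.
#' @export
step_agent <- function(state, turn, arena) {
  if (!state$alive) stop("cannot step: agent is dead")
  L <- arena$side_length
  h <- wrap_angle(state$heading + turn)
  x <- state$x + arena$speed * cos(h)
  y <- state$y + arena$speed * sin(h)
  state$heading <- h
  state$x <- x
  state$y <- y
  state$step_count <- state$step_count + 1L
  state$turn_cost_accum <- state$turn_cost_accum +
    arena$turning_penalty * turn * turn
  state$alive <- x >= 0 && x <= L && y >= 0 && y <= L
  state
}

#' Grid cell index of a position
#'
#' Row-major 0-based index of the square grid cell containing `(x, y)`.
#' Cells are half-open: a point on an interior cell edge belongs to the
#' cell with the larger index; the far boundary (`x = L` or `y = L`)
#' belongs to the last cell.
#'
#' @param x,y Position in pixels, inside the closed square. Vectorized.
#' @param arena An [arena_config()].
#' @return Integer cell index in `0:(grid_cells_per_side^2 - 1)`.
#' @examples
#' cell_index(15, 15, arena_config())   # 0
#' cell_index(585, 585, arena_config()) # 399
#' @export
cell_index <- function(x, y, arena) {
  L <- arena$side_length
  if (any(x < 0 | x > L | y < 0 | y > L))
    stop("point outside the arena")
  g <- arena$grid_cells_per_side
  cell_index_raw(x, y, L, g)
}

# internal: no validation, used by the vectorized simulation core
cell_index_raw <- function(x, y, L, g) {
  cw <- L / g
  col <- pmin(as.integer(floor(x / cw)), g - 1L)
  row <- pmin(as.integer(floor(y / cw)), g - 1L)
  row * g + col
}

# internal vectorized percept pieces, shared with the simulation core.
# Tie order left, right, bottom, top matches closest_wall().
wall_cues_vec <- function(x, y, heading, L) {
  dl <- x
  dr <- L - x
  db <- y
  dt <- L - y
  dw <- pmin(dl, dr, db, dt)
  bearing <- ifelse(dl <= dw, pi,
             ifelse(dr <= dw, 0,
             ifelse(db <= dw, -pi / 2, pi / 2)))
  list(d_w = dw, theta_w = wrap_angle(heading - bearing))
}
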