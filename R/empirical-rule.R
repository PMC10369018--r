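# The closed-form fish wall-avoidance rule, supervised fitting of steering
# networks to it, and the hidden-layer-size sweep used to gauge the minimal
# sufficient network.

#' Empirical wall-avoidance rule parameters
#'
#' The simplified rule of interaction measured in rummy-nose tetra:
#' `dphi = sin(theta_w) * exp(-(d_w / l_w)^2)` — an odd function of the
#' wall angle (direction of avoidance) times a Gaussian decay in the wall
#' distance (range of the repulsion). `l_w` controls the interaction
#' range; the default of 60 px (a tenth of the reference arena side) is a
#' package choice, configurable here.
#'
#' @param interaction_range `l_w` in pixels (> 0).
#' @return An object of class `empirical_rule`.
#' @export
empirical_rule <- function(interaction_range = 60) {
  if (interaction_range <= 0) stop("interaction_range must be positive")
  structure(list(interaction_range = interaction_range),
            class = "empirical_rule")
}

#' Turning angle under the empirical wall-avoidance rule
#'
#' `dphi = sin(theta_w) * exp(-(d_w / l_w)^2)`. With the package sign
#' convention (positive `theta_w` = wall to the right), positive output
#' turns the agent left, i.e. away from the wall. The magnitude never
#' exceeds 1 radian and decays monotonically with distance.
#'
#' @param theta_w Signed wall angle(s) in radians.
#' @param d_w Wall distance(s) in pixels (>= 0).
#' @param params An [empirical_rule()].
#' @return Turning angle(s) in radians. Vectorized.
#' @examples
#' empirical_turn(pi / 2, 0, empirical_rule())   # 1 rad
#' empirical_turn(pi / 2, 60, empirical_rule())  # exp(-1)
#' @export
empirical_turn <- function(theta_w, d_w, params = empirical_rule()) {
  if (params$interaction_range <= 0) stop("interaction_range must be positive")
  sin(theta_w) * exp(-(d_w / params$interaction_range)^2)
}

#' Training set for fitting a network to the empirical rule
#'
#' Evaluates the empirical rule on a regular grid over
#' `theta_w in (-pi, pi]` and `d_w in [0, L/2]`, normalizes the inputs
#' exactly as the simulator does, and expresses the targets in output-unit
#' space: `o1* = dphi* / i_steering + 0.5`, the inverse of
#' [steering_angle()]. With `i_steering = 2*pi` all targets lie within
#' `0.5 +/- 1/(2*pi)`, so a fitted network is directly usable as an agent
#' brain.
#'
#' @param params An [empirical_rule()].
#' @param arena An [arena_config()].
#' @param n_angle,n_dist Grid resolution (>= 2 each).
#' @return A data.frame with columns `theta_w`, `d_w`, `d_norm`, `a_norm`,
#'   `target_o1`.
#' @export
rule_training_set <- function(params = empirical_rule(),
                              arena = arena_config(),
                              n_angle = 24, n_dist = 20) {
  stopifnot(n_angle >= 2, n_dist >= 2)
  if (arena$steering_increment < 2)
    stop("steering increment too small to represent a 1-radian avoidance turn")
  theta <- -pi + seq_len(n_angle) * (2 * pi / n_angle)  # (-pi, pi]
  d <- seq(0, arena$side_length / 2, length.out = n_dist)
  grid <- expand.grid(theta_w = theta, d_w = d)
  dphi <- empirical_turn(grid$theta_w, grid$d_w, params)
  data.frame(theta_w = grid$theta_w, d_w = grid$d_w,
             d_norm = grid$d_w / (arena$side_length / 2),
             a_norm = (grid$theta_w + pi) / (2 * pi),
             target_o1 = dphi / arena$steering_increment + 0.5)
}

# mean squared error and analytic gradient of the network output against
# targets, in o1 units; genome layout as in pack_brain()
mlp_mse <- function(genome, K, X, target) {
  W1 <- genome[seq(1, 2 * K, by = 2)]
  W2 <- genome[seq(2, 2 * K, by = 2)]
  b <- genome[2 * K + seq_len(K)]
  v <- genome[3 * K + seq_len(K)]
  b0 <- genome[4 * K + 1]
  Z <- sweep(X[, 1, drop = FALSE] %*% rbind(W1) +
             X[, 2, drop = FALSE] %*% rbind(W2), 2, b, `+`)
  H <- 1 / (1 + exp(-Z))
  o <- 1 / (1 + exp(-(drop(H %*% v) + b0)))
  mean((o - target)^2)
}

mlp_mse_grad <- function(genome, K, X, target) {
  N <- nrow(X)
  W1 <- genome[seq(1, 2 * K, by = 2)]
  W2 <- genome[seq(2, 2 * K, by = 2)]
  b <- genome[2 * K + seq_len(K)]
  v <- genome[3 * K + seq_len(K)]
  b0 <- genome[4 * K + 1]
  Z <- sweep(X[, 1, drop = FALSE] %*% rbind(W1) +
             X[, 2, drop = FALSE] %*% rbind(W2), 2, b, `+`)
  H <- 1 / (1 + exp(-Z))
  o <- 1 / (1 + exp(-(drop(H %*% v) + b0)))
  delta_o <- 2 * (o - target) * o * (1 - o) / N          # dL/dz_out
  gv <- drop(crossprod(H, delta_o))
  gb0 <- sum(delta_o)
  delta_h <- (delta_o %o% v) * H * (1 - H)               # N x K
  gW1 <- drop(crossprod(delta_h, X[, 1]))
  gW2 <- drop(crossprod(delta_h, X[, 2]))
  gb <- colSums(delta_h)
  out <- numeric(4 * K + 1)
  out[seq(1, 2 * K, by = 2)] <- gW1
  out[seq(2, 2 * K, by = 2)] <- gW2
  out[2 * K + seq_len(K)] <- gb
  out[3 * K + seq_len(K)] <- gv
  out[4 * K + 1] <- gb0
  out
}

#' Fit a steering network to a training set by least squares
#'
#' Minimizes the mean squared error between the network output and the
#' target `o1*` values by gradient-based optimization (BFGS with an
#' analytic gradient) from several random restarts, returning the best
#' restart. The reported RMSE is rescaled to turning-angle units
#' (multiplied by the steering increment) so fits of different network
#' sizes are compared on the behavioural scale.
#'
#' @param n_hidden Hidden-layer size.
#' @param training_set A [rule_training_set()] (columns `d_norm`,
#'   `a_norm`, `target_o1`).
#' @param restarts Number of random restarts.
#' @param maxit Optimizer iterations per restart.
#' @param seed Integer seed for the restarts' initial values.
#' @param i_steering Steering increment used to express the RMSE in
#'   radians.
#' @return List with `params` (a [brain_params()]) and `rmse` (radians).
#' @export
fit_network_to_rule <- function(n_hidden, training_set, restarts = 10,
                                maxit = 2000, seed = 1,
                                i_steering = 2 * pi) {
  if (!nrow(training_set)) stop("training set is empty")
  K <- as.integer(n_hidden)
  len <- param_count(K)
  X <- cbind(training_set$d_norm, training_set$a_norm)
  target <- training_set$target_o1
  best <- NULL
  set.seed(seed)
  inits <- matrix(stats::rnorm(restarts * len, 0, 2), restarts, len)
  for (r in seq_len(restarts)) {
    fit <- try(stats::optim(inits[r, ], mlp_mse, mlp_mse_grad,
                            K = K, X = X, target = target,
                            method = "BFGS",
                            control = list(maxit = maxit, reltol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer restarts diverged")
  list(params = unpack_brain(best$par, K),
       rmse = sqrt(best$value) * i_steering)
}

#' Evaluate a turn function on a regular (angle, distance) grid
#'
#' Deterministically evaluates either a fitted network or the empirical
#' rule at the bin centres of a regular grid, producing the heatmap
#' surface ("rule of interaction") used to compare controllers.
#'
#' @param turn_source A [brain_params()] or [empirical_rule()].
#' @param arena An [arena_config()].
#' @param n_angle,n_dist Number of angle and distance bins.
#' @return A `rule_grid` object: list with `angle_edges`, `dist_edges`,
#'   `mean_turn` (`n_angle x n_dist` matrix), `counts` (1 everywhere:
#'   deterministic evaluation, no sampling).
#' @export
evaluate_rule_grid <- function(turn_source, arena = arena_config(),
                               n_angle = 36, n_dist = 30) {
  edges <- rule_grid_edges(arena, n_angle, n_dist)
  ac <- midpoints(edges$angle_edges)
  dc <- midpoints(edges$dist_edges)
  g <- expand.grid(theta_w = ac, d_w = dc)
  turn <- decide_turn(turn_source, g$d_w, g$theta_w, arena)
  structure(list(angle_edges = edges$angle_edges,
                 dist_edges = edges$dist_edges,
                 mean_turn = matrix(turn, n_angle, n_dist),
                 counts = matrix(1L, n_angle, n_dist)),
            class = "rule_grid")
}

rule_grid_edges <- function(arena, n_angle, n_dist) {
  list(angle_edges = seq(-pi, pi, length.out = n_angle + 1),
       dist_edges = seq(0, arena$side_length / 2, length.out = n_dist + 1))
}

midpoints <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

#' @export
print.rule_grid <- function(x, ...) {
  cat(sprintf("<rule_grid> %d angle x %d distance bins, %d populated\n",
              nrow(x$mean_turn), ncol(x$mean_turn), sum(x$counts > 0)))
  invisible(x)
}

#' Heatmap image of a rule grid
#'
#' @param x A `rule_grid`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.rule_grid <- function(x, ...) {
  graphics::image(midpoints(x$angle_edges), midpoints(x$dist_edges),
                  x$mean_turn, xlab = "wall angle (rad)",
                  ylab = "wall distance (px)",
                  col = grDevices::hcl.colors(64, "Blue-Red 3"), ...)
}

#' Compare fit quality across hidden-layer sizes
#'
#' Fits networks of each requested hidden-layer size to the same training
#' set with matched optimizer budgets and reports the RMSE per size. The
#' size at which the RMSE stops improving is an effective measure of the
#' cognitive difficulty of the task; for the fish wall-avoidance rule,
#' three hidden neurons suffice.
#'
#' @param n_hidden_list Integer vector of hidden-layer sizes.
#' @param training_set A [rule_training_set()].
#' @param restarts,maxit,seed Matched optimizer budget for every size.
#' @param i_steering Steering increment (RMSE scale).
#' @return A data.frame with columns `n_hidden` and `rmse` (radians).
#' @export
compare_structures <- function(n_hidden_list, training_set, restarts = 10,
                               maxit = 2000, seed = 1, i_steering = 2 * pi) {
  if (!length(n_hidden_list)) stop("n_hidden_list is empty")
  rmse <- vapply(n_hidden_list, function(K) {
    fit_network_to_rule(K, training_set, restarts = restarts, maxit = maxit,
                        seed = seed, i_steering = i_steering)$rmse
  }, numeric(1))
  data.frame(n_hidden = as.integer(n_hidden_list), rmse = rmse)
}
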