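# Independent oracles used across the suite. Each deliberately takes a
# different computational route than the package implementation.

# MLP forward pass via matrix algebra and plogis (the package accumulates
# scalar terms neuron by neuron)
oracle_forward <- function(params, d_norm, a_norm) {
  z <- params$hidden_weights %*% rbind(d_norm, a_norm) + params$hidden_biases
  h <- stats::plogis(z)
  stats::plogis(drop(crossprod(h, params$output_weights)) + params$output_bias)
}

# circular mean via the argument of the mean complex exponential
oracle_circular_mean <- function(angles) {
  Arg(mean(complex(argument = angles)))
}

# cell index via a brute-force scan over every cell rectangle
oracle_cell_index <- function(x, y, arena) {
  g <- arena$grid_cells_per_side
  cw <- arena$side_length / g
  for (row in 0:(g - 1)) {
    for (col in 0:(g - 1)) {
      x0 <- col * cw; y0 <- row * cw
      hi_x <- if (col == g - 1) x <= x0 + cw else x < x0 + cw
      hi_y <- if (row == g - 1) y <= y0 + cw else y < y0 + cw
      if (x >= x0 && hi_x && y >= y0 && hi_y) return(row * g + col)
    }
  }
  stop("point in no cell")
}

# distinct cells crossed by recorded positions, enumerated independently
oracle_cells_of_path <- function(xs, ys, arena) {
  idx <- mapply(oracle_cell_index, xs, ys, MoreArgs = list(arena = arena))
  length(unique(idx))
}

# a hand-scripted trajectory data.frame from positions + decisions
scripted_trajectory <- function(x, y, delta_phi, arena = arena_config(),
                                heading = NULL) {
  n <- length(x)
  if (is.null(heading)) heading <- rep(0, n)
  cues <- evosteer:::wall_cues_vec(x, y, heading, arena$side_length)
  data.frame(time = seq_len(n) - 1L, x = x, y = y, heading = heading,
             d_w = cues$d_w, theta_w = cues$theta_w, delta_phi = delta_phi)
}

tiny_arena <- function(...) arena_config(max_lifespan = 200L, ...)
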