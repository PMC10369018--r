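# Post-hoc trajectory statistics: circular means, inferred interaction-rule
# heatmaps, presence densities, turning-angle distributions, and
# emergent-strategy metrics (freezing segment length, wall following).

#' Circular mean of a set of angles
#'
#' `atan2(sum(sin(a)), sum(cos(a)))`, the correct average on the circle:
#' e.g. the circular mean of `pi - 0.1` and `-pi + 0.1` is `pi`, not 0.
#' When the resultant vector has length below `1e-12` (antipodal
#' cancellation) the mean direction is undefined and `NA` is returned.
#'
#' @param angles Nonempty numeric vector of radians.
#' @return Mean direction in `(-pi, pi]`, or `NA` if undefined.
#' @examples
#' circular_mean(c(0, pi / 2))  # pi/4
#' @export
circular_mean <- function(angles) {
  if (!length(angles)) stop("cannot take the circular mean of nothing")
  S <- sum(sin(angles))
  C <- sum(cos(angles))
  if (sqrt(S^2 + C^2) < 1e-12) return(NA_real_)
  atan2(S, C)
}

#' Bind round results into a long trajectory table
#'
#' @param rounds A `round_result` or list of them.
#' @param ids Optional identifiers (e.g. agent or seed labels), recycled.
#' @return A data.frame with the trajectory columns plus `id` and `round`.
#' @export
bind_trajectories <- function(rounds, ids = NULL) {
  if (inherits(rounds, "round_result")) rounds <- list(rounds)
  if (is.null(ids)) ids <- seq_along(rounds)
  out <- do.call(rbind, lapply(seq_along(rounds), function(i) {
    tr <- rounds[[i]]$trajectory
    tr$id <- ids[[min(i, length(ids))]]
    tr$round <- i
    tr
  }))
  rownames(out) <- NULL
  out
}

# steps that carry a turning decision (terminal lifespan states do not)
decision_steps <- function(traj) traj[!is.na(traj$delta_phi), , drop = FALSE]

#' Infer the rule of interaction from trajectories
#'
#' Bins every decision step by its wall cues `(theta_w, d_w)` and takes
#' the circular mean of the turning angles in each bin, recovering the
#' behavioural map from observed behaviour alone — the same procedure used
#' on real animal trajectories. Empty bins are `NA` with count 0.
#'
#' @param trajectories A trajectory data.frame ([bind_trajectories()]) or
#'   a `round_result`.
#' @param arena An [arena_config()].
#' @param n_angle,n_dist Bin counts (defaults 36 x 30).
#' @return A `rule_grid` (see [evaluate_rule_grid()]), with per-bin sample
#'   `counts`.
#' @export
inferred_rule_heatmap <- function(trajectories, arena = arena_config(),
                                  n_angle = 36, n_dist = 30) {
  traj <- decision_steps(as_trajectory_df(trajectories))
  if (!nrow(traj)) stop("no decision steps to bin")
  edges <- rule_grid_edges(arena, n_angle, n_dist)
  ia <- bin_of(traj$theta_w, edges$angle_edges)
  id <- bin_of(traj$d_w, edges$dist_edges)
  mean_turn <- matrix(NA_real_, n_angle, n_dist)
  counts <- matrix(0L, n_angle, n_dist)
  key <- (id - 1L) * n_angle + ia
  split_phi <- split(traj$delta_phi, key)
  for (nm in names(split_phi)) {
    k <- as.integer(nm)
    counts[k] <- length(split_phi[[nm]])
    mean_turn[k] <- circular_mean(split_phi[[nm]])
  }
  structure(list(angle_edges = edges$angle_edges,
                 dist_edges = edges$dist_edges,
                 mean_turn = mean_turn, counts = counts),
            class = "rule_grid")
}

as_trajectory_df <- function(trajectories) {
  if (inherits(trajectories, "round_result")) return(trajectories$trajectory)
  if (is.list(trajectories) && !is.data.frame(trajectories) &&
      all(vapply(trajectories, inherits, logical(1), "round_result")))
    return(bind_trajectories(trajectories))
  as.data.frame(trajectories)
}

# half-open bins closed at the last edge, matching the grid-cell convention
bin_of <- function(x, edges) {
  b <- findInterval(x, edges, rightmost.closed = TRUE, left.open = FALSE)
  pmin(pmax(b, 1L), length(edges) - 1L)
}

#' Presence density over (wall angle, wall distance)
#'
#' Normalized 2D histogram of where (relative to the closest wall) the
#' steps of a trajectory set were spent. Sums to 1.
#'
#' @inheritParams inferred_rule_heatmap
#' @return A `rule_grid`-shaped object whose `mean_turn` slot holds the
#'   per-bin probability mass (named `density`), plus raw `counts`.
#' @export
presence_density <- function(trajectories, arena = arena_config(),
                             n_angle = 36, n_dist = 30) {
  traj <- as_trajectory_df(trajectories)
  if (!nrow(traj)) stop("no steps to bin")
  edges <- rule_grid_edges(arena, n_angle, n_dist)
  ia <- bin_of(traj$theta_w, edges$angle_edges)
  id <- bin_of(traj$d_w, edges$dist_edges)
  counts <- matrix(0L, n_angle, n_dist)
  tab <- table((id - 1L) * n_angle + ia)
  counts[as.integer(names(tab))] <- as.integer(tab)
  structure(list(angle_edges = edges$angle_edges,
                 dist_edges = edges$dist_edges,
                 density = counts / sum(counts), counts = counts),
            class = c("presence_density", "rule_grid"))
}

#' Distribution of signed turning relative to the wall
#'
#' For each decision step, `dphi_plus = delta_phi * sign(theta_w)`:
#' positive when the agent turns away from the closest wall, negative when
#' it turns towards it (steps exactly facing the wall, `theta_w = 0`,
#' contribute 0). Restricted to a distance regime: `near` keeps steps with
#' `d_w < 50` px, `far` keeps `d_w > 150` px, `all` keeps everything.
#'
#' @inheritParams inferred_rule_heatmap
#' @param regime `"near"`, `"far"` or `"all"`.
#' @param n_bins Number of histogram bins over `(-pi, pi]`.
#' @param near_threshold,far_threshold Regime cut-offs in pixels.
#' @return An `angle_distribution` object: `bin_edges` (radians),
#'   `densities` (integrating to 1), `values` (the raw `dphi_plus`
#'   samples), `regime`, `empty` flag.
#' @export
signed_turn_distribution <- function(trajectories,
                                     regime = c("all", "near", "far"),
                                     n_bins = 72, near_threshold = 50,
                                     far_threshold = 150) {
  regime <- match.arg(regime)
  traj <- decision_steps(as_trajectory_df(trajectories))
  keep <- switch(regime,
                 near = traj$d_w < near_threshold,
                 far = traj$d_w > far_threshold,
                 all = rep(TRUE, nrow(traj)))
  traj <- traj[keep, , drop = FALSE]
  vals <- traj$delta_phi * sign(traj$theta_w)
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  if (!length(vals)) {
    return(structure(list(bin_edges = edges,
                          densities = rep(0, n_bins), values = numeric(0),
                          regime = regime, empty = TRUE),
                     class = "angle_distribution"))
  }
  counts <- tabulate(bin_of(vals, edges), nbins = n_bins)
  widths <- diff(edges)
  structure(list(bin_edges = edges,
                 densities = counts / (sum(counts) * widths),
                 values = vals, regime = regime, empty = FALSE),
            class = "angle_distribution")
}

#' Gaussian fit to small far-from-wall turning angles
#'
#' Moment-based normal fit to the turns whose magnitude is below `cutoff`
#' (default 60 degrees), reporting the Kolmogorov-Smirnov distance between
#' the empirical distribution of those small angles and the fitted normal.
#' The KS distance quantifies compatibility; no hypothesis-test verdict is
#' implied.
#'
#' @param turns Numeric vector of turning angles in radians.
#' @param cutoff Magnitude cut-off in radians (default `pi/3`, i.e. 60
#'   degrees).
#' @param min_n Minimum number of retained samples (default 30).
#' @return List with `mean`, `sd`, `ks_distance`, `n`, and a `degenerate`
#'   flag (`TRUE` when the retained sample has zero variance).
#' @export
gaussian_small_angle_fit <- function(turns, cutoff = pi / 3, min_n = 30) {
  x <- turns[abs(turns) < cutoff]
  if (length(x) < min_n)
    stop("only ", length(x), " turns below the cutoff; need >= ", min_n)
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0)
    return(list(mean = m, sd = 0, ks_distance = NA_real_, n = length(x),
                degenerate = TRUE))
  xs <- sort(x)
  F_hat <- stats::pnorm(xs, m, s)
  n <- length(xs)
  ks <- max(pmax(seq_len(n) / n - F_hat, F_hat - (seq_len(n) - 1) / n))
  list(mean = m, sd = s, ks_distance = ks, n = n, degenerate = FALSE)
}

#' Characteristic back-and-forth segment length
#'
#' Detects U-turn events (decision steps with `|delta_phi|` above the
#' threshold, default `pi/2`) and returns the median Euclidean distance
#' between consecutive U-turn positions. For the freezing strategy evolved
#' under the survive objective this collapses to the per-step displacement
#' (50 px at reference speed).
#'
#' @param trajectory A trajectory data.frame or `round_result`.
#' @param uturn_threshold Turn magnitude defining a U-turn (radians).
#' @return Median segment length in pixels, or `NA` when fewer than two
#'   U-turns occur.
#' @export
segment_length_estimate <- function(trajectory, uturn_threshold = pi / 2) {
  traj <- decision_steps(as_trajectory_df(trajectory))
  ut <- traj[abs(traj$delta_phi) > uturn_threshold, , drop = FALSE]
  if (nrow(ut) < 2) return(NA_real_)
  stats::median(sqrt(diff(ut$x)^2 + diff(ut$y)^2))
}

#' Fraction of time spent near the wall
#'
#' @param trajectory A trajectory data.frame or `round_result`.
#' @param band Distance band in pixels; steps with `d_w < band` count as
#'   wall-following.
#' @return Fraction in `[0, 1]`.
#' @export
wall_following_fraction <- function(trajectory, band = 100) {
  traj <- as_trajectory_df(trajectory)
  if (!nrow(traj)) stop("empty trajectory")
  mean(traj$d_w < band)
}

#' Sign antisymmetry of an inferred heatmap across theta_w = 0
#'
#' Checks, for near-wall bins, that mirrored angle bins carry opposite
#' turning signs — the signature of wall avoidance. Only bin pairs where
#' both members have at least `min_count` samples and a mean turn of
#' magnitude above `magnitude_floor` are compared (bins with negligible
#' mean turn carry no directional signal).
#'
#' @param grid A `rule_grid` from [inferred_rule_heatmap()].
#' @param max_dist Near-wall distance limit in pixels.
#' @param min_count Minimum samples per bin.
#' @param magnitude_floor Minimum `|mean turn|` (radians) for a bin to
#'   carry sign information.
#' @param magnitude_ceiling Maximum `|mean turn|`: a circular mean at the
#'   `+/-pi` wrap describes a full U-turn whose left/right sign is
#'   numerically arbitrary, so such bins are excluded too.
#' @return List with `n_pairs` compared and `fraction_antisymmetric`.
#' @export
heatmap_antisymmetry <- function(grid, max_dist = 50, min_count = 50,
                                 magnitude_floor = 0.01,
                                 magnitude_ceiling = 3) {
  ac <- midpoints(grid$angle_edges)
  dc <- midpoints(grid$dist_edges)
  na <- length(ac)
  stopifnot(na %% 2 == 0)  # even angle bins mirror exactly
  dcols <- which(dc < max_dist)
  ok <- 0L; total <- 0L
  for (j in dcols) {
    for (i in which(ac > 0)) {
      im <- na + 1L - i  # mirror bin: ac[im] == -ac[i]
      if (grid$counts[i, j] >= min_count && grid$counts[im, j] >= min_count &&
          is.finite(grid$mean_turn[i, j]) && is.finite(grid$mean_turn[im, j]) &&
          abs(grid$mean_turn[i, j]) > magnitude_floor &&
          abs(grid$mean_turn[im, j]) > magnitude_floor &&
          abs(grid$mean_turn[i, j]) < magnitude_ceiling &&
          abs(grid$mean_turn[im, j]) < magnitude_ceiling) {
        total <- total + 1L
        if (sign(grid$mean_turn[i, j]) == -sign(grid$mean_turn[im, j]))
          ok <- ok + 1L
      }
    }
  }
  list(n_pairs = total,
       fraction_antisymmetric = if (total) ok / total else NA_real_)
}
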