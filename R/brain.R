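#' Steering-network parameters
#'
#' The agent brain is a multilayer perceptron with two inputs (normalized
#' wall distance and wall angle), one hidden layer of `n_hidden` sigmoid
#' neurons and one sigmoid output neuron. The reference network has three
#' hidden neurons, hence `4 * 3 + 1 = 13` parameters: nine weights and
#' four biases.
#'
#' @param hidden_weights `n_hidden x 2` matrix; column 1 weighs the
#'   normalized distance, column 2 the normalized angle.
#' @param hidden_biases Length-`n_hidden` vector.
#' @param output_weights Length-`n_hidden` vector.
#' @param output_bias Scalar.
#' @return An object of class `brain_params`.
#' @export
brain_params <- function(hidden_weights, hidden_biases, output_weights,
                         output_bias) {
  hidden_weights <- matrix(as.numeric(hidden_weights), ncol = 2)
  K <- nrow(hidden_weights)
  stopifnot(K >= 1, length(hidden_biases) == K, length(output_weights) == K,
            length(output_bias) == 1)
  p <- structure(list(hidden_weights = hidden_weights,
                      hidden_biases = as.numeric(hidden_biases),
                      output_weights = as.numeric(output_weights),
                      output_bias = as.numeric(output_bias),
                      n_hidden = K),
                 class = "brain_params")
  if (!all(vapply(p[1:4], function(v) all(is.finite(v)), logical(1))))
    stop("brain parameters must be finite")
  p
}

#' @export
print.brain_params <- function(x, ...) {
  cat(sprintf("<brain_params> 2-%d-1 sigmoid network, %d parameters\n",
              x$n_hidden, param_count(x$n_hidden)))
  invisible(x)
}

#' Number of parameters of a 2-K-1 network
#'
#' `2*K` hidden weights + `K` hidden biases + `K` output weights + 1 output
#' bias = `4*K + 1`; 13 for the reference three-neuron hidden layer.
#'
#' @param n_hidden Hidden-layer size (>= 1).
#' @return Integer parameter count.
#' @examples
#' param_count(3)  # 13
#' @export
param_count <- function(n_hidden) {
  if (n_hidden < 1) stop("n_hidden must be >= 1")
  as.integer(4 * n_hidden + 1)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Forward pass of the steering network
#'
#' `o1 = sigma(b_out + sum_k v_k * sigma(b_k + w_k1 * d + w_k2 * a))` with
#' `sigma(z) = 1 / (1 + exp(-z))` applied at the hidden and the output
#' neuron, so `o1` lies strictly in (0, 1). The map is deterministic:
#' identical parameters and inputs give bit-identical outputs.
#'
#' @param params A [brain_params()].
#' @param d_norm Normalized wall distance in `[0, 1]`.
#' @param a_norm Normalized wall angle in `[0, 1]`.
#' @return Output activation `o1` in (0, 1). Vectorized over inputs.
#' @export
brain_forward <- function(params, d_norm, a_norm) {
  W <- params$hidden_weights
  b <- params$hidden_biases
  v <- params$output_weights
  # accumulate output bias first, then hidden contributions in neuron order:
  # the vectorized population core uses the same order, keeping the two
  # code paths bit-identical
  acc <- rep(params$output_bias, length.out = length(d_norm))
  for (k in seq_len(params$n_hidden)) {
    z <- b[k] + W[k, 1] * d_norm + W[k, 2] * a_norm
    acc <- acc + v[k] / (1 + exp(-z))
  }
  1 / (1 + exp(-acc))
}

#' Map the network output to a turning angle
#'
#' The centred coefficient `c_steering = o1 - 0.5` scales the steering
#' increment: `dphi = (o1 - 0.5) * i_steering`, so with the reference
#' `i_steering = 2*pi` a single step can turn by any angle in `(-pi, pi)`.
#'
#' @param o1 Network output in `[0, 1]`.
#' @param i_steering Steering increment in `[0, 2*pi]`.
#' @return Turning angle in radians. Vectorized.
#' @examples
#' steering_angle(0.5, 2 * pi)  # 0: neutral output goes straight
#' steering_angle(1, 2 * pi)    # pi
#' @export
steering_angle <- function(o1, i_steering) {
  (o1 - 0.5) * i_steering
}

#' Flatten brain parameters to a genome vector
#'
#' Fixed genome ordering: hidden weights row-major (`w_11, w_12, w_21,
#' w_22, ...`), then hidden biases, then output weights, then the output
#' bias; length `4 * n_hidden + 1`. This is the representation the genetic
#' algorithm selects and mutates.
#'
#' @param params A [brain_params()].
#' @return Numeric vector of length `param_count(n_hidden)`.
#' @seealso [unpack_brain()]
#' @export
pack_brain <- function(params) {
  c(t(params$hidden_weights), params$hidden_biases, params$output_weights,
    params$output_bias)
}

#' Rebuild brain parameters from a genome vector
#'
#' Inverse of [pack_brain()]; `unpack_brain(pack_brain(p), p$n_hidden)`
#' is the identity.
#'
#' @param genome Numeric vector of length `4 * n_hidden + 1`.
#' @param n_hidden Hidden-layer size.
#' @return A [brain_params()].
#' @export
unpack_brain <- function(genome, n_hidden = 3L) {
  len <- param_count(n_hidden)
  if (length(genome) != len)
    stop("genome has length ", length(genome), " but a 2-", n_hidden,
         "-1 network needs ", len)
  K <- n_hidden
  brain_params(hidden_weights = matrix(genome[seq_len(2 * K)], nrow = K,
                                       byrow = TRUE),
               hidden_biases = genome[2 * K + seq_len(K)],
               output_weights = genome[3 * K + seq_len(K)],
               output_bias = genome[4 * K + 1])
}
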