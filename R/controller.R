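#' Neural controller topology
#'
#' The controller is a three-layer feed-forward network: one constant bias
#' input plus 17 sensory inputs (8 proximity, 9 camera neurons), 9 hidden
#' neurons, and 2 output neurons driving the wheels.  With the memory
#' neuron an 18th sensory input is appended.  Hidden and output neurons use
#' the logistic activation `1/(1 + exp(-x))`; outputs are mapped linearly
#' onto wheel velocities in `[-8.2, 8.2]` cm/s.
#'
#' The weight count is `(1 + n_sensor_inputs) * n_hidden +
#' (n_hidden + 1) * n_outputs`: 182 without memory (18 x 9 + 10 x 2) and
#' 191 with (the hidden-to-output block carries one bias weight per output
#' neuron — the only arrangement consistent with 182 weights given the
#' stated layer sizes).
#'
#' @param has_memory logical; append the memory input neuron?
#' @return An object of class `network_topology`.
#' @export
network_topology <- function(has_memory = FALSE) {
  n_in <- if (has_memory) 18L else 17L
  structure(list(n_sensor_inputs = n_in, n_hidden = 9L, n_outputs = 2L,
                 has_memory = has_memory,
                 n_weights = (1L + n_in) * 9L + (9L + 1L) * 2L),
            class = "network_topology")
}

#' @export
print.network_topology <- function(x, ...) {
  cat(sprintf("Network topology: %d+1 inputs -> %d hidden -> %d outputs (%d weights)%s\n",
              x$n_sensor_inputs, x$n_hidden, x$n_outputs, x$n_weights,
              if (x$has_memory) " [memory]" else ""))
  invisible(x)
}

#' Assemble a controller network from a weight vector
#'
#' Weight order (the genome decode order): the input-to-hidden block comes
#' first, hidden-neuron-major, each hidden neuron's weights ordered
#' `[bias, proximity 1..8, camera 1..9]`; for memory topologies the 9
#' memory-input weights follow as a block (so 182-weight genomes are
#' prefix-compatible); the hidden-to-output block comes last,
#' output-neuron-major, each output's weights ordered
#' `[hidden 1..9, bias]`.
#'
#' @param weights numeric vector whose length matches the topology.
#' @param topology a [network_topology()].
#' @return An object of class `robot_network` with weight matrices `W1`
#'   (hidden x inputs, bias column first) and `W2` (outputs x (hidden+1)).
#' @export
build_network <- function(weights, topology = network_topology()) {
  if (!inherits(topology, "network_topology")) stop("invalid topology")
  if (length(weights) != topology$n_weights)
    stop(sprintf("topology error: expected %d weights, got %d",
                 topology$n_weights, length(weights)))
  nh <- topology$n_hidden
  base <- matrix(weights[seq_len(18L * nh)], nrow = nh, byrow = TRUE)
  if (topology$has_memory) {
    W1 <- cbind(base, weights[18L * nh + seq_len(nh)])
    off <- 18L * nh + nh
  } else {
    W1 <- base
    off <- 18L * nh
  }
  W2 <- matrix(weights[off + seq_len((nh + 1L) * topology$n_outputs)],
               nrow = topology$n_outputs, byrow = TRUE)
  structure(list(W1 = W1, W2 = W2, topology = topology,
                 weights = as.numeric(weights)),
            class = "robot_network")
}

#' @export
print.robot_network <- function(x, ...) {
  print(x$topology)
  invisible(x)
}

#' Forward pass: sensor activations to wheel velocities
#'
#' Pure and deterministic: `h = sigmoid(W1 [1, sensors])`,
#' `o = sigmoid(W2 [h, 1])`, wheel velocity `= -8.2 + o * 16.4` cm/s.
#'
#' @param network a [build_network()] result.
#' @param sensor_values numeric vector of sensor activations in `[0, 1]`,
#'   length `n_sensor_inputs` (memory activation last for memory
#'   topologies).
#' @param vmax wheel speed bound in cm/s.
#' @return Numeric length-2 vector of wheel velocities (left, right) in
#'   cm/s, each within `[-vmax, vmax]`.
#' @export
activate_network <- function(network, sensor_values, vmax = 8.2) {
  if (!inherits(network, "robot_network")) stop("not a robot_network")
  n_in <- network$topology$n_sensor_inputs
  if (length(sensor_values) != n_in)
    stop(sprintf("expected %d sensor values, got %d", n_in,
                 length(sensor_values)))
  if (anyNA(sensor_values) || any(sensor_values < 0 | sensor_values > 1))
    stop("sensor-range error: activations must be in [0, 1]")
  h <- stats::plogis(as.vector(network$W1 %*% c(1, sensor_values)))
  o <- stats::plogis(as.vector(network$W2 %*% c(h, 1)))
  -vmax + o * 2 * vmax
}

#' Memory-neuron state and activation
#'
#' The memory neuron reports the fraction of a robot's completed stuck
#' episodes that ended with partner help.  With no completed episode it sits
#' at its maximum of 1 (the value it is reset to at the start of every
#' evaluation).
#'
#' @param opportunities integer count of completed stuck episodes.
#' @param helps integer count of those ended by partner help.
#' @return For `memory_state`, an object of class `memory_state`; for
#'   `memory_activation`, a value in `[0, 1]`.
#' @export
memory_state <- function(opportunities = 0L, helps = 0L) {
  opportunities <- as.integer(opportunities); helps <- as.integer(helps)
  if (is.na(opportunities) || is.na(helps) || opportunities < 0 || helps < 0)
    stop("counts must be non-negative integers")
  if (helps > opportunities)
    stop("invariant violation: helps > opportunities")
  structure(list(opportunities = opportunities, helps = helps),
            class = "memory_state")
}

#' @rdname memory_state
#' @param state a `memory_state`.
#' @export
memory_activation <- function(state) {
  if (!inherits(state, "memory_state")) stop("not a memory_state")
  if (state$opportunities == 0L) 1.0 else state$helps / state$opportunities
}
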