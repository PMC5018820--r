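# Shared fixtures built in code.

# genome whose every byte is the given value (0..255)
constant_byte_genome <- function(byte, spec = decoding_spec()) {
  bits <- as.integer(rev(intToBits(byte)[1:8]))
  g <- rep(bits, spec$n_weights)
  structure(g, spec = spec, class = "genome")
}

# genome decoding to (approximately) the given weight vector
genome_from_weights <- function(weights, spec = decoding_spec()) {
  stopifnot(length(weights) == spec$n_weights)
  v <- round((weights - spec$weight_min) /
             (spec$weight_max - spec$weight_min) * 255)
  bits <- unlist(lapply(v, function(x) as.integer(rev(intToBits(x)[1:8]))))
  structure(as.integer(bits), spec = spec, class = "genome")
}

# exact zero is not on the 8-bit decoding grid, so motionless robots are
# expressed as plain weight vectors (all zeros -> sigmoid(0) = 0.5 ->
# wheel velocity exactly 0), which the evaluation entry points accept
motionless_weights <- function(has_memory = FALSE) {
  rep(0, network_topology(has_memory)$n_weights)
}

# the reference payoff matrix without touching the installed fixture
table_payoffs <- function() {
  payoff_matrix(matrix(c(152, 205, 160,
                         132, 198, 175,
                         147, 203, 173), 3, 3, byrow = TRUE,
                       dimnames = list(c("Selfish", "Helper", "Reciprocator"),
                                       c("Selfish", "Helper", "Reciprocator"))))
}

fast_arena <- function(...) arena_config(eval_steps = 500L, ...)

# independent oracle: absorption probability of the frequency-dependent
# Moran birth-death chain, solved as a linear system over states 0..N
moran_absorption <- function(a, b, cc, d, N, w) {
  Tp <- Tm <- numeric(N + 1)
  for (k in 1:(N - 1)) {
    piA <- (a * (k - 1) + b * (N - k)) / (N - 1)
    piB <- (cc * k + d * (N - k - 1)) / (N - 1)
    fA <- 1 - w + w * piA
    fB <- 1 - w + w * piB
    Tp[k + 1] <- fA * k / (fA * k + fB * (N - k)) * (N - k) / N
    Tm[k + 1] <- fB * (N - k) / (fA * k + fB * (N - k)) * k / N
  }
  A <- matrix(0, N + 1, N + 1)
  rhs <- numeric(N + 1)
  A[1, 1] <- 1; rhs[1] <- 0
  A[N + 1, N + 1] <- 1; rhs[N + 1] <- 1
  for (k in 1:(N - 1)) {
    row <- k + 1
    A[row, row] <- Tp[row] + Tm[row]
    A[row, row - 1] <- -Tm[row]
    A[row, row + 1] <- -Tp[row]
  }
  solve(A, rhs)[2] # single invader
}
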