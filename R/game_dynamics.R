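#' Strategy payoff matrix
#'
#' Square matrix whose entry (i, j) is the mean payoff of a row player of
#' strategy i against a partner of strategy j, in fitness units (food
#' items per evaluation).
#'
#' @param payoffs square numeric matrix with matching row/column names.
#' @param standard_errors optional same-shape matrix of standard errors.
#' @return An object of class `payoff_matrix`.
#' @export
payoff_matrix <- function(payoffs, standard_errors = NULL) {
  payoffs <- as.matrix(payoffs)
  storage.mode(payoffs) <- "double"
  if (nrow(payoffs) != ncol(payoffs)) stop("payoff matrix must be square")
  if (is.null(rownames(payoffs)) || is.null(colnames(payoffs)))
    stop("payoff matrix needs strategy names on rows and columns")
  if (!identical(rownames(payoffs), colnames(payoffs)))
    stop("row and column strategy names must match")
  if (any(!is.finite(payoffs)) || any(payoffs < 0))
    stop("payoffs must be finite and non-negative")
  structure(list(payoffs = payoffs, standard_errors = standard_errors,
                 strategies = rownames(payoffs)),
            class = "payoff_matrix")
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat("Row-player payoff matrix:\n")
  print(x$payoffs)
  invisible(x)
}

#' The measured Selfish/Helper/Reciprocator payoff matrix
#'
#' The packaged reference payoff matrix among the three bred strategies
#' (row player's mean payoff over 1000 simulated interactions per ordered
#' pair), shipped as a TSV fixture.
#'
#' @return A [payoff_matrix()].
#' @export
reference_payoffs <- function() {
  read_payoff_matrix(system.file("extdata", "reference_payoffs.tsv",
                                 package = "reciprobot", mustWork = TRUE))
}

#' Read / write payoff matrices as TSV
#'
#' Layout: header row of strategy names, then one line per row strategy
#' (name followed by its payoffs).
#'
#' @param path file path.
#' @export
read_payoff_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  payoff_matrix(m)
}

#' @rdname read_payoff_matrix
#' @param matrix a [payoff_matrix()].
#' @export
write_payoff_matrix <- function(matrix, path) {
  utils::write.table(matrix$payoffs, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

get_payoffs <- function(matrix) {
  if (inherits(matrix, "payoff_matrix")) matrix$payoffs else as.matrix(matrix)
}

#' Classify a two-strategy game
#'
#' With cooperator payoffs R (mutual cooperation) and S (against a
#' defector), and defector payoffs T (against a cooperator) and P (mutual
#' defection): `T > R > P > S` is a prisoner's dilemma, `T > R > S > P` a
#' snowdrift game, `R > T, P > S` a stag hunt, `R > T, S > P` a harmony
#' game; anything else is `"other"`, and ties across the defining
#' comparisons give `"ambiguous"`.
#'
#' @param matrix a [payoff_matrix()] (or plain named matrix).
#' @param cooperator,defector strategy names.
#' @return One of `"prisoners_dilemma"`, `"snowdrift"`, `"stag_hunt"`,
#'   `"harmony"`, `"other"`, `"ambiguous"`.
#' @export
classify_two_strategy_game <- function(matrix, cooperator, defector) {
  p <- get_payoffs(matrix)
  R <- p[cooperator, cooperator]; S <- p[cooperator, defector]
  T <- p[defector, cooperator];   P <- p[defector, defector]
  vals <- c(T = T, R = R, P = P, S = S)
  if (anyDuplicated(vals)) return("ambiguous")
  if (T > R && R > P && P > S) return("prisoners_dilemma")
  if (T > R && R > S && S > P) return("snowdrift")
  if (R > T && P > S && T > P) return("stag_hunt")
  if (R > T && S > P) return("harmony")
  "other"
}

#' Invasion threshold of one strategy against a resident
#'
#' Solves the payoff-equality condition
#' `x P(i,i) + (1-x) P(i,r) = x P(r,i) + (1-x) P(r,r)` for the invader
#' frequency `x`.  Returns the root if it lies in (0, 1); 0 if the
#' invader's expected payoff exceeds the resident's at every frequency;
#' `NA` if the invader is never favored on (0, 1].
#'
#' @param matrix a [payoff_matrix()].
#' @param invader,resident strategy names.
#' @return Frequency in `[0, 1]`, or `NA`.
#' @export
invasion_threshold <- function(matrix, invader, resident) {
  if (identical(invader, resident)) stop("invader must differ from resident")
  p <- get_payoffs(matrix)
  # payoff advantage of the invader at frequency x:
  # delta(x) = d0 + (d1 - d0) x, with
  d0 <- p[invader, resident] - p[resident, resident]
  d1 <- p[invader, invader] - p[resident, invader]
  if (d0 == 0 && d1 == 0)
    stop("degenerate game: strategies are payoff-identical")
  if (d0 > 0 && d1 > 0) return(0)
  if (d1 == d0) return(if (d0 > 0) 0 else NA_real_)
  x <- -d0 / (d1 - d0)
  if (x > 0 && x < 1) return(x)
  if (d0 > 0) 0 else NA_real_
}

#' Format a frequency at a table's printed precision
#'
#' Truncates toward zero at `digits` decimals — the convention under which
#' the reference threshold 5/18 = 0.2778 prints as 0.27.
#'
#' @param x numeric value.
#' @param digits decimal places kept.
#' @export
printed_frequency <- function(x, digits = 2) {
  trunc(x * 10^digits) / 10^digits
}

#' Moran fixation probability in a frequency-dependent 2x2 game
#'
#' A single invader in a resident population of size N under the
#' frequency-dependent Moran process with self-excluded expected payoffs
#' and the payoff-to-fitness map `f = 1 - w + w * pi` (intensity `w`; the
#' default `w = 1` uses payoffs as fitness directly, mirroring
#' fecundity-proportional selection).  Fixation probability
#' `rho = 1 / (1 + sum_k prod_j f_B(j)/f_A(j))`.
#'
#' @param matrix 2x2 [payoff_matrix()] (or named matrix); the first
#'   strategy name is the invader unless given.
#' @param N population size (>= 2).
#' @param intensity selection intensity `w >= 0`.
#' @param invader,resident strategy names.
#' @return Fixation probability in `[0, 1]`.
#' @export
moran_fixation_probability <- function(matrix, N = 100L, intensity = 1,
                                       invader = NULL, resident = NULL) {
  p <- get_payoffs(matrix)
  if (is.null(invader)) invader <- rownames(p)[1L]
  if (is.null(resident)) resident <- setdiff(rownames(p), invader)[1L]
  if (N < 2L) stop("N must be >= 2")
  if (intensity < 0) stop("intensity must be >= 0")
  a <- p[invader, invader]; b <- p[invader, resident]
  cc <- p[resident, invader]; d <- p[resident, resident]
  k <- seq_len(N - 1L)
  piA <- (a * (k - 1) + b * (N - k)) / (N - 1)
  piB <- (cc * k + d * (N - k - 1)) / (N - 1)
  fA <- 1 - intensity + intensity * piA
  fB <- 1 - intensity + intensity * piB
  if (any(fA <= 0) || any(fB <= 0))
    stop("intensity error: non-positive fitness at some state")
  gamma <- fB / fA
  1 / (1 + sum(cumprod(gamma)))
}

#' Finite-population dynamics of two or more strategies
#'
#' Wright-Fisher resampling on strategy counts: each generation, every
#' strategy's expected payoff is computed under random pairing excluding
#' self, counts are resampled multinomially in proportion to
#' count x fitness (fitness = payoff with the default unit intensity), and
#' each offspring mutates to one of the other strategies with probability
#' `mu`, split equally.
#'
#' @param matrix a [payoff_matrix()].
#' @param N population size.
#' @param mu per-offspring mutation probability per generation.
#' @param generations number of generations to simulate.
#' @param init_counts integer vector over strategies summing to N;
#'   defaults to an (almost) equal split.
#' @param intensity payoff-to-fitness intensity as in
#'   [moran_fixation_probability()].
#' @return An object of class `strategy_trajectory`: `counts`
#'   (generations x strategies matrix, including generation 0), `N`.
#' @export
simulate_strategy_dynamics <- function(matrix, N = 100L, mu = 1e-2,
                                       generations = 1000L,
                                       init_counts = NULL, intensity = 1) {
  p <- get_payoffs(matrix)
  s <- nrow(p)
  if (is.null(init_counts)) {
    init_counts <- rep(N %/% s, s)
    init_counts[1L] <- init_counts[1L] + N - sum(init_counts)
  }
  if (sum(init_counts) != N) stop("init_counts must sum to N")
  counts <- matrix(0L, generations + 1L, s,
                   dimnames = list(NULL, rownames(p)))
  counts[1L, ] <- as.integer(init_counts)
  n <- as.numeric(init_counts)
  for (g in seq_len(generations)) {
    pay <- as.vector(p %*% n - diag(p) ) / (N - 1)  # self-excluded
    f <- 1 - intensity + intensity * pay
    f[n == 0] <- 0
    w <- n * f
    if (sum(w) <= 0) w <- n
    off <- as.numeric(stats::rmultinom(1L, N, w))
    if (mu > 0) {
      for (i in seq_len(s)) {
        m <- stats::rbinom(1L, off[i], mu)
        if (m > 0) {
          dest <- stats::rmultinom(1L, m, rep(1, s - 1L))
          off[i] <- off[i] - m
          off[-i] <- off[-i] + as.numeric(dest)
        }
      }
    }
    n <- off
    counts[g + 1L, ] <- as.integer(n)
  }
  structure(list(counts = counts, N = as.integer(N),
                 generations = as.integer(generations)),
            class = "strategy_trajectory")
}

#' @export
print.strategy_trajectory <- function(x, ...) {
  cat(sprintf("Strategy trajectory: N=%d, %d generations; final counts: %s\n",
              x$N, x$generations,
              paste(sprintf("%s=%d", colnames(x$counts),
                            x$counts[nrow(x$counts), ]), collapse = ", ")))
  invisible(x)
}

#' Occupancy histogram of a trajectory over the frequency simplex
#'
#' Bins the per-generation frequency vectors of the first two strategies
#' on an `n_bins` x `n_bins` grid (the third coordinate is implied); total
#' visits equal the number of recorded generations.
#'
#' @param trajectory a `strategy_trajectory`.
#' @param n_bins bins per axis.
#' @return Matrix of visit counts; `dimnames` give the bin lower edges.
#' @export
occupancy_histogram <- function(trajectory, n_bins = 20L) {
  # generation 0 is the initial condition, not a visit
  fr <- trajectory$counts[-1L, , drop = FALSE] / trajectory$N
  ix <- pmin(floor(fr[, 1L] * n_bins), n_bins - 1L) + 1L
  iy <- pmin(floor(fr[, 2L] * n_bins), n_bins - 1L) + 1L
  h <- matrix(0L, n_bins, n_bins,
              dimnames = list(sprintf("%.3f", (0:(n_bins - 1)) / n_bins),
                              sprintf("%.3f", (0:(n_bins - 1)) / n_bins)))
  for (k in seq_along(ix)) h[ix[k], iy[k]] <- h[ix[k], iy[k]] + 1L
  h
}

#' Write a strategy trajectory as TSV
#'
#' @param trajectory a `strategy_trajectory`.
#' @param path output path.
#' @export
write_trajectory_log <- function(trajectory, path) {
  df <- data.frame(generation = 0:trajectory$generations,
                   trajectory$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
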