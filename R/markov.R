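#' One row of the genotypic-state transition matrix
#'
#' The probability of moving from `source` to each target state in one
#' generation is multinomial: `N` offspring are drawn independently with
#' category probabilities [offspring_freqs()] of the source state.
#' Probabilities are computed in log space with `lgamma` coefficients,
#' exponentiated, and renormalised to sum exactly 1 (the
#' pre-normalisation drift must be rounding-level and is asserted to be
#' `< 1e-13`).
#'
#' @param source integer vector `c(n_aa, n_aA, n_AA)`.
#' @param space a [state_space()] object.
#' @param c rate of asexuality in `[0, 1]`.
#' @param mu reciprocal mutation rate in `[0, 0.5]`.
#' @return numeric probability vector over `space$states` (canonical
#'   order).
#' @examples
#' sp <- state_space(2)
#' transition_row(c(0, 2, 0), sp, c = 0, mu = 0)
#' @export
transition_row <- function(source, space, c, mu) {
  stopifnot(inherits(space, "state_space"))
  f <- offspring_freqs(source, space$N, c, mu)
  row <- transition_row_cpp(log(f), space$states, log_multinom_coef(space))
  assert_row_drift(attr(row, "max_row_drift"), space$N)
  attr(row, "max_row_drift") <- NULL
  row
}

#' Exact one-generation transition matrix
#'
#' Builds the dense `S x S` row-stochastic matrix of multinomial
#' transition probabilities between all genotypic states,
#' `S = (N+1)(N+2)/2`. All entries are strictly positive for
#' `mu` in `(0, 0.5)`, making the chain irreducible and aperiodic, hence
#' ergodic with a unique stationary distribution.
#'
#' Memory is the practical limit: the matrix holds `S^2` doubles
#' (about 0.8 GB at `N = 140`, `S = 10011`). The build is chunk-free and
#' compiled; `max_states` guards against accidentally requesting an
#' out-of-budget size.
#'
#' @param space a [state_space()] object.
#' @param c rate of asexuality in `[0, 1]`.
#' @param mu reciprocal mutation rate in `[0, 0.5]`.
#' @param max_states refuse to allocate above this state count
#'   (default 16000, about 2 GB dense).
#' @return An object of class `transition_matrix`: list with `P` (the
#'   matrix), `N`, `c`, `mu`, and `max_row_drift` (largest
#'   pre-normalisation row-sum deviation).
#' @examples
#' sp <- state_space(5)
#' tm <- transition_matrix(sp, c = 0.5, mu = 0.05)
#' range(rowSums(tm$P))
#' @export
transition_matrix <- function(space, c, mu, max_states = 16000) {
  stopifnot(inherits(space, "state_space"))
  S <- nrow(space$states)
  if (S > max_states) {
    stop(sprintf(paste0(
      "state space has %d states; dense build capped at %d ",
      "(raise `max_states` if you have ~%.1f GB to spare)"),
      S, max_states, 8 * (S / 1e3)^2 / 1e3), call. = FALSE)
  }
  fr <- offspring_freqs_all(space, c, mu)
  P <- build_transition_cpp(log(fr), space$states, log_multinom_coef(space))
  drift <- attr(P, "max_row_drift")
  assert_row_drift(drift, space$N)
  attr(P, "max_row_drift") <- NULL
  structure(list(P = P, N = space$N, c = c, mu = mu,
                 max_row_drift = drift),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf(
    "Transition matrix: N = %d (%d states), c = %g, mu = %g\n",
    x$N, nrow(x$P), x$c, x$mu))
  cat(sprintf("  max pre-normalisation row drift: %.2e\n", x$max_row_drift))
  invisible(x)
}

# lgamma(N+1) - sum_k lgamma(n_k + 1) per state, reused across rows.
log_multinom_coef <- function(space) {
  lgamma(space$N + 1) - rowSums(lgamma(space$states + 1))
}

# Pre-normalisation row sums deviate from 1 only by the rounding of the
# log-space terms, whose absolute log error is of order lgamma(N+1) ulps
# (lgamma(141) ~ 500, so ~1e-13 relative at N = 140). Anything above a
# generous multiple of that bound indicates a model error, not rounding.
assert_row_drift <- function(drift, N) {
  tol <- 64 * (lgamma(N + 1) + 1) * .Machine$double.eps
  if (drift >= tol) {
    stop(sprintf(
      "transition row sums deviate from 1 by %.3e before renormalisation
  (rounding-level bound %.3e at N = %d): upstream error",
      drift, tol, N), call. = FALSE)
  }
  invisible(TRUE)
}

#' Evolve a distribution over genotypic states
#'
#' Applies the one-generation update `p <- p P` repeatedly (vector-matrix
#' products; the matrix is never powered explicitly).
#'
#' @param initial probability vector over states (canonical order),
#'   summing to 1.
#' @param tm a [transition_matrix()] object.
#' @param n_generations number of generations (0 returns `initial`).
#' @return probability vector over states after `n_generations`.
#' @examples
#' sp <- state_space(3)
#' tm <- transition_matrix(sp, c = 0, mu = 0.1)
#' p0 <- replace(numeric(nrow(sp$states)), 1, 1)
#' evolve(p0, tm, 5)
#' @export
evolve <- function(initial, tm, n_generations) {
  stopifnot(inherits(tm, "transition_matrix"))
  p <- as.numeric(initial)
  if (length(p) != nrow(tm$P) || abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
    stop("`initial` must be a probability vector over the state space",
         call. = FALSE)
  }
  if (n_generations < 0 || n_generations != round(n_generations)) {
    stop("`n_generations` must be a nonnegative integer", call. = FALSE)
  }
  for (i in seq_len(n_generations)) p <- as.numeric(p %*% tm$P)
  p
}

#' Stationary distribution of the genotypic-state chain
#'
#' Solves the left eigenproblem `pi P = pi`, `sum(pi) = 1` directly: one
#' equation of the singular system `(P^T - I) pi = 0` is replaced by the
#' normalisation constraint and the result obtained by a dense LU solve.
#' This honours the Perron-Frobenius dominant-eigenvector
#' characterisation of the ergodic chain's limit while avoiding power
#' iteration, whose mixing time is of order `1/mu` (hopeless at
#' `mu = 1e-8`). Entries in `[-1e-12, 0)` are clipped to 0 and the vector
#' renormalised; the max-norm residual `||pi P - pi||` is checked against
#' `tol`.
#'
#' @param tm a [transition_matrix()] object with `mu > 0` (for `mu = 0`
#'   the chain is not ergodic and the stationary distribution is not
#'   unique).
#' @param tol residual tolerance (default `1e-12`).
#' @return An object of class `stationary_distribution`: list with `pi`
#'   (probability vector over states, canonical order), `residual`
#'   (max-norm of `pi P - pi`), `N`, `c`, `mu`.
#' @examples
#' sp <- state_space(5)
#' tm <- transition_matrix(sp, c = 0.5, mu = 0.05)
#' st <- stationary_distribution(tm)
#' st$residual
#' @export
stationary_distribution <- function(tm, tol = 1e-12) {
  stopifnot(inherits(tm, "transition_matrix"))
  if (tm$mu <= 0) {
    stop(paste("mu = 0: chain is not ergodic (fixation states are",
               "absorbing) and has no unique stationary distribution"),
         call. = FALSE)
  }
  S <- nrow(tm$P)
  A <- t(tm$P)
  diag(A) <- diag(A) - 1
  A[S, ] <- 1                      # replace one equation by sum(pi) = 1
  b <- c(numeric(S - 1), 1)
  pi <- solve(A, b)
  rm(A)
  if (any(pi < -1e-12)) {
    stop(sprintf(
      "stationary solve produced entries as low as %.3e (< -1e-12)",
      min(pi)), call. = FALSE)
  }
  pi[pi < 0] <- 0
  pi <- pi / sum(pi)
  residual <- max(abs(as.numeric(pi %*% tm$P) - pi))
  if (residual > tol) {
    stop(sprintf(
      "stationary residual %.3e exceeds tolerance %.1e (N = %d, c = %g, mu = %g)",
      residual, tol, tm$N, tm$c, tm$mu), call. = FALSE)
  }
  structure(list(pi = pi, residual = residual,
                 N = tm$N, c = tm$c, mu = tm$mu),
            class = "stationary_distribution")
}

#' @export
print.stationary_distribution <- function(x, ...) {
  cat(sprintf(
    "Stationary distribution: N = %d (%d states), c = %g, mu = %g\n",
    x$N, length(x$pi), x$c, x$mu))
  cat(sprintf("  residual ||pi P - pi|| = %.2e\n", x$residual))
  invisible(x)
}

#' Export a stationary distribution keyed by genotypic state
#'
#' @param st a [stationary_distribution()] object.
#' @param space the matching [state_space()].
#' @param file path of the CSV to write.
#' @return the file path, invisibly.
#' @export
write_stationary <- function(st, space, file) {
  stopifnot(inherits(st, "stationary_distribution"),
            inherits(space, "state_space"),
            length(st$pi) == nrow(space$states))
  df <- data.frame(space$states, probability = st$pi)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
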