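#' Expected offspring genotype frequencies under asexual reproduction
#'
#' A clonal offspring receives the whole diploid genotype of one parent
#' drawn uniformly from the population; each of its two alleles then
#' mutates independently (reciprocal mutation, a <-> A, rate `mu` per
#' transmission). With `v = 1 - mu`:
#' \deqn{f'_{aa} = f_{aa} v^2 + f_{aA} \mu v + f_{AA} \mu^2}
#' \deqn{f'_{aA} = 2 \mu v (f_{aa} + f_{AA}) + f_{aA} (v^2 + \mu^2)}
#' and symmetrically for `f'_AA`.
#'
#' @param f numeric vector of genotype frequencies `c(f_aa, f_aA, f_AA)`
#'   (or a matrix with one frequency triple per row).
#' @param mu reciprocal per-allele mutation rate, in `[0, 0.5]` (beyond
#'   0.5 the two-allele reciprocal model aliases back).
#' @return genotype frequencies after one clonal generation, same shape
#'   as `f`.
#' @examples
#' asexual_offspring_freqs(c(1, 0, 0), 0.1)  # (0.81, 0.18, 0.01)
#' @export
asexual_offspring_freqs <- function(f, mu) {
  mu <- check_rate(mu, "mu", max = 0.5)
  if (!is.matrix(f)) {
    f <- matrix(check_freqs(f), 1); drop <- TRUE
  } else drop <- FALSE
  v <- 1 - mu
  out <- cbind(
    f[, 1] * v^2 + f[, 2] * mu * v + f[, 3] * mu^2,
    2 * mu * v * (f[, 1] + f[, 3]) + f[, 2] * (v^2 + mu^2),
    f[, 3] * v^2 + f[, 2] * mu * v + f[, 1] * mu^2
  )
  if (drop) out[1, ] else out
}

#' Expected offspring genotype frequencies under sexual reproduction
#'
#' Random union of gametes (pangamy and panmixy; selfing occurs at the
#' background rate `1/N` implied by sampling gametes with replacement):
#' the parental allele frequency `p = f_aa + f_aA/2` mutates to
#' `p' = p(1 - mu) + (1 - p) mu`, and offspring are in Hardy-Weinberg
#' proportions `(p'^2, 2 p'(1-p'), (1-p')^2)`.
#'
#' @inheritParams asexual_offspring_freqs
#' @return genotype frequencies after one sexual generation.
#' @examples
#' sexual_offspring_freqs(c(1, 0, 0), 0.1)  # (0.81, 0.18, 0.01)
#' @export
sexual_offspring_freqs <- function(f, mu) {
  mu <- check_rate(mu, "mu", max = 0.5)
  if (!is.matrix(f)) {
    f <- matrix(check_freqs(f), 1); drop <- TRUE
  } else drop <- FALSE
  p <- f[, 1] + f[, 2] / 2
  p <- p * (1 - mu) + (1 - p) * mu
  out <- cbind(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (drop) out[1, ] else out
}

#' Expected offspring genotype frequencies of a genotypic state
#'
#' The one-generation expectation is the `c`-mixture of the clonal and
#' sexual maps applied to the state's genotype frequencies
#' `(n_aa, n_aA, n_AA)/N`:
#' `f' = c * asexual(f) + (1 - c) * sexual(f)`.
#' These are the category probabilities of the multinomial transition
#' law of the finite-population chain.
#'
#' @param state integer vector `c(n_aa, n_aA, n_AA)`.
#' @param N population size.
#' @param c rate of asexuality in `[0, 1]`: probability that an offspring
#'   is produced clonally.
#' @param mu reciprocal per-allele mutation rate in `[0, 0.5]`.
#' @return numeric vector of expected offspring genotype frequencies.
#' @examples
#' offspring_freqs(c(5, 5, 0), N = 10, c = 0.5, mu = 1e-3)
#' @export
offspring_freqs <- function(state, N, c, mu) {
  N <- check_N(N)
  state <- check_state(state, N)
  c <- check_rate(c, "c")
  f <- state / N
  c * asexual_offspring_freqs(f, mu) + (1 - c) * sexual_offspring_freqs(f, mu)
}

# Mixture map for all states of a space at once: S x 3 matrix.
offspring_freqs_all <- function(space, c, mu) {
  c <- check_rate(c, "c")
  f <- space$states / space$N
  c * asexual_offspring_freqs(f, mu) +
    (1 - c) * sexual_offspring_freqs(f, mu)
}

#' F_IS of a genotype-frequency triple
#'
#' `Q_w = 1 - f_aA` (homozygosity), `Q_b = p^2 + q^2` with
#' `p = f_aa + f_aA/2`; `F_IS = (Q_w - Q_b)/(1 - Q_b)`, `NA` when an
#' allele is fixed (`Q_b = 1`).
#'
#' @param f genotype frequencies `c(f_aa, f_aA, f_AA)`.
#' @return F_IS, or `NA` if undefined.
#' @export
fis_of_freqs <- function(f) {
  f <- check_freqs(f)
  p <- f[1] + f[2] / 2
  qb <- p^2 + (1 - p)^2
  if (qb >= 1) return(NA_real_)
  ((1 - f[2]) - qb) / (1 - qb)
}

#' Deterministic infinite-population recursion
#'
#' Iterates the expected-frequency map (the `c`-mixture of the clonal and
#' sexual maps) without multinomial sampling, i.e. the infinite-population
#' limit of the chain. For any `mu > 0` the unique fixed point is
#' `(1/4, 1/2, 1/4)` with `F_IS = 0`: reciprocal mutation drives allele
#' frequencies to 1/2 and, in the limit of no drift, heterozygosity to
#' its Hardy-Weinberg value even under full asexuality.
#'
#' @param f0 initial genotype frequencies `c(f_aa, f_aA, f_AA)`.
#' @param c rate of asexuality.
#' @param mu mutation rate.
#' @param n_generations number of iterations (the trajectory is recorded
#'   at every generation, including generation 0).
#' @param tol convergence tolerance on the max-norm change per
#'   generation; iteration may stop early once reached.
#' @param max_iter iteration cap for the fixed-point search when
#'   `n_generations` is `NULL`.
#' @return A data frame with columns `generation`, `f_aa`, `f_aA`,
#'   `f_AA`, `fis`, with attributes `converged` (logical), `fixed_point`
#'   (last iterate) and `tol`.
#' @examples
#' tr <- iterate_infinite_population(c(1, 0, 0), c = 1, mu = 0.01,
#'                                   n_generations = 2000)
#' tail(tr, 1)
#' @export
iterate_infinite_population <- function(f0, c, mu, n_generations = NULL,
                                        tol = 1e-12, max_iter = 1e6) {
  f <- check_freqs(f0)
  c <- check_rate(c, "c")
  mu <- check_rate(mu, "mu", max = 0.5)
  fixed_horizon <- !is.null(n_generations)
  cap <- if (fixed_horizon) n_generations else max_iter
  record <- fixed_horizon && cap <= 1e5
  traj <- if (record) matrix(NA_real_, cap + 1, 3) else NULL
  if (record) traj[1, ] <- f
  converged <- FALSE
  n_done <- 0
  for (i in seq_len(cap)) {
    f_new <- c * asexual_offspring_freqs(f, mu) +
      (1 - c) * sexual_offspring_freqs(f, mu)
    delta <- max(abs(f_new - f))
    f <- f_new
    n_done <- i
    if (record) traj[i + 1, ] <- f
    if (delta < tol) {
      converged <- TRUE
      if (!fixed_horizon) break
    }
  }
  if (fixed_horizon && cap == 0) converged <- NA
  if (record) {
    traj <- traj[seq_len(n_done + 1), , drop = FALSE]
  } else {
    traj <- matrix(f, 1)
  }
  fis <- apply(traj, 1, fis_of_freqs)
  out <- data.frame(
    generation = if (record) 0:n_done else n_done,
    f_aa = traj[, 1], f_aA = traj[, 2], f_AA = traj[, 3], fis = fis)
  attr(out, "converged") <- converged
  attr(out, "fixed_point") <- f
  attr(out, "tol") <- tol
  out
}

#' Write a deterministic trajectory as CSV
#'
#' @param trajectory output of [iterate_infinite_population()].
#' @param file path to write.
#' @return the file path, invisibly.
#' @export
write_trajectory <- function(trajectory, file) {
  utils::write.csv(trajectory, file, row.names = FALSE, na = "")
  invisible(file)
}
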