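#' Forward Monte-Carlo simulation of the generative process
#'
#' Independent simulator of the same reproduction model, sampling each
#' offspring's lineage explicitly: with probability `c` it copies the
#' full diploid genotype of one uniformly chosen parent, otherwise it
#' unites two gametes (each a uniformly chosen allele of a uniformly
#' chosen parent, with replacement); every transmitted allele mutates
#' independently with probability `mu`. This path never touches the
#' mixture/multinomial algebra of the exact transition law, so its
#' occupancy frequencies are a genuine cross-check of the exact chain.
#'
#' @param N population size.
#' @param c rate of asexuality in `[0, 1]`.
#' @param mu reciprocal mutation rate in `[0, 0.5]`.
#' @param initial starting genotypic state `c(n_aa, n_aA, n_AA)`.
#' @param n_generations total generations to simulate.
#' @param burn_in generations discarded before counting occupancy
#'   (default `n_generations %/% 10`; a heuristic — the true mixing time
#'   scales like `1/mu` and must be judged per parameter set).
#' @param seed integer seed; recorded in the result. Identical seed and
#'   parameters give identical trajectories.
#' @param keep_trajectory if `TRUE`, return the full per-generation state
#'   trajectory.
#' @param thin count occupancy only every `thin`-th post-burn-in
#'   generation (default 1). Thinning makes the retained samples nearly
#'   independent, so binomial standard errors of occupancy frequencies
#'   are approximately valid.
#' @return list of class `simulation_run`: `params`, `seed`, `occupancy`
#'   (data frame `n_aa, n_aA, n_AA, frequency, visits` over visited
#'   states), `n_samples`, and optionally `trajectory` (matrix, one row
#'   per generation).
#' @examples
#' run <- simulate_population(5, c = 0.5, mu = 0.05, initial = c(5, 0, 0),
#'                            n_generations = 1000, seed = 1)
#' head(run$occupancy)
#' @export
simulate_population <- function(N, c, mu, initial, n_generations,
                                burn_in = n_generations %/% 10,
                                seed = NULL, keep_trajectory = FALSE,
                                thin = 1) {
  N <- check_N(N)
  c <- check_rate(c, "c")
  mu <- check_rate(mu, "mu", max = 0.5)
  initial <- check_state(initial, N)
  stopifnot(n_generations > burn_in, burn_in >= 0, thin >= 1)
  if (!is.null(seed)) set.seed(seed)
  states <- simulate_chain_cpp(N, c, mu, initial, as.integer(n_generations))
  kept <- seq(from = burn_in + 2, to = n_generations + 1, by = thin)
  sp <- state_space(N)
  k <- N - states[kept, 1]
  idx <- k * (k + 1) / 2 + (N - states[kept, 1] - states[kept, 2]) + 1
  visits <- tabulate(idx, nbins = nrow(sp$states))
  occ <- data.frame(sp$states,
                    frequency = visits / length(kept),
                    visits = visits)
  out <- list(params = list(N = N, c = c, mu = mu),
              seed = seed, n_generations = n_generations,
              burn_in = burn_in, thin = thin,
              n_samples = length(kept), occupancy = occ)
  if (keep_trajectory) out$trajectory <- states
  class(out) <- "simulation_run"
  out
}

#' @export
print.simulation_run <- function(x, ...) {
  cat(sprintf(
    "Simulation: N = %d, c = %g, mu = %g, %d generations (burn-in %d, thin %d)\n",
    x$params$N, x$params$c, x$params$mu,
    x$n_generations, x$burn_in, x$thin))
  cat(sprintf("  %d occupancy samples over %d visited states\n",
              x$n_samples, sum(x$occupancy$visits > 0)))
  invisible(x)
}

#' Write a simulated trajectory or occupancy table as CSV
#'
#' @param run a [simulate_population()] result.
#' @param file path to write.
#' @param what `"occupancy"` (default) or `"trajectory"` (requires
#'   `keep_trajectory = TRUE` at simulation time).
#' @return the file path, invisibly.
#' @export
write_simulation <- function(run, file, what = c("occupancy", "trajectory")) {
  what <- match.arg(what)
  stopifnot(inherits(run, "simulation_run"))
  if (what == "occupancy") {
    utils::write.csv(run$occupancy, file, row.names = FALSE)
  } else {
    if (is.null(run$trajectory)) {
      stop("run was simulated without `keep_trajectory = TRUE`",
           call. = FALSE)
    }
    df <- data.frame(generation = seq_len(nrow(run$trajectory)) - 1L,
                     run$trajectory)
    names(df)[2:4] <- c("n_aa", "n_aA", "n_AA")
    utils::write.csv(df, file, row.names = FALSE)
  }
  invisible(file)
}
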