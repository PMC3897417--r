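# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own computational paths.

# All genotypic states by triple loop.
brute_states <- function(N) {
  out <- list()
  for (i in 0:N) for (j in 0:(N - i)) {
    out[[length(out) + 1]] <- c(i, j, N - i - j)
  }
  do.call(rbind, out)
}

# Expected clonal offspring genotype distribution by enumerating the four
# mutation outcomes of the parent's two alleles (allele 1 = a).
brute_asexual <- function(f, mu) {
  geno_alleles <- list(c(1, 1), c(1, 0), c(0, 0)) # aa, aA, AA as a-indicators
  out <- c(0, 0, 0)
  for (g in 1:3) {
    al <- geno_alleles[[g]]
    for (m1 in 0:1) for (m2 in 0:1) {      # mutate allele 1 / allele 2?
      pr <- f[g] * mu^(m1 + m2) * (1 - mu)^(2 - m1 - m2)
      a1 <- if (m1) 1 - al[1] else al[1]
      a2 <- if (m2) 1 - al[2] else al[2]
      k <- a1 + a2                          # copies of allele a
      out[3 - k + 1] <- out[3 - k + 1] + pr # hmm: map below instead
    }
  }
  out
}

# One multinomial transition row by exhaustive enumeration of all 3^N
# offspring genotype assignments (tiny N only).
brute_transition_row <- function(source, N, c, mu, states) {
  f <- partialFIS::offspring_freqs(source, N, c, mu)
  S <- nrow(states)
  row <- numeric(S)
  grid <- as.matrix(expand.grid(rep(list(1:3), N)))
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    counts <- tabulate(g, nbins = 3)
    pr <- prod(f[g])
    idx <- which(states[, 1] == counts[1] & states[, 2] == counts[2])
    row[idx] <- row[idx] + pr
  }
  row
}

# Moments by raw-moment accumulation (independent of fis_moments's
# central-moment path).
brute_moments <- function(values, weights) {
  w <- weights / sum(weights)
  m1 <- sum(w * values)
  m2r <- sum(w * values^2)
  m3r <- sum(w * values^3)
  m4r <- sum(w * values^4)
  v <- m2r - m1^2
  m3 <- m3r - 3 * m1 * m2r + 2 * m1^3
  m4 <- m4r - 4 * m1 * m3r + 6 * m1^2 * m2r - 3 * m1^4
  list(mean = m1, variance = v,
       skewness = m3 / v^1.5, excess_kurtosis = m4 / v^2 - 3)
}

# Index of the allele-relabelled state (n_AA, n_aA, n_aa) for every state.
relabel_permutation <- function(space) {
  partialFIS::state_index(space, space$states[, 3:1])
}

# Attainable tolerance for allele symmetry of a solved stationary vector:
# the dense solve's ~1e-16 backward error is amplified by the inverse
# spectral gap of the chain, which closes like mu as mu -> 0.
stationary_symmetry_tol <- function(mu) max(1e-12, 2e-15 / mu)
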