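test_that("clonal map matches brute-force enumeration of mutation outcomes", {
  # enumerate the 2x2 mutate/keep outcomes of the parent's two alleles
  oracle <- function(f, mu) {
    out <- c(0, 0, 0)
    alleles <- list(c(0, 0), c(0, 1), c(1, 1))    # 0 = a, 1 = A
    for (g in 1:3) for (m1 in 0:1) for (m2 in 0:1) {
      pr <- f[g] * mu^(m1 + m2) * (1 - mu)^(2 - m1 - m2)
      a1 <- xor(alleles[[g]][1], m1)
      a2 <- xor(alleles[[g]][2], m2)
      out[a1 + a2 + 1] <- out[a1 + a2 + 1] + pr   # index by # of A alleles
    }
    out
  }
  set.seed(42)
  for (rep in 1:25) {
    f <- as.numeric(rmultinom(1, 50, c(1, 1, 1))) / 50
    mu <- runif(1, 0, 0.5)
    expect_equal(asexual_offspring_freqs(f, mu), oracle(f, mu),
                 tolerance = 1e-14)
  }
  expect_equal(asexual_offspring_freqs(c(1, 0, 0), 0.1),
               c(0.81, 0.18, 0.01))
})

test_that("mu = 0 is the identity for the clonal map", {
  set.seed(7)
  for (rep in 1:10) {
    f <- as.numeric(rmultinom(1, 30, c(2, 1, 3))) / 30
    expect_equal(asexual_offspring_freqs(f, 0), f)
  }
})

test_that("sexual map gives Hardy-Weinberg proportions of the mutated pool", {
  expect_equal(sexual_offspring_freqs(c(1, 0, 0), 0), c(1, 0, 0))
  expect_equal(sexual_offspring_freqs(c(1, 0, 0), 0.1),
               c(0.81, 0.18, 0.01))              # p' = 0.9
  # p = 0.5 is a fixed point for any mu
  for (mu in c(0, 0.01, 0.3, 0.5)) {
    expect_equal(sexual_offspring_freqs(c(0.25, 0.5, 0.25), mu),
                 c(0.25, 0.5, 0.25))
    expect_equal(sexual_offspring_freqs(c(0.5, 0, 0.5), mu),
                 c(0.25, 0.5, 0.25))
  }
})

test_that("(1/4, 1/2, 1/4) is a fixed point of both maps for every mu", {
  hw <- c(0.25, 0.5, 0.25)
  for (mu in c(0, 1e-8, 1e-3, 0.2, 0.5)) {
    expect_equal(asexual_offspring_freqs(hw, mu), hw)
    expect_equal(sexual_offspring_freqs(hw, mu), hw)
  }
})

test_that("c-mixture interpolates the two maps", {
  st <- c(10, 0, 0); N <- 10; mu <- 0.1
  f <- st / N
  expect_equal(offspring_freqs(st, N, c = 1, mu),
               asexual_offspring_freqs(f, mu))
  expect_equal(offspring_freqs(st, N, c = 0, mu),
               sexual_offspring_freqs(f, mu))
  expect_equal(offspring_freqs(st, N, c = 0.5, mu),
               (asexual_offspring_freqs(f, mu) +
                  sexual_offspring_freqs(f, mu)) / 2)
})

test_that("all maps preserve the simplex and allele-relabel equivariance", {
  set.seed(11)
  n <- 2000
  f <- matrix(rexp(3 * n), n, 3)
  f <- f / rowSums(f)
  for (mu in c(0, 0.07, 0.5)) {
    for (map in list(asexual_offspring_freqs, sexual_offspring_freqs)) {
      out <- map(f, mu)
      expect_true(all(out >= 0))
      expect_lt(max(abs(rowSums(out) - 1)), 1e-12)
      # swapping a <-> A in the input swaps f_aa <-> f_AA in the output
      swapped <- map(f[, 3:1], mu)
      expect_equal(swapped, out[, 3:1], tolerance = 1e-14)
    }
  }
})

test_that("mutation rates outside [0, 0.5] are rejected", {
  expect_error(asexual_offspring_freqs(c(1, 0, 0), 0.6), "mu")
  expect_error(sexual_offspring_freqs(c(1, 0, 0), -0.1), "mu")
  expect_error(offspring_freqs(c(1, 0, 0), 1, c = 1.2, mu = 0.1), "c")
})

test_that("infinite-population recursion converges to (1/4, 1/2, 1/4)", {
  # unique fixed point with F_IS -> 0 for mu > 0, over a (c, mu) grid
  for (c in c(0, 0.5, 0.9, 1)) for (mu in c(1e-3, 1e-2, 0.1)) {
    tr <- iterate_infinite_population(c(1, 0, 0), c, mu, tol = 1e-13)
    fp <- attr(tr, "fixed_point")
    expect_true(attr(tr, "converged"))
    expect_equal(fp, c(0.25, 0.5, 0.25), tolerance = 1e-6)
    expect_equal(tail(tr$fis, 1), 0, tolerance = 1e-6)
  }
})

test_that("degenerate recursions behave as expected", {
  # c = 1, mu = 0: identity map
  f0 <- c(0.2, 0.5, 0.3)
  tr <- iterate_infinite_population(f0, c = 1, mu = 0, n_generations = 5)
  expect_equal(nrow(tr), 6)
  for (i in 1:6) expect_equal(unlist(tr[i, 2:4], use.names = FALSE), f0)
  # c = 0, mu = 0: Hardy-Weinberg proportions after one step, F_IS = 0 on
  p <- f0[1] + f0[2] / 2
  tr2 <- iterate_infinite_population(f0, c = 0, mu = 0, n_generations = 3)
  expect_equal(unlist(tr2[2, 2:4], use.names = FALSE),
               c(p^2, 2 * p * (1 - p), (1 - p)^2))
  expect_equal(tr2$fis[-1], rep(0, 3), tolerance = 1e-12)
})

test_that("trajectory CSV round-trips", {
  tr <- iterate_infinite_population(c(1, 0, 0), 0.5, 0.01,
                                    n_generations = 10)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- read.csv(f)
  expect_equal(back$f_aA, tr$f_aA, tolerance = 1e-12)
})
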