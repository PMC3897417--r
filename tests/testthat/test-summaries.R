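# A small stationary case reused across summary tests.
summary_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- state_space(20)
      tm <- transition_matrix(sp, c = 0.5, mu = 0.01)
      st <- stationary_distribution(tm)
      cache <<- list(sp = sp, tm = tm, st = st)
    }
    cache
  }
})

test_that("sign probabilities are conditional on non-fixation and sum to 1", {
  fx <- summary_fixture()
  pr <- sign_probabilities(fx$st, fx$sp)
  expect_equal(pr$p_negative + pr$p_nonnegative, 1, tolerance = 1e-12)
  expect_gte(pr$p_fixation, 0)
  expect_lte(pr$p_fixation, 1)
  # independent direct computation
  keep <- !fx$sp$is_fixed
  expect_equal(pr$p_negative,
               sum(fx$st$pi[fx$sp$fis < 0 & keep]) / sum(fx$st$pi[keep]),
               tolerance = 1e-14)
})

test_that("point mass on the all-heterozygote state gives p_negative = 1", {
  sp <- state_space(8)
  pi <- numeric(nrow(sp$states))
  pi[state_index(sp, c(0, 8, 0))] <- 1
  pr <- sign_probabilities(pi, sp)
  expect_equal(pr$p_negative, 1)
  expect_equal(pr$p_fixation, 0)
})

test_that("all mass on fixation states is rejected as undefined", {
  sp <- state_space(5)
  pi <- numeric(nrow(sp$states))
  pi[state_index(sp, c(5, 0, 0))] <- 1
  expect_error(sign_probabilities(pi, sp), "undefined")
})

test_that("discrete distributions aggregate exact rational values", {
  fx <- summary_fixture()
  for (w in c("fis", "qw", "qb")) {
    d <- statistic_distribution(fx$st, fx$sp, w)
    expect_equal(sum(d$probability), 1, tolerance = 1e-12)
    expect_false(is.unsorted(d$value))
    expect_equal(d$value, d$numerator / d$denominator)
    expect_false(any(duplicated(paste(d$numerator, d$denominator))))
  }
  # F_IS = 1 is shared by all (k, 0, N-k) polymorphic states: the support
  # holds it once, with their aggregated mass
  d <- statistic_distribution(fx$st, fx$sp, "fis")
  sp <- fx$sp
  ones <- sp$states[, 2] == 0 & !sp$is_fixed
  expect_equal(sum(d$value == 1), 1)
  expect_equal(d$probability[d$value == 1],
               sum(fx$st$pi[ones]) / sum(fx$st$pi[!sp$is_fixed]),
               tolerance = 1e-12)
  # Q_w support is k/N over all states: N+1 distinct values
  dqw <- statistic_distribution(fx$st, fx$sp, "qw")
  expect_equal(nrow(dqw), fx$sp$N + 1)
})

test_that("moments match analytic values and a brute-force path", {
  sp <- state_space(10)
  # half the mass on F_IS = -1 (all heterozygotes), half on F_IS = +1
  pi <- numeric(nrow(sp$states))
  pi[state_index(sp, c(0, 10, 0))] <- 0.5
  pi[state_index(sp, c(5, 0, 5))] <- 0.5
  m <- fis_moments(pi, sp)
  expect_equal(m$mean, 0)
  expect_equal(m$variance, 1)
  expect_equal(m$skewness, 0)
  expect_equal(m$excess_kurtosis, -2)

  # point mass: zero variance, undefined shape moments
  pi2 <- numeric(nrow(sp$states))
  pi2[state_index(sp, c(0, 10, 0))] <- 1
  m2 <- fis_moments(pi2, sp)
  expect_equal(m2$variance, 0)
  expect_true(is.na(m2$skewness))

  # real stationary case against the independent raw-moment oracle
  fx <- summary_fixture()
  m3 <- fis_moments(fx$st, fx$sp)
  keep <- !fx$sp$is_fixed
  bf <- brute_moments(fx$sp$fis[keep], fx$st$pi[keep])
  expect_equal(m3$mean, bf$mean, tolerance = 1e-12)
  expect_equal(m3$variance, bf$variance, tolerance = 1e-10)
  expect_equal(m3$skewness, bf$skewness, tolerance = 1e-8)
  expect_equal(m3$excess_kurtosis, bf$excess_kurtosis, tolerance = 1e-8)
  # moment inequality
  expect_gte(m3$excess_kurtosis, m3$skewness^2 - 2)
})

test_that("ranks are ordinal with canonical-order tie fallback", {
  fx <- summary_fixture()
  r <- rank_states(fx$st)
  expect_setequal(r, seq_along(fx$st$pi))
  expect_equal(which(r == 1), which.max(fx$st$pi))
  # uniform distribution: all tied, fallback is canonical order
  S <- nrow(fx$sp$states)
  ru <- rank_states(rep(1 / S, S))
  expect_identical(as.integer(ru), seq_len(S))
  expect_equal(attr(ru, "n_tied"), S)
})

test_that("identical distributions compare as fully rank-identical", {
  fx <- summary_fixture()
  cmp <- compare_rankings(fx$st, fx$st)
  expect_equal(cmp$n_identical, length(fx$st$pi))
  expect_equal(cmp$n_changed, 0)
  expect_equal(cmp$n_identical + cmp$n_changed, nrow(fx$sp$states))
})

test_that("sign flux partitions all states with uniform source weight", {
  sp <- state_space(20)
  neg_share <- mean(sp$sign == "negative")
  for (pars in list(c(0, 1e-8), c(0.5, 1e-3), c(1, 1e-3))) {
    tm <- transition_matrix(sp, c = pars[1], mu = pars[2])
    fx <- sign_flux_summary(tm, sp)
    expect_equal(sum(fx), 1, tolerance = 1e-9)
    # negative-source row total is a structural constant, c- and
    # mu-independent: the class share of the state space
    expect_equal(sum(fx["negative", ]), neg_share, tolerance = 1e-12)
    # independent double-loop computation
    neg <- sp$sign == "negative"
    expect_equal(fx["negative", "negative"],
                 sum(tm$P[neg, neg]) / nrow(sp$states), tolerance = 1e-13)
    expect_equal(fx["nonnegative", "negative"],
                 sum(tm$P[!neg, neg]) / nrow(sp$states), tolerance = 1e-13)
  }
})

test_that("summary CSV writers emit the documented schemas", {
  fx <- summary_fixture()
  f <- withr::local_tempfile(fileext = ".csv")
  write_summary(statistic_distribution(fx$st, fx$sp, "fis"), f)
  expect_named(read.csv(f),
               c("value", "numerator", "denominator", "probability"))
  write_summary(sign_flux_summary(fx$tm, fx$sp), f)
  df <- read.csv(f)
  expect_named(df, c("source", "target", "probability"))
  expect_equal(sum(df$probability), 1, tolerance = 1e-9)
  write_summary(sign_probabilities(fx$st, fx$sp), f)
  expect_named(read.csv(f), c("p_negative", "p_nonnegative", "p_fixation"))
})
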