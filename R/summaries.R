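#' Stationary sign and fixation probabilities of F_IS
#'
#' Fixation probability is the unconditional stationary mass of the two
#' allele-fixation states `(N,0,0)` and `(0,0,N)`. The negative /
#' nonnegative probabilities are CONDITIONAL on no allele fixation
#' (renormalised): at low mutation rates nearly all unconditional mass
#' sits on the fixation states, and the conditional probabilities are the
#' quantities of interest for polymorphic loci. The all-heterozygote
#' state `(0,N,0)` (`F_IS = -1`) belongs to the negative class.
#'
#' @param st a [stationary_distribution()] object.
#' @param space the matching [state_space()].
#' @return list of class `sign_probabilities` with `p_negative`,
#'   `p_nonnegative` (conditional, summing to 1) and `p_fixation`
#'   (unconditional).
#' @export
sign_probabilities <- function(st, space) {
  pi <- check_pi(st, space)
  p_fix <- sum(pi[space$is_fixed])
  denom <- 1 - p_fix
  if (denom <= 0) {
    stop("all stationary mass is on the fixation states; conditional sign
  probabilities are undefined", call. = FALSE)
  }
  p_neg <- sum(pi[space$sign == "negative"]) / denom
  structure(list(p_negative = p_neg, p_nonnegative = 1 - p_neg,
                 p_fixation = p_fix),
            class = "sign_probabilities")
}

#' @export
print.sign_probabilities <- function(x, ...) {
  cat(sprintf(paste0(
    "P(F_IS < 0 | no fixation)  = %.6f\n",
    "P(F_IS >= 0 | no fixation) = %.6f\n",
    "P(allele fixation)         = %.6f\n"),
    x$p_negative, x$p_nonnegative, x$p_fixation))
  invisible(x)
}

#' Discrete stationary distribution of F_IS, Q_w or Q_b
#'
#' Aggregates stationary mass over states sharing the same exact value of
#' the statistic. Values are matched as exact reduced rationals
#' (numerator, denominator), not floats, so states whose statistics agree
#' mathematically but differ in the last floating-point bit aggregate
#' correctly. For `"fis"` the two allele-fixation states (undefined F_IS)
#' are excluded and the distribution renormalised; `"qw"` and `"qb"`
#' distributions are over all states.
#'
#' @param st a [stationary_distribution()] object.
#' @param space the matching [state_space()].
#' @param which one of `"fis"`, `"qw"`, `"qb"`.
#' @return data frame of class `discrete_distribution` with columns
#'   `value`, `numerator`, `denominator`, `probability`, sorted by value;
#'   probabilities sum to 1 over the conditioning set.
#' @export
statistic_distribution <- function(st, space, which = c("fis", "qw", "qb")) {
  which <- match.arg(which)
  pi <- check_pi(st, space)
  N <- space$N
  s <- space$states
  if (which == "fis") {
    keep <- !space$is_fixed
    pi <- pi[keep] / sum(pi[keep])
    s <- s[keep, , drop = FALSE]
    b <- (2 * s[, 1] + s[, 2])^2 + (2 * s[, 3] + s[, 2])^2
    num <- 4 * N * (s[, 1] + s[, 3]) - b
    den <- 4 * N^2 - b
  } else if (which == "qw") {
    num <- s[, 1] + s[, 3]
    den <- rep.int(N, nrow(s))
  } else {
    num <- (2 * s[, 1] + s[, 2])^2 + (2 * s[, 3] + s[, 2])^2
    den <- rep.int(4 * N^2, nrow(s))
  }
  g <- mapply(gcd_int, abs(num), den)
  g[g == 0] <- 1
  num <- num / g; den <- den / g
  key <- paste(num, den, sep = "/")
  agg <- rowsum(pi, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- data.frame(value = num[first] / den[first],
                    numerator = num[first], denominator = den[first],
                    probability = agg[match(key[first], rownames(agg)), 1])
  out <- out[order(out$value), ]
  rownames(out) <- NULL
  attr(out, "statistic") <- which
  class(out) <- c("discrete_distribution", "data.frame")
  out
}

#' Four moments of the stationary F_IS distribution
#'
#' Mean, variance, classical skewness `g1 = m3 / m2^(3/2)` and classical
#' excess kurtosis `m4 / m2^2 - 3` (Gaussian reference 0) of F_IS under
#' the stationary distribution conditioned on no allele fixation (the two
#' fixation states, where F_IS is undefined, are excluded and the
#' distribution renormalised; the all-heterozygote state is retained with
#' `F_IS = -1`).
#'
#' @param st a [stationary_distribution()] object.
#' @param space the matching [state_space()].
#' @return list of class `moments_summary` with `mean`, `variance`,
#'   `skewness`, `excess_kurtosis` (the last two `NA` when the variance
#'   is 0).
#' @export
fis_moments <- function(st, space) {
  pi <- check_pi(st, space)
  keep <- !space$is_fixed
  w <- pi[keep] / sum(pi[keep])
  x <- space$fis[keep]
  m <- sum(w * x)
  m2 <- sum(w * (x - m)^2)
  if (m2 > 0) {
    m3 <- sum(w * (x - m)^3)
    m4 <- sum(w * (x - m)^4)
    skew <- m3 / m2^1.5
    exk <- m4 / m2^2 - 3
  } else {
    skew <- NA_real_; exk <- NA_real_
  }
  structure(list(mean = m, variance = m2, skewness = skew,
                 excess_kurtosis = exk),
            class = "moments_summary")
}

#' @export
print.moments_summary <- function(x, ...) {
  cat(sprintf(
    "F_IS moments | no fixation: mean %.6g, var %.6g, skew %.6g, ex.kurt %.6g\n",
    x$mean, x$variance, x$skewness, x$excess_kurtosis))
  invisible(x)
}

#' Ordinal ranks of genotypic states by stationary probability
#'
#' Rank 1 is the most probable state. Stationary probabilities are
#' generically distinct; exact floating-point ties are broken by
#' canonical state order and reported via the `n_tied` attribute (a
#' diagnostic, since no principled tie rule exists).
#'
#' @param st a [stationary_distribution()] object (or a bare probability
#'   vector).
#' @return integer vector of ranks in canonical state order, with
#'   attribute `n_tied` = number of states involved in exact ties.
#' @export
rank_states <- function(st) {
  pi <- if (inherits(st, "stationary_distribution")) st$pi else as.numeric(st)
  r <- integer(length(pi))
  r[order(-pi, seq_along(pi))] <- seq_along(pi)
  tied <- sum(duplicated(pi) | duplicated(pi, fromLast = TRUE))
  attr(r, "n_tied") <- tied
  r
}

#' Compare state rankings under two stationary distributions
#'
#' @param st_a,st_b [stationary_distribution()] objects over the same
#'   state space.
#' @return list of class `rank_comparison` with `ranks_a`, `ranks_b`,
#'   `n_identical`, `n_changed`, and `n_tied` (total states in exact
#'   probability ties in either distribution, a diagnostic for rank
#'   stability).
#' @export
compare_rankings <- function(st_a, st_b) {
  ra <- rank_states(st_a)
  rb <- rank_states(st_b)
  if (length(ra) != length(rb)) {
    stop("the two distributions live on different state spaces",
         call. = FALSE)
  }
  structure(list(ranks_a = ra, ranks_b = rb,
                 n_identical = sum(ra == rb),
                 n_changed = sum(ra != rb),
                 n_tied = attr(ra, "n_tied") + attr(rb, "n_tied")),
            class = "rank_comparison")
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat(sprintf(
    "Rank comparison over %d states: %d identical, %d changed (%d tied)\n",
    length(x$ranks_a), x$n_identical, x$n_changed, x$n_tied))
  invisible(x)
}

#' One-generation sign-transition flux table
#'
#' Average probability of moving between F_IS sign classes in one
#' generation: every state is given uniform source weight `1/S`
#' (the stationary distribution is NOT involved), the two sign classes
#' partition ALL states (allele-fixation states in the nonnegative
#' class), and `flux[X, Y]` is the summed transition mass from class `X`
#' into class `Y` divided by `S`. Consequently the four cells sum to 1
#' and each source row's total equals that class's share of the state
#' space — a structural constant independent of `c` and `mu`.
#'
#' @param tm a [transition_matrix()] object.
#' @param space the matching [state_space()].
#' @return 2 x 2 matrix with dimnames `source`/`target` in
#'   `{negative, nonnegative}`, of class `sign_flux`.
#' @export
sign_flux_summary <- function(tm, space) {
  stopifnot(inherits(tm, "transition_matrix"),
            inherits(space, "state_space"),
            nrow(tm$P) == nrow(space$states))
  S <- nrow(tm$P)
  neg <- space$sign == "negative"
  # mass into the negative target class, per source state (one matvec)
  into_neg <- as.numeric(tm$P %*% ifelse(neg, 1, 0))
  flux <- matrix(NA_real_, 2, 2,
                 dimnames = list(source = c("negative", "nonnegative"),
                                 target = c("negative", "nonnegative")))
  flux["negative", "negative"] <- sum(into_neg[neg]) / S
  flux["negative", "nonnegative"] <- sum(1 - into_neg[neg]) / S
  flux["nonnegative", "negative"] <- sum(into_neg[!neg]) / S
  flux["nonnegative", "nonnegative"] <- sum(1 - into_neg[!neg]) / S
  class(flux) <- c("sign_flux", "matrix", "array")
  flux
}

#' @export
print.sign_flux <- function(x, ...) {
  cat("Uniform-source one-generation F_IS sign flux (cells sum to 1):\n")
  print(unclass(x), digits = 6)
  invisible(x)
}

check_pi <- function(st, space) {
  stopifnot(inherits(space, "state_space"))
  pi <- if (inherits(st, "stationary_distribution")) st$pi else as.numeric(st)
  if (length(pi) != nrow(space$states)) {
    stop("distribution and state space sizes differ", call. = FALSE)
  }
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-9) {
    stop("`st` must be a probability vector over the state space",
         call. = FALSE)
  }
  pi
}

#' Write a discrete distribution, moments summary or sign-flux table
#'
#' CSV mirrors of the summary objects, one row per support point / cell.
#'
#' @param x a `discrete_distribution`, `moments_summary` or `sign_flux`
#'   object.
#' @param file path to write.
#' @return the file path, invisibly.
#' @export
write_summary <- function(x, file) {
  if (inherits(x, "discrete_distribution")) {
    utils::write.csv(as.data.frame(x), file, row.names = FALSE)
  } else if (inherits(x, "moments_summary")) {
    utils::write.csv(as.data.frame(unclass(x)), file, row.names = FALSE)
  } else if (inherits(x, "sign_flux")) {
    df <- as.data.frame(as.table(unclass(x)))
    names(df) <- c("source", "target", "probability")
    utils::write.csv(df, file, row.names = FALSE)
  } else if (inherits(x, "sign_probabilities")) {
    utils::write.csv(as.data.frame(unclass(x)), file, row.names = FALSE)
  } else {
    stop("unsupported summary object", call. = FALSE)
  }
  invisible(file)
}
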