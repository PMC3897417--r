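#' Enumerate all genotypic states of a population
#'
#' A genotypic state is a distribution `(n_aa, n_aA, n_AA)` of the `N`
#' diploid individuals of a population over the three genotypes at a
#' biallelic locus. There are `(N+1)(N+2)/2` such states. The canonical
#' order is `n_aa` descending, then `n_aA` descending, so the first state
#' is `(N, 0, 0)` and the last is `(0, 0, N)`; the order is fixed and all
#' outputs carry explicit count labels so it never leaks into results.
#'
#' Per-state identity statistics are computed at enumeration time:
#' \itemize{
#'   \item `qw = (n_aa + n_AA) / N`, the probability that the two
#'     homologous alleles of one individual are identical (observed
#'     homozygosity);
#'   \item `qb = p^2 + q^2` with `p = (2 n_aa + n_aA) / (2N)`, the
#'     probability that two alleles drawn with replacement from the
#'     population allele pool are identical;
#'   \item `fis = (qw - qb) / (1 - qb)`, undefined (`NA`) at the two
#'     allele-fixation states `(N,0,0)` and `(0,0,N)` where `qb = 1`.
#' }
#'
#' @param N population size (number of diploid individuals), a single
#'   positive integer.
#'
#' @return An object of class `state_space`: a list with elements
#'   \describe{
#'     \item{N}{population size.}
#'     \item{states}{integer matrix with `S = (N+1)(N+2)/2` rows and
#'       columns `n_aa`, `n_aA`, `n_AA`.}
#'     \item{qw, qb, fis}{numeric vectors of per-state statistics
#'       (`fis` is `NA` at the fixation states).}
#'     \item{sign}{character vector, `"negative"` where `fis < 0`,
#'       `"nonnegative"` otherwise; the fixation states are classed
#'       nonnegative by convention so that the sign classes partition the
#'       state space.}
#'     \item{is_fixed}{logical vector flagging `(N,0,0)` and `(0,0,N)`.}
#'   }
#'
#' @examples
#' sp <- state_space(2)
#' sp$states
#' sp$fis
#' @export
state_space <- function(N) {
  N <- check_N(N)
  # block k (k = N..0) holds states with n_aa = k, n_aA = (N-k)..0
  n_aa <- rep.int(N:0, times = 1:(N + 1))
  n_aA <- sequence(1:(N + 1), from = N - (N:0), by = -1L)
  n_AA <- N - n_aa - n_aA
  states <- cbind(n_aa = n_aa, n_aA = n_aA, n_AA = n_AA)
  storage.mode(states) <- "integer"

  qw <- (n_aa + n_AA) / N
  x <- 2 * n_aa + n_aA                    # copies of allele a among 2N
  qb <- (x^2 + (2 * N - x)^2) / (4 * N^2)
  fis <- ifelse(qb < 1, (qw - qb) / (1 - qb), NA_real_)
  is_fixed <- qb == 1
  sign <- ifelse(!is.na(fis) & fis < 0, "negative", "nonnegative")

  structure(
    list(N = N, states = states, qw = qw, qb = qb, fis = fis,
         sign = sign, is_fixed = is_fixed),
    class = "state_space"
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf(
    "Genotypic state space: N = %d diploid individuals, %d states\n",
    x$N, nrow(x$states)))
  cat(sprintf("  negative F_IS states: %d; fixation states: 2\n",
              sum(x$sign == "negative")))
  invisible(x)
}

#' Position of a genotypic state in the canonical order
#'
#' @param space a [state_space()] object.
#' @param state integer vector `c(n_aa, n_aA, n_AA)` (or a matrix with one
#'   state per row).
#' @return integer index (or vector of indices) into `space$states`.
#' @examples
#' sp <- state_space(10)
#' state_index(sp, c(10, 0, 0))
#' @export
state_index <- function(space, state) {
  stopifnot(inherits(space, "state_space"))
  if (is.matrix(state)) {
    return(vapply(seq_len(nrow(state)),
                  function(i) state_index(space, state[i, ]), integer(1)))
  }
  state <- check_state(state, space$N)
  N <- space$N
  k <- N - state[1]                       # states with larger n_aa first
  idx <- k * (k + 1) / 2 + (N - state[1] - state[2]) + 1L
  as.integer(idx)
}

#' Identity statistics and F_IS of a single genotypic state
#'
#' Computes Q_w, Q_b and the inbreeding coefficient
#' `F_IS = (Q_w - Q_b)/(1 - Q_b)` for one state, plus its sign class.
#' Exact rationals are carried alongside the floating-point values:
#' `F_IS = (4*N*(n_aa + n_AA) - b) / (4*N^2 - b)` with
#' `b = x^2 + (2N - x)^2`, `x = 2*n_aa + n_aA`, reduced to lowest terms.
#'
#' @param state integer vector `c(n_aa, n_aA, n_AA)`.
#' @param N population size.
#' @return A list of class `state_statistics` with elements `qw`, `qb`,
#'   `fis` (`NA` when undefined), `fis_num`, `fis_den` (reduced exact
#'   rational, `NA` when undefined), `sign_class`, `is_allele_fixed`,
#'   `is_polymorphic`.
#' @examples
#' state_statistics(c(116, 24, 0), 140)$fis  # -0.09375
#' @export
state_statistics <- function(state, N) {
  N <- check_N(N)
  state <- check_state(state, N)
  n_aa <- state[1]; n_aA <- state[2]; n_AA <- state[3]
  qw <- (n_aa + n_AA) / N
  x <- 2 * n_aa + n_aA
  b <- x^2 + (2 * N - x)^2
  qb <- b / (4 * N^2)
  fixed <- b == 4 * N^2
  if (fixed) {
    fis <- NA_real_; num <- NA_integer_; den <- NA_integer_
  } else {
    num <- 4 * N * (n_aa + n_AA) - b
    den <- 4 * N^2 - b
    g <- gcd_int(abs(num), den)
    if (g > 0) { num <- num / g; den <- den / g }
    fis <- num / den
  }
  structure(
    list(qw = qw, qb = qb, fis = fis, fis_num = num, fis_den = den,
         sign_class = if (!fixed && fis < 0) "negative" else "nonnegative",
         is_allele_fixed = fixed, is_polymorphic = !fixed),
    class = "state_statistics"
  )
}

#' Sign class of a state's F_IS
#'
#' `"negative"` iff F_IS is defined and strictly negative; states with
#' zero or positive F_IS and the two allele-fixation states (undefined
#' F_IS) are `"nonnegative"`, so the two classes partition the state
#' space.
#'
#' @param stats a `state_statistics` object.
#' @return `"negative"` or `"nonnegative"`.
#' @export
classify_sign <- function(stats) {
  stopifnot(inherits(stats, "state_statistics"))
  stats$sign_class
}

#' Write the per-state statistics table as CSV
#'
#' Columns: `n_aa,n_aA,n_AA,Qw,Qb,FIS,sign_class,is_allele_fixed`; `FIS`
#' is empty for the fixation states.
#'
#' @param space a [state_space()] object.
#' @param file path to write.
#' @return the file path, invisibly.
#' @export
write_state_table <- function(space, file) {
  stopifnot(inherits(space, "state_space"))
  df <- data.frame(space$states,
                   Qw = space$qw, Qb = space$qb, FIS = space$fis,
                   sign_class = space$sign,
                   is_allele_fixed = space$is_fixed)
  utils::write.csv(df, file, row.names = FALSE, na = "")
  invisible(file)
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}
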