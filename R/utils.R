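# Input validation shared across modules.

check_N <- function(N) {
  if (length(N) != 1 || !is.numeric(N) || is.na(N) ||
      N < 1 || N != round(N)) {
    stop("`N` must be a single positive integer", call. = FALSE)
  }
  as.integer(N)
}

check_state <- function(state, N) {
  if (length(state) != 3 || any(is.na(state)) ||
      any(state < 0) || any(state != round(state)) || sum(state) != N) {
    stop(sprintf(
      "`state` must be three nonnegative integer counts summing to N = %d",
      N), call. = FALSE)
  }
  as.integer(state)
}

check_rate <- function(x, name, max = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0 || x > max) {
    stop(sprintf("`%s` must be a single number in [0, %g]", name, max),
         call. = FALSE)
  }
  as.numeric(x)
}

check_freqs <- function(f) {
  if (length(f) != 3 || any(is.na(f)) || any(f < -1e-12) ||
      abs(sum(f) - 1) > 1e-9) {
    stop("`f` must be three nonnegative genotype frequencies summing to 1",
         call. = FALSE)
  }
  as.numeric(f)
}
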