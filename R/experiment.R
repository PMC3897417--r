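#' Define a reproducible experiment over a parameter grid
#'
#' An experiment evaluates the model on the full cross of `N`, `c` and
#' `mu` values and writes the requested summaries as CSV files plus a
#' JSON manifest. Outputs are deterministic: rerunning an identical
#' config rewrites byte-identical tables (the manifest timestamp aside).
#'
#' @param N integer vector of population sizes.
#' @param c numeric vector of asexuality rates.
#' @param mu numeric vector of mutation rates (must be `> 0`; the
#'   stationary distribution requires an ergodic chain).
#' @param outputs character vector from `c("stationary", "sign-probs",
#'   "distribution", "moments", "sign-flux", "ranks", "states")`.
#' @param out_dir output directory (created if missing).
#' @param digits decimal places in printed CSV numbers; `NA` writes full
#'   precision (default: full precision).
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(N, c, mu,
                              outputs = c("sign-probs", "moments"),
                              out_dir = "partialFIS-out", digits = NA) {
  if (length(N) < 1 || length(c) < 1 || length(mu) < 1) {
    stop("`N`, `c` and `mu` must each have at least one value",
         call. = FALSE)
  }
  N <- vapply(N, check_N, integer(1))
  c <- vapply(c, check_rate, numeric(1), name = "c")
  mu <- vapply(mu, check_rate, numeric(1), name = "mu", max = 0.5)
  known <- c("stationary", "sign-probs", "distribution", "moments",
             "sign-flux", "ranks", "states")
  bad <- setdiff(outputs, known)
  if (length(bad)) {
    stop("unknown outputs: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(mu == 0) && length(setdiff(outputs, "states"))) {
    stop("mu = 0 gives a non-ergodic chain; stationary summaries need mu > 0",
         call. = FALSE)
  }
  structure(list(N = N, c = c, mu = mu, outputs = outputs,
                 out_dir = out_dir, digits = digits),
            class = "experiment_config")
}

#' Read an experiment config from a flat key = value file
#'
#' Lines are `key = value`, with comma-separated lists; `#` starts a
#' comment. Recognised keys: `N`, `c`, `mu`, `outputs`, `out_dir`,
#' `digits`.
#'
#' @param file path to the config file.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) {
    stop("config lines must be `key = value`", call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  get <- function(k, default = NULL) {
    if (k %in% keys) strsplit(vals[match(k, keys)], ",[ ]*")[[1]] else default
  }
  experiment_config(
    N = as.integer(get("N", stop("config needs `N`", call. = FALSE))),
    c = as.numeric(get("c", stop("config needs `c`", call. = FALSE))),
    mu = as.numeric(get("mu", stop("config needs `mu`", call. = FALSE))),
    outputs = get("outputs", c("sign-probs", "moments")),
    out_dir = get("out_dir", "partialFIS-out")[1],
    digits = as.numeric(get("digits", NA))[1])
}

#' Run an experiment over the (N, c, mu) grid
#'
#' For each `N` the state space and, per `(c, mu)`, the transition matrix
#' are built once and reused across the requested summaries. Each output
#' becomes one CSV named by its parameters; a `manifest.json` records the
#' package version, grid, tolerances and file list.
#'
#' @param config an [experiment_config()].
#' @param verbose print progress to standard error.
#' @return (invisibly) character vector of files written.
#' @export
run_experiment <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  files <- character(0)
  fmt <- function(x) {
    if (is.na(config$digits)) x else round(x, config$digits)
  }
  tag <- function(N, c = NULL, mu = NULL) {
    s <- sprintf("N%d", N)
    if (!is.null(c)) s <- paste0(s, sprintf("_c%g", c))
    if (!is.null(mu)) s <- paste0(s, sprintf("_mu%g", mu))
    s
  }
  emit <- function(df, name) {
    path <- file.path(config$out_dir, paste0(name, ".csv"))
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], fmt)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    files <<- c(files, path)
    path
  }

  for (N in config$N) {
    sp <- state_space(N)
    if ("states" %in% config$outputs) {
      emit(data.frame(sp$states, Qw = sp$qw, Qb = sp$qb, FIS = sp$fis,
                      sign_class = sp$sign, is_allele_fixed = sp$is_fixed),
           paste0("states_", tag(N)))
    }
    for (mu in config$mu) for (c in config$c) {
      need_tm <- length(setdiff(config$outputs, "states")) > 0
      if (!need_tm) next
      say("building transition matrix %s ...", tag(N, c, mu))
      tm <- transition_matrix(sp, c = c, mu = mu)
      if ("sign-flux" %in% config$outputs) {
        fx <- sign_flux_summary(tm, sp)
        df <- as.data.frame(as.table(unclass(fx)))
        names(df) <- c("source", "target", "probability")
        emit(df, paste0("sign_flux_", tag(N, c, mu)))
      }
      need_pi <- length(setdiff(config$outputs,
                                c("states", "sign-flux"))) > 0
      if (need_pi) {
        say("solving stationary distribution %s ...", tag(N, c, mu))
        st <- stationary_distribution(tm)
        say("  residual %.2e", st$residual)
        rm(tm)
        if ("stationary" %in% config$outputs) {
          emit(data.frame(sp$states, probability = st$pi),
               paste0("stationary_", tag(N, c, mu)))
        }
        if ("sign-probs" %in% config$outputs) {
          pr <- sign_probabilities(st, sp)
          emit(as.data.frame(unclass(pr)),
               paste0("sign_probs_", tag(N, c, mu)))
        }
        if ("distribution" %in% config$outputs) {
          for (w in c("fis", "qw", "qb")) {
            emit(as.data.frame(statistic_distribution(st, sp, w)),
                 paste0("distribution_", w, "_", tag(N, c, mu)))
          }
        }
        if ("moments" %in% config$outputs) {
          emit(as.data.frame(unclass(fis_moments(st, sp))),
               paste0("moments_", tag(N, c, mu)))
        }
        if ("ranks" %in% config$outputs) {
          emit(data.frame(sp$states, probability = st$pi,
                          rank = rank_states(st)),
               paste0("ranks_", tag(N, c, mu)))
        }
      }
    }
  }
  manifest <- list(
    package = "partialFIS",
    version = as.character(utils::packageVersion("partialFIS")),
    created = format(Sys.time(), tz = "UTC"),
    grid = list(N = config$N, c = config$c, mu = config$mu),
    outputs = config$outputs,
    stationary_residual_tolerance = 1e-12,
    files = basename(files))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("wrote %d files to %s", length(files) + 1, config$out_dir)
  invisible(c(files, manifest_path))
}
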