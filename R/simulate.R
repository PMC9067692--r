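#' Run one simulation
#'
#' Initialises the population (one all-punisher group, `N - 1` all-defector
#' groups), seeds R's RNG with `seed`, and applies `par$periods` five-stage
#' periods in the compiled engine.  The whole trajectory is a deterministic
#' function of `(par, seed)`.
#'
#' @param par a [param_set()].
#' @param seed integer seed for this run (defaults to `par$seed`).
#' @param init optional initial `N x 4` count matrix overriding the
#'   canonical start state.
#' @return A `pgg_run` object: list with `params`, `seed`, `records` (a
#'   data frame with one row per period: `period`, `freq_defector`,
#'   `freq_contributor`, `freq_punisher`, `freq_nonparticipant`,
#'   `freq_cooperation`, all measured after the period's final stage) and
#'   `final_counts`.
#' @examples
#' par <- param_set(n = 20, scenario = "compulsory", periods = 50, burn_in = 25)
#' run <- run_simulation(par, seed = 1)
#' tail(run$records)
#' @export
run_simulation <- function(par, seed = par$seed, init = NULL) {
  validate_params(par)
  if (is.null(init)) init <- init_population(par)
  check_state(init, par)
  omega <- if (is.na(par$omega)) 1e-9 else par$omega
  set.seed(as.integer(seed))
  res <- pg_run_cpp(init, par$periods, par$b, par$c, par$p, par$k,
                    par$m, par$mu, par$s, par$e, omega,
                    par$scenario == "voluntary")
  if (res$clamped > 0) {
    warning(sprintf(
      "%d occupied payoff subclasses clamped at the positivity floor during the run",
      res$clamped), call. = FALSE)
  }
  rec <- res$records
  records <- data.frame(
    period = seq_len(nrow(rec)),
    freq_defector = rec[, 1], freq_contributor = rec[, 2],
    freq_punisher = rec[, 3], freq_nonparticipant = rec[, 4],
    freq_cooperation = rec[, 5]
  )
  colnames(res$counts) <- pgg_strategies
  structure(list(params = par, seed = as.integer(seed), records = records,
                 final_counts = res$counts),
            class = "pgg_run")
}

#' @export
print.pgg_run <- function(x, ...) {
  cat(sprintf("pgg_run: %s scenario, N = %d, n = %d, %d periods, seed %d\n",
              x$params$scenario, x$params$N, x$params$n,
              nrow(x$records), x$seed))
  if (nrow(x$records) > 0) {
    f <- x$records[nrow(x$records), ]
    cat(sprintf("  final frequencies: coop %.3f, defect %.3f, nonpart %.3f\n",
                f$freq_cooperation, f$freq_defector, f$freq_nonparticipant))
  }
  invisible(x)
}

#' Run a replicate set under derived seeds
#'
#' Runs `replicates` independent simulations of one parameter set, with
#' replicate `i` seeded `seed + i - 1`.  The fixed seed-derivation rule
#' makes sweeps reproducible and gives matched (common) random numbers to
#' cells that differ only in payoff parameters, such as a compulsory
#' baseline and its voluntary counterparts.
#'
#' @param par a [param_set()].
#' @param replicates number of replicate runs (defaults to
#'   `par$replicates`).
#' @param seed root seed (defaults to `par$seed`).
#' @return List of `pgg_run` objects.
#' @export
run_replicates <- function(par, replicates = par$replicates, seed = par$seed) {
  validate_params(par)
  lapply(seq_len(replicates), function(i) {
    run_simulation(par, seed = as.integer(seed) + i - 1L)
  })
}

#' Per-replicate long-run means
#'
#' Means of the recorded frequencies over the post-burn-in periods
#' (`burn_in + 1` through `periods`) of each run.
#'
#' @param runs a list of `pgg_run` objects (or a single one).
#' @param burn_in periods to discard (defaults to the runs' `burn_in`).
#' @return Data frame with one row per replicate: `seed`,
#'   `freq_cooperation`, `freq_defection`, `freq_nonparticipation`.
#' @export
replicate_means <- function(runs, burn_in = NULL) {
  if (inherits(runs, "pgg_run")) runs <- list(runs)
  stopifnot(length(runs) >= 1, all(vapply(runs, inherits, TRUE, "pgg_run")))
  if (is.null(burn_in)) burn_in <- runs[[1]]$params$burn_in
  periods <- nrow(runs[[1]]$records)
  stopifnot(burn_in < periods)
  keep <- seq.int(burn_in + 1L, periods)
  do.call(rbind, lapply(runs, function(r) {
    rec <- r$records[keep, ]
    data.frame(seed = r$seed,
               freq_cooperation = mean(rec$freq_cooperation),
               freq_defection = mean(rec$freq_defector),
               freq_nonparticipation = mean(rec$freq_nonparticipant))
  }))
}

#' Long-run average over replicates
#'
#' The long-run summary protocol: average each frequency over the last
#' `periods - burn_in` periods of each replicate, then across replicates;
#' dispersion is the standard deviation of the per-replicate means.  With
#' the defaults (2000 periods, burn-in 1000) this is the mean over the last
#' 1000 periods.  Cooperation, defection and nonparticipation partition the
#' population, so the three means sum to one.
#'
#' @param runs list of `pgg_run` objects sharing one parameter set.
#' @param burn_in periods to discard (defaults to the runs' `burn_in`).
#' @return One-row data frame: `scenario`, `n`, `omega`, `m`, `mu`, `p`,
#'   `replicates`, and mean and `_sd` columns for
#'   `freq_cooperation`, `freq_defection`, `freq_nonparticipation`.
#' @export
long_run_average <- function(runs, burn_in = NULL) {
  if (inherits(runs, "pgg_run")) runs <- list(runs)
  stopifnot(length(runs) >= 1, all(vapply(runs, inherits, TRUE, "pgg_run")))
  key <- function(r) {
    p <- r$params
    paste(p$scenario, p$N, p$n, p$b, p$c, p$p, p$k, p$m, p$mu, p$s, p$e,
          p$omega, p$periods, sep = "|")
  }
  keys <- vapply(runs, key, "")
  if (length(unique(keys)) != 1L) {
    stop("long_run_average: runs do not share one parameter set", call. = FALSE)
  }
  par <- runs[[1]]$params
  pm <- replicate_means(runs, burn_in)
  sd0 <- function(v) if (length(v) > 1) sd(v) else 0
  data.frame(
    scenario = par$scenario, n = par$n, omega = par$omega,
    m = par$m, mu = par$mu, p = par$p, replicates = nrow(pm),
    freq_cooperation_mean = mean(pm$freq_cooperation),
    freq_cooperation_sd = sd0(pm$freq_cooperation),
    freq_defection_mean = mean(pm$freq_defection),
    freq_defection_sd = sd0(pm$freq_defection),
    freq_nonparticipation_mean = mean(pm$freq_nonparticipation),
    freq_nonparticipation_sd = sd0(pm$freq_nonparticipation)
  )
}

#' Run one sweep cell and summarise it
#'
#' Convenience wrapper: [run_replicates()] followed by
#' [long_run_average()].
#'
#' @inheritParams run_replicates
#' @return One-row summary data frame (see [long_run_average()]).
#' @export
run_cell <- function(par, replicates = par$replicates, seed = par$seed) {
  long_run_average(run_replicates(par, replicates, seed))
}
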