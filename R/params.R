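#' Model parameters for one simulation scenario
#'
#' Bundles every model constant and run-control setting of the multilevel
#' public-goods simulation.  Defaults are the standard cultural-evolution
#' parameterisation: 128 groups, benefit `b = 0.5`, cooperation cost
#' `c = 0.2`, fine `p = 0.8`, punishing cost `k = 0.2`, between-group mixing
#' `m = 0.01`, mutation `mu = 0.01`, group-pairing rate `s = 0.015` and
#' erroneous-defection rate `e = 0.02`.  The group size `n` and (in the
#' voluntary scenario) the nonparticipant payoff `omega` have no default:
#' they are the quantities experiments sweep, so they must be given
#' explicitly.
#'
#' `omega` is the fixed outside payoff of a nonparticipant.  A contributor's
#' payoff ranges from `1 - c` (no cooperators) to `1 + b - c` (all
#' cooperators), so omegas outside `[1 - c, 1 + b - c]` are permitted but
#' draw a warning.  In the compulsory scenario nonparticipation is not in
#' the strategy set, so `omega` is inert; supplying one is accepted with a
#' note.
#'
#' @param n group size (number of individuals per group), integer `>= 2`.
#' @param scenario `"voluntary"` (nonparticipant strategy available) or
#'   `"compulsory"` (participation forced).
#' @param omega nonparticipants' payoff; required for the voluntary
#'   scenario, ignored (inert) in the compulsory scenario.
#' @param N number of groups, integer `>= 2`.
#' @param b benefit of the public good if everyone cooperates.
#' @param c cost of contributing.
#' @param p cost inflicted on a defector by each punisher (fine).
#' @param k cost a punisher pays per punished defector.
#' @param m probability that an imitation model is drawn from another group.
#' @param mu per-individual mutation probability per period.
#' @param s per-group probability of initiating a group conflict per period.
#' @param e probability that a cooperator erroneously defects.
#' @param periods number of periods to simulate.
#' @param burn_in number of initial periods excluded from long-run averages;
#'   must be smaller than `periods`.
#' @param replicates default number of replicate runs for experiments.
#' @param seed default root seed for experiments.
#'
#' @return An object of class `pgg_params`: a validated named list.
#' @examples
#' param_set(n = 20, scenario = "compulsory")
#' param_set(n = 120, scenario = "voluntary", omega = 0.95)
#' @export
param_set <- function(n, scenario = c("voluntary", "compulsory"),
                      omega = NULL, N = 128, b = 0.5, c = 0.2, p = 0.8,
                      k = 0.2, m = 0.01, mu = 0.01, s = 0.015, e = 0.02,
                      periods = 2000, burn_in = 1000, replicates = 100,
                      seed = 1L) {
  scenario <- match.arg(scenario)
  if (missing(n)) {
    stop("param_set: 'n' (group size) must be given explicitly", call. = FALSE)
  }
  if (scenario == "voluntary") {
    if (is.null(omega) || !is.finite(omega)) {
      stop("param_set: 'omega' (nonparticipants' payoff) must be given ",
           "explicitly in the voluntary scenario", call. = FALSE)
    }
  } else {
    if (!is.null(omega) && is.finite(omega)) {
      message("param_set: 'omega' is inert in the compulsory scenario ",
              "(no nonparticipant strategy)")
    }
    if (is.null(omega)) omega <- NA_real_
  }
  par <- list(N = as.integer(N), n = as.integer(n), b = b, c = c, p = p,
              k = k, m = m, mu = mu, s = s, e = e,
              omega = as.numeric(omega), scenario = scenario,
              periods = as.integer(periods), burn_in = as.integer(burn_in),
              replicates = as.integer(replicates), seed = as.integer(seed))
  class(par) <- "pgg_params"
  validate_params(par)
  par
}

#' Validate a parameter set
#'
#' Checks every field of a [param_set()] and stops with an error naming the
#' first offending field.  Called by every entry point that accepts
#' parameters; exported so configuration loaders can validate eagerly.
#'
#' @param par a `pgg_params` object (or a bare list with the same fields).
#' @return `par`, invisibly, if valid.
#' @export
validate_params <- function(par) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) {
      stop(sprintf("invalid parameter '%s': %s", field, msg), call. = FALSE)
    }
  }
  num1 <- function(v) length(v) == 1L && is.numeric(v) && !is.na(v)
  chk(num1(par$N) && par$N >= 2, "N", "must be an integer >= 2")
  chk(num1(par$n) && par$n >= 2, "n", "must be an integer >= 2")
  for (f in c("b", "c", "p", "k")) {
    chk(num1(par[[f]]) && par[[f]] >= 0, f, "must be a non-negative number")
  }
  for (f in c("m", "mu", "s", "e")) {
    chk(num1(par[[f]]) && par[[f]] >= 0 && par[[f]] <= 1, f,
        "must be a probability in [0, 1]")
  }
  chk(par$scenario %in% c("voluntary", "compulsory"), "scenario",
      "must be 'voluntary' or 'compulsory'")
  if (par$scenario == "voluntary") {
    chk(num1(par$omega), "omega", "must be a finite number (voluntary scenario)")
    lo <- 1 - par$c
    hi <- 1 + par$b - par$c
    if (par$omega < lo || par$omega > hi) {
      warning(sprintf(
        "omega = %g lies outside the feasible contributor-payoff range [%g, %g]",
        par$omega, lo, hi), call. = FALSE)
    }
  }
  chk(num1(par$periods) && par$periods >= 0, "periods",
      "must be a non-negative integer")
  chk(num1(par$burn_in) && par$burn_in >= 0, "burn_in",
      "must be a non-negative integer")
  if (par$periods > 0) {
    chk(par$periods > par$burn_in, "burn_in", "must be smaller than 'periods'")
  }
  chk(num1(par$replicates) && par$replicates >= 1, "replicates",
      "must be a positive integer")
  chk(num1(par$seed), "seed", "must be an integer")
  invisible(par)
}

#' @export
print.pgg_params <- function(x, ...) {
  cat(sprintf("Public-goods model parameters (%s scenario)\n", x$scenario))
  cat(sprintf("  groups N = %d, group size n = %d\n", x$N, x$n))
  cat(sprintf("  b = %g, c = %g, p = %g, k = %g\n", x$b, x$c, x$p, x$k))
  cat(sprintf("  m = %g, mu = %g, s = %g, e = %g\n", x$m, x$mu, x$s, x$e))
  if (x$scenario == "voluntary") {
    cat(sprintf("  nonparticipant payoff omega = %g\n", x$omega))
  }
  cat(sprintf("  periods = %d (burn-in %d), replicates = %d, seed = %d\n",
              x$periods, x$burn_in, x$replicates, x$seed))
  invisible(x)
}

# fields a config file may set; anything else is rejected
params_fields <- function() {
  c("N", "n", "b", "c", "p", "k", "m", "mu", "s", "e", "omega",
    "scenario", "periods", "burn_in", "replicates", "seed")
}
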