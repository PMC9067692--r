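#' Sweep grid for batch experiments
#'
#' Describes a batch of simulation cells over scenarios, group sizes and
#' nonparticipant payoffs, plus run-control settings shared by every cell.
#' The default grids match the experiments the harness reproduces: group
#' sizes `{20, 40, 60, 80, 100, 120}` and an omega grid from `0.80` to
#' `1.30` in steps of `0.05` (covering the feasible contributor-payoff
#' range `[1 - c, 1 + b - c]`).  The `scale` switch selects the replicate
#' count: `"full"` uses 100 replicates per cell, `"reduced"` uses 10.
#'
#' @param scenarios character subset of `c("voluntary", "compulsory")`.
#' @param n integer vector of group sizes.
#' @param omega numeric vector of nonparticipant payoffs (voluntary cells).
#' @param replicates replicates per cell; overrides `scale` when given.
#' @param periods periods per run.
#' @param burn_in initial periods excluded from long-run averages.
#' @param seed root seed; replicate `i` of every cell runs under
#'   `seed + i - 1`, so cells share common random numbers.
#' @param scale `"full"` (100 replicates) or `"reduced"` (10).
#' @param ... overrides for model constants (`N`, `b`, `c`, `p`, `k`, `m`,
#'   `mu`, `s`, `e`) applied to every cell.
#' @return A `pgg_grid` object.
#' @export
sweep_grid <- function(scenarios = c("voluntary", "compulsory"),
                       n = c(20L, 40L, 60L, 80L, 100L, 120L),
                       omega = seq(0.80, 1.30, by = 0.05),
                       replicates = NULL, periods = 2000, burn_in = 1000,
                       seed = 1L, scale = c("full", "reduced"), ...) {
  scale <- match.arg(scale)
  if (is.null(replicates)) replicates <- if (scale == "full") 100L else 10L
  bad <- setdiff(scenarios, c("voluntary", "compulsory"))
  if (length(bad)) {
    stop("unknown scenario(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  over <- list(...)
  badk <- setdiff(names(over), c("N", "b", "c", "p", "k", "m", "mu", "s", "e"))
  if (length(badk)) {
    stop("unknown model parameter(s): ", paste(badk, collapse = ", "),
         call. = FALSE)
  }
  grid <- structure(list(scenarios = scenarios, n = as.integer(n),
                         omega = as.numeric(omega),
                         replicates = as.integer(replicates),
                         periods = as.integer(periods),
                         burn_in = as.integer(burn_in),
                         seed = as.integer(seed), scale = scale,
                         overrides = over),
                    class = "pgg_grid")
  grid
}

#' @export
print.pgg_grid <- function(x, ...) {
  cat(sprintf("pgg_grid: scenarios {%s}, n {%s}, omega {%s}\n",
              paste(x$scenarios, collapse = ", "),
              paste(x$n, collapse = ", "),
              paste(x$omega, collapse = ", ")))
  cat(sprintf("  %d replicates x %d periods (burn-in %d), root seed %d\n",
              x$replicates, x$periods, x$burn_in, x$seed))
  invisible(x)
}

# internal: build the ParamSet of one cell of a grid
cell_params <- function(grid, scenario, n, omega = NA_real_) {
  args <- c(list(n = n, scenario = scenario,
                 omega = if (scenario == "voluntary") omega else NULL,
                 periods = grid$periods, burn_in = grid$burn_in,
                 replicates = grid$replicates, seed = grid$seed),
            grid$overrides)
  suppressMessages(do.call(param_set, args))
}

# internal: run every (scenario, n, omega) cell of a grid into a tidy table.
# Compulsory cells carry omega = NA ("N/A"): there is one baseline per n,
# shared across all omega comparisons.
run_sweep_cells <- function(grid, progress = interactive()) {
  cells <- list()
  for (scen in grid$scenarios) {
    omegas <- if (scen == "voluntary") grid$omega else NA_real_
    if (scen == "voluntary" && length(omegas) == 0) next
    for (n in grid$n) for (om in omegas) {
      cells[[length(cells) + 1L]] <- list(scenario = scen, n = n, omega = om)
    }
  }
  rows <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    cl <- cells[[i]]
    if (isTRUE(progress)) {
      message(sprintf("[%d/%d] %s n=%d omega=%s", i, length(cells),
                      cl$scenario, cl$n, format(cl$omega)))
    }
    par <- cell_params(grid, cl$scenario, cl$n, cl$omega)
    rows[[i]] <- run_cell(par, grid$replicates, grid$seed)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cooperation surface over group size and nonparticipant payoff
#'
#' The headline experiment: long-run cooperation for every `(n, omega)`
#' voluntary cell plus the compulsory baseline at each `n` (reported with
#' `omega = NA`).  At large group sizes cooperation peaks at an
#' intermediate omega — the inverted-U signature of voluntary
#' participation combined with group selection — while at small group
#' sizes no omega improves on the compulsory baseline.
#'
#' @param grid a [sweep_grid()]; an empty `omega` vector yields the
#'   compulsory-only baseline table.
#' @param progress print per-cell progress messages.
#' @return Tidy summary data frame, one row per cell (see
#'   [long_run_average()]).
#' @export
fig1_sweep <- function(grid = sweep_grid(), progress = interactive()) {
  stopifnot(inherits(grid, "pgg_grid"))
  run_sweep_cells(grid, progress)
}

#' Behaviour profiles at low, moderate and high nonparticipant payoff
#'
#' Long-run cooperation, defection and nonparticipation across group sizes
#' at three representative omegas — low (0.80), moderate (0.925) and high
#' (1.05) — alongside the compulsory baseline (`omega = NA`).
#'
#' @param grid a [sweep_grid()]; defaults to `omega = c(0.80, 0.925, 1.05)`.
#' @param progress print per-cell progress messages.
#' @return Tidy summary data frame, one row per cell.
#' @export
fig2_profiles <- function(grid = sweep_grid(omega = c(0.80, 0.925, 1.05)),
                          progress = interactive()) {
  stopifnot(inherits(grid, "pgg_grid"))
  run_sweep_cells(grid, progress)
}

#' Voluntary-minus-compulsory differences at the moderate payoff
#'
#' For each group size, the difference in long-run frequency of each
#' behaviour between the voluntary scenario at `omega` (default the
#' moderate payoff 0.925) and the matched compulsory baseline.  A positive
#' `delta_cooperation` means voluntary participation raised cooperation.
#'
#' @param grid a [sweep_grid()]; its `omega` must be a single value and
#'   both scenarios must be present (matched cells).
#' @param progress print per-cell progress messages.
#' @return Data frame with one row per `n`: `n`, `omega`,
#'   `delta_cooperation`, `delta_defection`, `delta_nonparticipation`.
#' @export
fig3_differences <- function(grid = sweep_grid(omega = 0.925,
                                               n = c(20L, 60L, 120L)),
                             progress = interactive()) {
  stopifnot(inherits(grid, "pgg_grid"))
  if (length(grid$omega) != 1L) {
    stop("fig3_differences: grid$omega must be a single value", call. = FALSE)
  }
  if (!all(c("voluntary", "compulsory") %in% grid$scenarios)) {
    stop("fig3_differences: grid must include both scenarios ",
         "(matched compulsory cells missing)", call. = FALSE)
  }
  tab <- run_sweep_cells(grid, progress)
  vol <- tab[tab$scenario == "voluntary", ]
  cmp <- tab[tab$scenario == "compulsory", ]
  out <- lapply(grid$n, function(n) {
    v <- vol[vol$n == n, ]
    b <- cmp[cmp$n == n, ]
    if (nrow(v) != 1L || nrow(b) != 1L) {
      stop(sprintf("fig3_differences: missing matched cell for n = %d", n),
           call. = FALSE)
    }
    data.frame(
      n = n, omega = grid$omega,
      delta_cooperation = v$freq_cooperation_mean - b$freq_cooperation_mean,
      delta_defection = v$freq_defection_mean - b$freq_defection_mean,
      delta_nonparticipation =
        v$freq_nonparticipation_mean - b$freq_nonparticipation_mean
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' One-parameter sensitivity sweep
#'
#' Re-runs the grid's cells while varying exactly one of the stochastic or
#' punishment parameters (`m`, `mu`, or `p`), all other constants at their
#' defaults.  Qualitatively, cooperation falls as the mixing rate `m` or
#' the mutation rate `mu` rises, and collapses when punishment is removed
#' (`p = 0`, typically swept together with `k` via the grid overrides).
#'
#' @param grid a [sweep_grid()] describing the fixed cells (scenario(s) and
#'   `n`; for compulsory-only sweeps set `scenarios = "compulsory"`).
#' @param vary which parameter to vary: `"m"`, `"mu"` or `"p"`.
#' @param values numeric vector of values for the varied parameter.
#' @param progress print per-cell progress messages.
#' @return Tidy summary data frame, one row per (cell, value), with the
#'   varied parameter's column reflecting each value.
#' @export
sensitivity_sweep <- function(grid, vary = c("m", "mu", "p"), values,
                              progress = interactive()) {
  stopifnot(inherits(grid, "pgg_grid"))
  vary <- match.arg(vary)
  if (length(vary) != 1L || missing(values) || length(values) < 1L) {
    stop("sensitivity_sweep: vary exactly one parameter over >= 1 values",
         call. = FALSE)
  }
  if (vary %in% names(grid$overrides)) {
    stop(sprintf(
      "sensitivity_sweep: '%s' is both fixed by the grid and varied", vary),
      call. = FALSE)
  }
  rows <- lapply(values, function(v) {
    g <- grid
    g$overrides[[vary]] <- v
    run_sweep_cells(g, progress)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
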