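#' Stage 3: payoff-biased imitation with between-group mixing
#'
#' Every individual independently draws one model: with probability `1 - m`
#' a uniformly chosen *other* member of its own group, with probability `m`
#' a uniformly chosen member of one uniformly chosen other group.  It then
#' adopts the model's strategy with probability `w_j / (w_j + w_i)`, the
#' relative-payoff comparison rule.  The update is synchronous: every
#' comparison uses the pre-step strategies and the current period's payoffs,
#' and all adoptions are applied simultaneously.  Nonparticipants take part
#' on both sides of imitation (their payoff is the fixed `omega`); this is
#' the only channel through which nonparticipation can spread.
#'
#' @param counts an `N x 4` population count matrix (pre-step state).
#' @param realized the `N x 2` error-count matrix of the current period
#'   ([realize_contributions()]); `NULL` means no errors.
#' @param payoffs the `N x 6` subclass payoff matrix ([payoff_profile()]).
#' @param m between-group mixing probability in `[0, 1]`.
#' @return The post-imitation `N x 4` count matrix.
#' @export
imitation_step <- function(counts, realized = NULL, payoffs, m) {
  stopifnot(is.matrix(counts), ncol(counts) == 4L,
            is.matrix(payoffs), ncol(payoffs) == 6L,
            nrow(payoffs) == nrow(counts), m >= 0, m <= 1)
  if (is.null(realized)) realized <- matrix(0L, nrow(counts), 2)
  if (any(counts[, 4] > 0L) && anyNA(payoffs[, 6])) {
    stop("nonparticipants present but their payoff (omega) is NA", call. = FALSE)
  }
  if (any(payoffs < 1e-9, na.rm = TRUE)) {
    warning("non-positive payoffs clamped at 1e-9 for imitation", call. = FALSE)
    payoffs <- pmax(payoffs, 1e-9)
  }
  payoffs[is.na(payoffs)] <- 1e-9  # unoccupied nonparticipant column
  out <- pg_imitation_cpp(counts, realized, payoffs, m)
  colnames(out) <- pgg_strategies
  out
}

#' Stage 4: group conflict with cultural takeover
#'
#' Each group independently initiates a conflict against one uniformly
#' chosen other group with probability `s`; the initiations are then
#' resolved sequentially in a uniformly random order.  In a conflict between
#' groups `i` and `j`, group `i` wins with probability
#' `0.5 * (1 + (x_i - x_j))`, where `x_g` is the strategy-based cooperator
#' fraction of group `g` at resolution time; the loser's strategy counts are
#' overwritten with a copy of the winner's (cultural replacement of the
#' whole group).  The group with more cooperators is thus more likely to
#' take over — cooperation is the sole target of group selection.
#'
#' @param counts an `N x 4` population count matrix.
#' @param s conflict-initiation probability in `[0, 1]`.
#' @return The post-conflict `N x 4` count matrix.
#' @export
group_conflict_step <- function(counts, s) {
  stopifnot(is.matrix(counts), ncol(counts) == 4L, nrow(counts) >= 2,
            s >= 0, s <= 1)
  out <- pg_conflict_cpp(counts, s)
  colnames(out) <- pgg_strategies
  out
}

#' Stage 5: mutation
#'
#' Each individual independently, with probability `mu`, replaces its
#' strategy with one drawn uniformly from the other available strategies —
#' three alternatives in the voluntary scenario, two in the compulsory
#' scenario (where the nonparticipant strategy does not exist).  Mutation is
#' how nonparticipation first enters a voluntary-scenario population.
#'
#' @param counts an `N x 4` population count matrix.
#' @param mu mutation probability in `[0, 1]`.
#' @param scenario `"voluntary"` or `"compulsory"`.
#' @return The post-mutation `N x 4` count matrix.
#' @export
mutation_step <- function(counts, mu, scenario = c("voluntary", "compulsory")) {
  scenario <- match.arg(scenario)
  stopifnot(is.matrix(counts), ncol(counts) == 4L, mu >= 0, mu <= 1)
  if (scenario == "compulsory" && any(counts[, 4] > 0L)) {
    stop("nonparticipants present in a compulsory-scenario population",
         call. = FALSE)
  }
  out <- pg_mutation_cpp(counts, mu, scenario == "voluntary")
  colnames(out) <- pgg_strategies
  out
}

#' One full period of the five-stage update
#'
#' Applies, in order: erroneous contribution, punishment/payoffs,
#' payoff-biased imitation, group conflict, and mutation, consuming random
#' draws in the package's canonical order (identical to the compiled
#' full-run loop, so stepping period by period reproduces [run_simulation()]
#' exactly under the same seed).
#'
#' @param counts an `N x 4` population count matrix.
#' @param par a [param_set()].
#' @return A list with `counts` (post-period state) and `record` (named
#'   vector of the four strategy frequencies plus `cooperation`, measured
#'   after stage 5).
#' @export
step_period <- function(counts, par) {
  validate_params(par)
  check_state(counts, par)
  errs <- realize_contributions(counts, par$e)
  pw <- pg_payoffs_cpp(counts, errs, par$b, par$c, par$p, par$k,
                       ifelse(is.na(par$omega), 1e-9, par$omega))
  if (pw$clamped > 0) {
    warning(sprintf("%d occupied payoff subclasses clamped at the positivity floor",
                    pw$clamped), call. = FALSE)
  }
  cnt <- pg_imitation_cpp(counts, errs, pw$payoffs, par$m)
  cnt <- pg_conflict_cpp(cnt, par$s)
  cnt <- pg_mutation_cpp(cnt, par$mu, par$scenario == "voluntary")
  colnames(cnt) <- pgg_strategies
  list(counts = cnt, record = pop_frequencies(cnt))
}
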