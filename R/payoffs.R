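#' Stage 1: realized contributions with execution error
#'
#' Each cooperator (contributor or punisher) contributes with probability
#' `1 - e` and erroneously defects with probability `e`, independently across
#' individuals, groups and periods; deliberate defectors and nonparticipants
#' are unaffected.  The per-group counts of erring cooperators are therefore
#' Binomial(`n_C`, `e`) and Binomial(`n_P`, `e`).
#'
#' Consumes one uniform draw per cooperator from R's RNG stream (groups in
#' index order, contributors before punishers), the canonical order shared
#' with the compiled engine.
#'
#' @param counts an `N x 4` population count matrix.
#' @param e erroneous defection probability in `[0, 1]`.
#' @return An `N x 2` integer matrix with columns `c_err`, `p_err`.
#' @export
realize_contributions <- function(counts, e) {
  stopifnot(is.matrix(counts), ncol(counts) == 4L, e >= 0, e <= 1)
  errs <- pg_realize_cpp(counts, e)
  colnames(errs) <- c("c_err", "p_err")
  errs
}

#' Stage 2: punishment and subclass payoffs
#'
#' Computes the period payoff of every behavioural subclass in every group.
#' With realized cooperation fraction `xhat = A/n` (`A` = cooperators who
#' actually contributed) and realized participant-defector count
#' `Dhat = n_D + c_err + p_err`:
#'
#' \describe{
#'   \item{defector}{`1 + b*xhat - p*n_P/n` — fined `p/n` by each punisher.}
#'   \item{contributor_ok}{`1 + b*xhat - c`.}
#'   \item{contributor_err}{`1 + b*xhat - p*n_P/n` — did not pay `c`, but is
#'     punished like a deliberate defector.}
#'   \item{punisher_ok}{`1 + b*xhat - c - (k/n)*Dhat` — pays `k/n` per
#'     realized defector.}
#'   \item{punisher_err}{`1 + b*xhat - p*(n_P - 1)/n - (k/n)*(Dhat - 1)` —
#'     still punishes the other realized defectors and is fined by the other
#'     punishers; no self-punishment.}
#'   \item{nonparticipant}{`omega`, independent of group composition.}
#' }
#'
#' With `e = 0` these reduce exactly to the fraction-based formulas
#' `1 + bx - c` (contributor), `1 + bx - py` (defector) and
#' `1 + bx - c - k(1 - x - z)` (punisher; `z = 0` under compulsory
#' participation).  Payoffs are clamped below at `1e-9` before use in
#' imitation; a warning reports how many occupied subclasses were clamped
#' (none under the default parameterisation).
#'
#' @param counts an `N x 4` population count matrix.
#' @param realized an `N x 2` matrix from [realize_contributions()]; `NULL`
#'   means no execution errors.
#' @param par a [param_set()].
#' @return An `N x 6` numeric matrix, columns [pgg_subclasses].
#' @examples
#' par <- param_set(n = 20, scenario = "voluntary", omega = 0.95)
#' grp <- matrix(c(14L, 6L, 0L, 0L), 1)  # x = 0.3
#' payoff_profile(grp, NULL, par)[, "contributor_ok"]  # 0.95
#' @export
payoff_profile <- function(counts, realized = NULL, par) {
  stopifnot(is.matrix(counts), ncol(counts) == 4L)
  if (is.null(realized)) realized <- matrix(0L, nrow(counts), 2)
  stopifnot(nrow(realized) == nrow(counts), ncol(realized) == 2L)
  if (par$scenario == "compulsory" && any(counts[, 4] > 0L)) {
    stop("nonparticipants present in a compulsory-scenario population",
         call. = FALSE)
  }
  if (any(realized[, 1] > counts[, 2]) || any(realized[, 2] > counts[, 3])) {
    stop("realized error counts exceed cooperator counts", call. = FALSE)
  }
  n <- rowSums(counts)
  A <- (counts[, 2] - realized[, 1]) + (counts[, 3] - realized[, 2])
  Dhat <- counts[, 1] + realized[, 1] + realized[, 2]
  xhat <- A / n
  y <- counts[, 3] / n
  base <- 1 + par$b * xhat
  w <- cbind(
    defector        = base - par$p * y,
    contributor_ok  = base - par$c,
    contributor_err = base - par$p * y,
    punisher_ok     = base - par$c - par$k * (Dhat / n),
    punisher_err    = base - par$p * ((counts[, 3] - 1) / n) -
                             par$k * ((Dhat - 1) / n),
    nonparticipant  = rep(par$omega, nrow(counts))
  )
  occ <- cbind(counts[, 1], counts[, 2] - realized[, 1], realized[, 1],
               counts[, 3] - realized[, 2], realized[, 2], counts[, 4])
  low <- w < 1e-9
  low[is.na(low)] <- FALSE  # inert NA omega in the compulsory scenario
  if (any(low & occ > 0L)) {
    warning(sprintf("%d occupied payoff subclasses clamped at the positivity floor",
                    sum(low & occ > 0L)), call. = FALSE)
  }
  w[low] <- 1e-9
  w
}
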