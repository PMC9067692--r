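#' Initial population state
#'
#' Builds the canonical starting population: one group composed entirely of
#' punishers and the remaining `N - 1` groups composed entirely of defectors,
#' so the global cooperation frequency at time zero is `1/N`.  This is the
#' classic seeding for studying whether a rare cooperative (punishing) norm
#' can invade a world of defection through group selection.
#'
#' @param par a [param_set()].
#' @return An `N x 4` integer matrix of per-group strategy counts with
#'   columns [pgg_strategies] (defector, contributor, punisher,
#'   nonparticipant).
#' @examples
#' head(init_population(param_set(n = 20, scenario = "compulsory")))
#' @export
init_population <- function(par) {
  validate_params(par)
  counts <- matrix(0L, nrow = par$N, ncol = 4,
                   dimnames = list(NULL, pgg_strategies))
  counts[1, "punisher"] <- par$n
  counts[-1, "defector"] <- par$n
  counts
}

#' Group composition fractions
#'
#' Computes the fractions the payoff formulas are written in: `x`, the
#' fraction of cooperators (contributors plus punishers); `y`, the fraction
#' of punishers; and `z`, the fraction of nonparticipants.  All denominators
#' are the full group size `n`, including nonparticipants.
#'
#' @param group an integer vector of length 4 (defector, contributor,
#'   punisher, nonparticipant counts) or a single-row population matrix.
#' @return Named numeric vector `c(x, y, z)`.
#' @examples
#' fractions(c(4L, 3L, 2L, 1L))  # x = 0.5, y = 0.2, z = 0.1
#' @export
fractions <- function(group) {
  group <- as.integer(group)
  stopifnot(length(group) == 4L, all(group >= 0L))
  n <- sum(group)
  c(x = (group[2] + group[3]) / n, y = group[3] / n, z = group[4] / n)
}

#' Global strategy frequencies of a population state
#'
#' @param counts an `N x 4` population count matrix.
#' @return Named numeric vector with the four strategy frequencies plus
#'   `cooperation` (contributor + punisher frequency).
#' @export
pop_frequencies <- function(counts) {
  tot <- sum(counts)
  f <- colSums(counts) / tot
  c(setNames(as.numeric(f), pgg_strategies),
    cooperation = as.numeric(f[2] + f[3]))
}

# internal: check a count matrix is a well-formed population for `par`
check_state <- function(counts, par) {
  if (!is.matrix(counts) || ncol(counts) != 4L) {
    stop("population state must be an N x 4 count matrix", call. = FALSE)
  }
  if (any(counts < 0L)) stop("negative strategy count", call. = FALSE)
  if (any(rowSums(counts) != par$n)) {
    stop("group counts must sum to the group size n", call. = FALSE)
  }
  if (par$scenario == "compulsory" && any(counts[, 4] > 0L)) {
    stop("nonparticipants present in a compulsory-scenario population",
         call. = FALSE)
  }
  invisible(counts)
}
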