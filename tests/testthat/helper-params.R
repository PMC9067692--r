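# small parameter sets and random valid states used across tests

tiny_params <- function(scenario = "voluntary", omega = 0.925, n = 6, N = 4,
                        ...) {
  suppressMessages(param_set(
    n = n, N = N, scenario = scenario,
    omega = if (scenario == "voluntary") omega else NULL,
    periods = 50, burn_in = 25, ...
  ))
}

# a random valid population state (optionally with nonparticipants)
random_state <- function(N, n, with_z = TRUE) {
  t(vapply(seq_len(N), function(g) {
    probs <- runif(4)
    if (!with_z) probs[4] <- 0
    cnt <- as.integer(rmultinom(1, n, probs))
    cnt
  }, integer(4)))
}

# every composition (nD, nC, nP, nZ) summing to n
all_compositions <- function(n, with_z = TRUE) {
  zmax <- if (with_z) n else 0
  out <- list()
  for (z in 0:zmax) for (p in 0:(n - z)) for (cc in 0:(n - z - p)) {
    out[[length(out) + 1L]] <- c(n - z - p - cc, cc, p, z)
  }
  do.call(rbind, out)
}
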