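test_that("imitation leaves a monomorphic group unchanged when m = 0", {
  par <- tiny_params()
  cnt <- rbind(c(0L, 6L, 0L, 0L), c(6L, 0L, 0L, 0L))
  errs <- matrix(0L, 2, 2)
  w <- payoff_profile(cnt, errs, par)
  set.seed(5)
  out <- imitation_step(cnt, errs, w, m = 0)
  expect_equal(unname(out), unname(cnt))
})

test_that("adoption follows the relative-payoff rule w_j / (w_j + w_i)", {
  # two-member group (one defector, one nonparticipant): each member's model
  # is deterministically the other, and the two adoption draws are
  # independent, so the joint outcome frequencies expose the comparison rule:
  # P(both end nonparticipant) = q^2 and P(both end defector) = (1 - q)^2
  # with q = w_Z / (w_Z + w_D)
  cnt <- rbind(c(1L, 0L, 0L, 1L))
  errs <- matrix(0L, 1, 2)
  reps <- 4000
  joint <- function(wZ, seed) {
    w <- matrix(1, 1, 6)
    w[1, 6] <- wZ
    set.seed(seed)
    out <- replicate(reps, pg_imitation_cpp(cnt, errs, w, 0)[1, 4])
    c(allZ = mean(out == 2L), allD = mean(out == 0L))
  }
  # equal payoffs: q = 1/2
  fr <- joint(1, 61)
  expect_lt(abs(fr["allZ"] - 0.25), 3 * sqrt(0.25 * 0.75 / reps))
  expect_lt(abs(fr["allD"] - 0.25), 3 * sqrt(0.25 * 0.75 / reps))
  # model payoff three times the imitator's: q = 3/4
  fr <- joint(3, 62)
  expect_lt(abs(fr["allZ"] - 0.5625), 3 * sqrt(0.5625 * 0.4375 / reps))
  expect_lt(abs(fr["allD"] - 0.0625), 3 * sqrt(0.0625 * 0.9375 / reps))
})

test_that("imitation under equal payoffs is a martingale in expectation", {
  cnt <- rbind(c(3L, 2L, 2L, 1L), c(1L, 4L, 2L, 1L), c(2L, 2L, 2L, 2L))
  errs <- matrix(0L, 3, 2)
  w <- matrix(1, 3, 6)
  f0 <- pop_frequencies(cnt)[1:4]
  reps <- 2000
  set.seed(63)
  freqs <- replicate(reps, pop_frequencies(
    pg_imitation_cpp(cnt, errs, w, 0.1))[1:4])
  # per-strategy mean change within 3 standard errors of zero
  for (q in 1:4) {
    se <- sd(freqs[q, ]) / sqrt(reps)
    expect_lt(abs(mean(freqs[q, ]) - f0[q]), 3 * se + 1e-12)
  }
})

test_that("group conflict follows the cooperator-weighted takeover rule", {
  set.seed(71)
  # full cooperators versus full defectors: the cooperative side always wins
  cnt <- rbind(c(0L, 0L, 6L, 0L), c(6L, 0L, 0L, 0L))
  out <- group_conflict_step(cnt, s = 1)
  expect_equal(unname(out[1, ]), c(0L, 0L, 6L, 0L))
  expect_equal(unname(out[2, ]), c(0L, 0L, 6L, 0L))
  # s = 0: no conflict ever
  expect_equal(unname(group_conflict_step(cnt, 0)), unname(cnt))
  # x_i = 0.8 vs x_j = 0.2: the stronger group's composition survives ~80%
  cnt <- rbind(c(2L, 4L, 4L, 0L), c(8L, 1L, 1L, 0L))
  reps <- 3000
  wins <- replicate(reps, {
    out <- group_conflict_step(cnt, s = 1)
    all(out[1, ] == cnt[1, ]) && all(out[2, ] == cnt[1, ])
  })
  expect_lt(abs(mean(wins) - 0.8), 3 * sqrt(0.8 * 0.2 / reps))
  # symmetric groups: either composition survives half the time
  cnt <- rbind(c(5L, 3L, 2L, 0L), c(5L, 2L, 3L, 0L))
  wins <- replicate(reps, {
    out <- group_conflict_step(cnt, s = 1)
    all(out[2, ] == cnt[1, ])
  })
  expect_lt(abs(mean(wins) - 0.5), 3 * sqrt(0.25 / reps))
})

test_that("mutation draws uniformly over the other available strategies", {
  par <- tiny_params()
  cnt <- rbind(c(6L, 0L, 0L, 0L))
  set.seed(81)
  expect_equal(unname(mutation_step(cnt, 0, "voluntary")), unname(cnt))
  # certain mutation in the voluntary scenario: all-defector group splits
  # evenly over the three alternatives
  reps <- 2000
  draws <- replicate(reps, mutation_step(cnt, 1, "voluntary")[1, 2:4])
  means <- rowMeans(draws)
  se <- 3 * sqrt(6 * (1 / 3) * (2 / 3) / reps)
  expect_true(all(abs(means - 2) < se))
  expect_true(all(colSums(draws) == 6L))
  # compulsory: nonparticipants never arise
  draws <- replicate(200, mutation_step(cnt, 1, "compulsory")[1, 4])
  expect_true(all(draws == 0L))
  expect_error(mutation_step(rbind(c(1L, 1L, 1L, 3L)), 0.5, "compulsory"),
               "compulsory")
})

test_that("a homogeneous population with all rates off is a fixed point", {
  par <- tiny_params(scenario = "compulsory", n = 6, N = 3,
                     m = 0, mu = 0, s = 0, e = 0)
  cnt <- rbind(c(0L, 0L, 6L, 0L), c(0L, 0L, 6L, 0L), c(0L, 0L, 6L, 0L))
  set.seed(91)
  st <- step_period(cnt, par)
  expect_equal(unname(st$counts), unname(cnt))
  run <- run_simulation(par, seed = 91, init = cnt)
  expect_true(all(run$records$freq_punisher == 1))
  expect_true(all(run$records$freq_cooperation == 1))
})

test_that("one period cannot move global frequencies far from 1/N", {
  par <- param_set(n = 20, N = 128, scenario = "compulsory", periods = 1,
                   burn_in = 0)
  for (sd in 1:5) {
    run <- run_simulation(par, seed = sd)
    expect_gt(run$records$freq_cooperation[1], 0)
    expect_lt(run$records$freq_cooperation[1], 0.1)
  }
})

test_that("every stage conserves the population and state validity", {
  par <- tiny_params(n = 8, N = 5)
  set.seed(103)
  for (i in 1:25) {
    cnt <- random_state(5, 8)
    errs <- realize_contributions(cnt, par$e)
    expect_true(all(errs[, 1] <= cnt[, 2] & errs[, 2] <= cnt[, 3]))
    w <- payoff_profile(cnt, errs, par)
    a <- imitation_step(cnt, errs, w, par$m)
    expect_true(all(rowSums(a) == 8L) && all(a >= 0L))
    b <- group_conflict_step(a, par$s)
    expect_true(all(rowSums(b) == 8L) && all(b >= 0L))
    cc <- mutation_step(b, par$mu, "voluntary")
    expect_true(all(rowSums(cc) == 8L) && all(cc >= 0L))
  }
})

test_that("compulsory trajectories are invariant to omega under shared seeds", {
  par <- param_set(n = 10, N = 8, scenario = "compulsory", periods = 60,
                   burn_in = 30)
  lo <- par
  lo$omega <- 0.80
  hi <- par
  hi$omega <- 1.30
  r_lo <- run_simulation(lo, seed = 1234)
  r_hi <- run_simulation(hi, seed = 1234)
  expect_identical(r_lo$records, r_hi$records)
  expect_identical(r_lo$final_counts, r_hi$final_counts)
})

test_that("with mu = 0 and no initial loners, scenarios coincide exactly", {
  parv <- param_set(n = 10, N = 8, scenario = "voluntary", omega = 1.0,
                    mu = 0, periods = 60, burn_in = 30)
  parc <- param_set(n = 10, N = 8, scenario = "compulsory", mu = 0,
                    periods = 60, burn_in = 30)
  rv <- run_simulation(parv, seed = 99)
  rc <- run_simulation(parc, seed = 99)
  expect_identical(rv$records, rc$records)
  expect_true(all(rv$records$freq_nonparticipant == 0))
})

test_that("the compiled engine matches the per-agent oracle bit for bit", {
  # voluntary scenario with loners present from the start
  par <- tiny_params(n = 6, N = 4, omega = 0.925)
  init <- rbind(c(2L, 1L, 2L, 1L), c(6L, 0L, 0L, 0L),
                c(0L, 3L, 3L, 0L), c(1L, 1L, 1L, 3L))
  run <- run_simulation(par, seed = 314, init = init)
  set.seed(314)
  expect_identical(unname(run$final_counts),
                   unname(oracle_run(init, par, 50)))
  # compulsory scenario
  parc <- tiny_params(scenario = "compulsory", n = 5, N = 3)
  initc <- rbind(c(0L, 0L, 5L, 0L), c(5L, 0L, 0L, 0L), c(2L, 2L, 1L, 0L))
  runc <- run_simulation(parc, seed = 2718, init = initc)
  set.seed(2718)
  expect_identical(unname(runc$final_counts),
                   unname(oracle_run(initc, parc, 50)))
})

test_that("stage-wise stepping reproduces the full-run engine exactly", {
  par <- tiny_params(n = 6, N = 4)
  init <- rbind(c(2L, 1L, 2L, 1L), c(6L, 0L, 0L, 0L),
                c(0L, 3L, 3L, 0L), c(1L, 1L, 1L, 3L))
  onep <- par
  onep$periods <- 5L
  onep$burn_in <- 0L
  full <- run_simulation(onep, seed = 55, init = init)
  set.seed(55)
  cnt <- init
  for (t in 1:5) cnt <- step_period(cnt, par)$counts
  expect_identical(unname(full$final_counts), unname(cnt))
})

test_that("trajectories are bit-identical under a repeated seed", {
  par <- tiny_params(n = 8, N = 6)
  r1 <- run_simulation(par, seed = 7)
  r2 <- run_simulation(par, seed = 7)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$final_counts, r2$final_counts)
})
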