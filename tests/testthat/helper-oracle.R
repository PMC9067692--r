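# Naive agent-level reference implementation of the five-stage period update.
#
# Consumes random draws from R's RNG in the same canonical order as the
# compiled engine (see src/engine.cpp), so that under a shared seed the two
# implementations must produce bit-identical trajectories.  Everything here
# is written per agent with explicit loops; it shares no code with the
# engine.

oracle_idx <- function(k) {
  j <- floor(runif(1) * k)
  if (j >= k) j <- k - 1
  as.integer(j)
}

oracle_period <- function(cnt, par) {
  N <- nrow(cnt)
  n <- sum(cnt[1, ])
  voluntary <- par$scenario == "voluntary"
  omega <- if (is.na(par$omega)) 1e-9 else par$omega
  cls2strat <- c(1L, 2L, 2L, 3L, 3L, 4L)

  # stage 1: groups in order, contributors then punishers, one uniform each
  errs <- matrix(0L, N, 2)
  for (g in 1:N) {
    ce <- 0L
    for (t in seq_len(cnt[g, 2])) if (runif(1) < par$e) ce <- ce + 1L
    pe <- 0L
    for (t in seq_len(cnt[g, 3])) if (runif(1) < par$e) pe <- pe + 1L
    errs[g, ] <- c(ce, pe)
  }

  # stage 2: subclass payoffs (deterministic)
  w <- matrix(0, N, 6)
  sub <- matrix(0L, N, 6)
  for (g in 1:N) {
    nD <- cnt[g, 1]; nC <- cnt[g, 2]; nP <- cnt[g, 3]; nZ <- cnt[g, 4]
    ce <- errs[g, 1]; pe <- errs[g, 2]
    A <- (nC - ce) + (nP - pe)
    Dhat <- nD + ce + pe
    xhat <- A / n
    y <- nP / n
    base <- 1 + par$b * xhat
    w[g, ] <- c(base - par$p * y,
                base - par$c,
                base - par$p * y,
                base - par$c - par$k * (Dhat / n),
                base - par$p * ((nP - 1) / n) - par$k * ((Dhat - 1) / n),
                omega)
    w[g, w[g, ] < 1e-9] <- 1e-9
    sub[g, ] <- c(nD, nC - ce, ce, nP - pe, pe, nZ)
  }

  # stage 3: individuals in canonical order, synchronous adoption
  post <- matrix(0L, N, 4)
  for (g in 1:N) {
    pos <- 0L
    for (q in 1:6) {
      wi <- w[g, q]
      for (t in seq_len(sub[g, q])) {
        if (runif(1) < par$m) {
          mg0 <- oracle_idx(N - 1)
          if (mg0 >= g - 1L) mg0 <- mg0 + 1L
          mg <- mg0 + 1L
          jidx <- oracle_idx(n)
        } else {
          mg <- g
          jidx <- oracle_idx(n - 1)
          if (jidx >= pos) jidx <- jidx + 1L
        }
        jq <- 1L
        acc <- sub[mg, 1]
        while (jidx >= acc) {
          jq <- jq + 1L
          acc <- acc + sub[mg, jq]
        }
        wj <- w[mg, jq]
        snew <- if (runif(1) < wj / (wj + wi)) cls2strat[jq] else cls2strat[q]
        post[g, snew] <- post[g, snew] + 1L
        pos <- pos + 1L
      }
    }
  }
  cnt <- post

  # stage 4: initiation pass, Fisher-Yates order, sequential resolution
  opp <- rep(-1L, N)
  for (g0 in 0:(N - 1)) {
    if (runif(1) < par$s) {
      o <- oracle_idx(N - 1)
      if (o >= g0) o <- o + 1L
      opp[g0 + 1L] <- o
    }
  }
  perm <- 0:(N - 1)
  for (i in 0:(N - 2)) {
    j <- i + oracle_idx(N - i)
    tmp <- perm[i + 1L]; perm[i + 1L] <- perm[j + 1L]; perm[j + 1L] <- tmp
  }
  for (t in 1:N) {
    i0 <- perm[t]
    j0 <- opp[i0 + 1L]
    if (j0 < 0) next
    xi <- (cnt[i0 + 1L, 2] + cnt[i0 + 1L, 3]) / n
    xj <- (cnt[j0 + 1L, 2] + cnt[j0 + 1L, 3]) / n
    if (runif(1) < 0.5 * (1 + (xi - xj))) {
      cnt[j0 + 1L, ] <- cnt[i0 + 1L, ]
    } else {
      cnt[i0 + 1L, ] <- cnt[j0 + 1L, ]
    }
  }

  # stage 5: individuals in canonical order, uniform draw over alternatives
  nstrat <- if (voluntary) 4L else 3L
  nalt <- nstrat - 1L
  post <- matrix(0L, N, 4)
  for (g in 1:N) {
    for (q in 1:4) {
      for (t in seq_len(cnt[g, q])) {
        snew <- q
        if (runif(1) < par$mu) {
          a <- oracle_idx(nalt)
          alts <- setdiff(seq_len(nstrat), q)
          snew <- alts[a + 1L]
        }
        post[g, snew] <- post[g, snew] + 1L
      }
    }
  }
  post
}

oracle_run <- function(cnt, par, periods) {
  for (t in seq_len(periods)) cnt <- oracle_period(cnt, par)
  cnt
}
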