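---
title: "A multilevel-selection model of public goods, punishment and voluntary participation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multilevel-selection model of public goods, punishment and voluntary participation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pggsel)
```

## The model

`pggsel` simulates cultural evolution in a population of `N` groups of `n`
individuals each. Every individual carries one of four strategies:

* **defector** — consumes the local public good without contributing;
* **contributor** — pays a cost `c` to contribute;
* **punisher** — contributes *and* imposes a fine on every defector, at a
  personal cost;
* **nonparticipant** (loner) — opts out of the joint project altogether and
  collects a fixed outside payoff `omega`, neither producing nor consuming
  the public good.

"Cooperators" always means contributors plus punishers. The *compulsory*
scenario removes the nonparticipant strategy from the strategy set; the
*voluntary* scenario includes it. Comparing the two scenarios across group
sizes and levels of `omega` is the package's purpose: it isolates the joint
effect of an exit option and group-level selection on the evolution of
costly cooperation and altruistic punishment.

With `x`, `y`, `z` the within-group fractions of cooperators, punishers and
nonparticipants (denominator: the full group size `n`), the error-free
period payoffs are

* contributor: `1 + b x − c`
* defector: `1 + b x − p y`
* punisher: `1 + b x − c − k (1 − x − z)` (compulsory: `z = 0`)
* nonparticipant: `omega`, independent of the group's composition.

The `1 + b x` term says the public benefit scales with the fraction of
cooperators; `p y` says each defector is fined `p/n` by every punisher;
`k (1 − x − z)` says each punisher pays `k/n` per punished defector.
Nonparticipants are never punished and never punish.

### The five stages of a period

1. **Erroneous contribution.** Each cooperator contributes with probability
   `1 − e` and accidentally defects with probability `e`; deliberate
   defectors always defect. Per group the error counts are binomial.
2. **Punishment and payoffs.** Punishers fine every individual who
   *actually* defected in stage 1 — including erring cooperators. The
   benefit term uses the realized contribution fraction. An erring punisher
   still punishes the other realized defectors and is fined by the other
   punishers; there is no self-punishment, which is why its payoff carries
   `(n_P − 1)` and `(D − 1)` terms. With `e = 0` all subclass payoffs
   reduce exactly to the four formulas above, which is the tested contract.
3. **Payoff-biased imitation.** Every individual draws one model — from its
   own group (excluding itself) with probability `1 − m`, from one
   uniformly chosen other group with probability `m` — and adopts the
   model's strategy with probability `w_j / (w_j + w_i)`. The update is
   synchronous: all comparisons use pre-update strategies and the current
   period's payoffs. Nonparticipants take part on both sides (their payoff
   is `omega`); imitation is the only channel through which
   nonparticipation can spread once present.
4. **Group conflict.** Each group initiates a conflict against one
   uniformly chosen other group with probability `s`. Initiated conflicts
   are resolved sequentially in a uniformly random order; in a conflict the
   initiator wins with probability `0.5 (1 + (x_i − x_j))` and the loser's
   strategy counts are overwritten by a copy of the winner's — cultural
   replacement of the whole group, making cooperation the sole target of
   group selection.
5. **Mutation.** Each individual, with probability `mu`, switches to a
   strategy drawn uniformly from the other available strategies (three
   alternatives in the voluntary scenario, two in the compulsory one).
   Mutation is how nonparticipation first appears.

Period records (global strategy frequencies) are taken after stage 5.

### Parameters

| parameter | meaning | default |
|---|---|---|
| `N` | number of groups | 128 |
| `n` | group size | swept, 20–120 |
| `b` | benefit when everyone cooperates | 0.5 |
| `c` | cost of contributing | 0.2 |
| `p` | fine received per punisher | 0.8 |
| `k` | punisher's cost per punished defector | 0.2 |
| `m` | between-group imitation (mixing) rate | 0.01 |
| `mu` | mutation rate | 0.01 |
| `s` | conflict-initiation rate per group | 0.015 |
| `e` | erroneous defection rate | 0.02 |
| `omega` | nonparticipant payoff | swept, 0.80–1.30 |

All payoffs are in dimensionless fitness units; one period is one
interaction-imitation-conflict-mutation cycle. `omega` is meaningful inside
`[1 − c, 1 + b − c] = [0.80, 1.30]`, the range a contributor's payoff can
take as `x` goes from 0 to 1; values outside are permitted with a warning.
Runs start from one all-punisher group among `N − 1` all-defector groups,
so cooperation starts at frequency `1/N`, and the long-run summary is the
mean over the last `periods − burn_in` periods (default: last 1000 of
2000), then over replicates.

## Design decisions

**Counts, not agents.** Within a group, individuals sharing a strategy are
exchangeable up to the current period's realized behaviour, so the state is
an `N x 4` count matrix plus per-period behavioural subclasses. The period
loop is compiled (Rcpp) for speed.

**A canonical random-draw order.** The compiled engine consumes R's RNG
stream (`unif_rand`) in a fixed, documented per-agent order (see
`src/engine.cpp`). This buys two things: trajectories are bit-reproducible
from a single integer seed across the R and C++ layers, and a naive
per-agent reference implementation written in plain R
(`tests/testthat/helper-oracle.R`) reproduces engine trajectories
*identically*, which the test suite asserts over 50 periods. Index draws
use `floor(u * k)`; the within-group model draw excludes the focal
individual by index shifting.

**Conflict protocol.** "Paired with probability `s`" underdetermines the
protocol. We let each group independently initiate at most one conflict per
period (it may additionally be drawn as an opponent) and resolve the
initiated conflicts sequentially in a random order against the current
state, avoiding ill-defined simultaneous overwrites. Every conflict ends in
a takeover by one side.

**Mutation targets.** Mutation draws uniformly over the *other available*
strategies, total probability `mu` per individual per period. We also
prototyped two alternatives — a dedicated participant-to-nonparticipant
flip at rate `mu` on top of participant-strategy mutation, and a
per-target flip probability `mu` (total `2mu`/`3mu`) — and kept the
uniform rule: in side-by-side sweeps it is the only reading under which
the exit option *raises* long-run cooperation in large groups while
leaving small groups essentially unchanged, which is the phenomenon this
model exists to study. The alternatives inject nonparticipants at a
payoff-independent rate from healthy groups too; that roughly triples the
standing level of nonparticipation but turns the exit option into a flat
tax on cooperation at every group size. The choice matters, and
re-running the experiments under a different mutation kernel only
requires replacing stage 5.

**Payoff positivity.** The imitation rule needs positive payoffs. Payoffs
are clamped below at `1e-9` with a warning; under the default parameters
every occupied subclass payoff is strictly positive (the envelope test
verifies `[0.6, 1 + b)` exhaustively for small groups), so clamping can
only trigger in extreme sensitivity sweeps (for example, very large `p`).

**Replicate seeding.** Replicate `i` of a cell runs under
`root_seed + i − 1`. Cells within a sweep share replicate seeds, giving
common random numbers to matched comparisons (a voluntary cell and its
compulsory baseline), which tightens difference estimates; with `mu = 0`
and no initial nonparticipants the matched trajectories coincide exactly,
a property the test suite uses.

## What the experiments compute

* `fig1_sweep()` — the long-run cooperation surface over `(n, omega)` with
  compulsory baselines (`omega = NA`).
* `fig2_profiles()` — cooperation, defection *and* nonparticipation at a
  low (0.80), moderate (0.925) and high (1.05) `omega` across group sizes.
* `fig3_differences()` — voluntary-minus-compulsory differences per
  behaviour at the moderate `omega`, per group size.
* `sensitivity_sweep()` — one-parameter sweeps over `m`, `mu` or `p`.

Two replicate profiles exist: `scale = "full"` (100 replicates per cell)
and `scale = "reduced"` (10). The test suite and the acceptance script use
the reduced profile with the full 2000-period protocol; the summary
schemas are identical, so full-scale runs are a flag away.

## Behaviour of the model, and a known sensitivity

Under the defaults the compulsory scenario maintains cooperation at high
levels in small groups. At large group sizes (`n` around 120) the
compulsory runs are *bimodal* across seeds: most runs sustain
punisher-backed cooperation, a minority collapse into defection for long
stretches, so cross-replicate dispersion is large and comparisons at
moderate replicate counts carry wide error bars. In the voluntary scenario
a moderate `omega` acts as an escape valve during defector episodes —
defectors in heavily punished groups fall below `omega` and exit, shrinking
defector strongholds until group conflict recolonises them — which
stabilises large-group cooperation noticeably above the compulsory
baseline, while small groups (which rarely collapse) see essentially no
benefit. A very high `omega` (approaching `1 + b − c`) beats every
attainable participant payoff and drains the population into
nonparticipation.

Under the uniform mutation kernel the standing frequency of
nonparticipation at a moderate `omega` is a few percent — exits are
payoff-driven and concentrated in struggling groups. As noted above, flip-
style mutation kernels produce several-fold larger standing
nonparticipation at the cost of reversing the large-group benefit; this is
the single most consequential under-determined modelling choice in this
family of models, and the package pins it explicitly and tests around it.

## What the tests do and do not establish

The suite checks: exact payoff algebra against a brute-force pairwise
oracle on small groups; exhaustive payoff envelopes; binomial error
statistics; the imitation rule's adoption probabilities and its
martingale property under equal payoffs; takeover probabilities;
conservation and scenario invariants; bit-level equivalence between the
compiled engine and the per-agent oracle; and scaled-down (10-replicate)
versions of the headline experiments under the full 2000-period protocol.
All of this establishes correctness *of the simulator with respect to its
stated rules*, and reproducibility of its experiments. It does not
establish that real human groups behave this way: the model world has
fixed group sizes, global random mixing, whole-group cultural replacement
and an exogenous, constant outside option — idealisations chosen to make
the selection forces legible, not to fit data.

## Numerical and edge-case choices

* Counts are exact integers end to end; frequencies are doubles.
* `periods = 0` returns an empty record and the initial state.
* Homogeneous populations with `m = mu = s = e = 0` are exact fixed
  points.
* `N >= 2` and `n >= 2` are required (the imitation and conflict draws
  need another group and another member to exist).
* Compulsory-scenario states containing nonparticipants are rejected with
  an invariant error rather than silently repaired.
* The feasible-`omega` warning, the inert-`omega` note in the compulsory
  scenario, and configuration errors all name the offending field.

## Limitations

* The engine is serial; replicates parallelise trivially by seed but the
  package does not manage workers.
* No checkpointing: a 2000-period run is cheap enough to re-run.
* Heterogeneous group sizes, spatial structure, endogenous `omega`,
  migration of individuals, and assortative conflict pairing are out of
  scope.
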