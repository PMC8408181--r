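---
title: "Reputation dynamics and evolution of generous leading-eight norms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reputation dynamics and evolution of generous leading-eight norms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(leadingeight)
```

## The model

`leadingeight` simulates indirect reciprocity in the donation game.  A
well-mixed population of `N` players interacts for `T` rounds.  Each round a
donor and a recipient are drawn uniformly among ordered pairs; the donor
either cooperates, conferring a benefit `b` on the recipient at own cost `c`
(`0 < c < b`), or defects.  Reputations are binary ("good"/"bad") and
*private*: every player keeps their own opinion of every other player, and
there is no central authority or gossip that synchronizes opinions.  The
state of the population is the binary image matrix `M`, where `M[i, j] = 1`
means player `i` currently regards player `j` as good.  All simulations
start from the all-good matrix.

Behavior is governed by a *social norm* with two components:

* an **assessment rule**: the probability of assigning a good reputation to
  a donor, given the perceived action (C/D) and the observer's current
  images of donor and recipient (8 entries);
* an **action rule**: the probability of cooperating, given the donor's
  self-image and its image of the recipient (4 entries).

After the donor acts, each of the `N - 1` other players independently
observes the interaction with probability `q`, misperceives the action
(C and D flipped) with probability `epsilon`, and updates its own image of
the donor through its assessment rule.  Private updating under noise is what
drives the dynamics: two observers of the same interaction can reach
opposite judgments, and their disagreement then propagates because they
judge the donor's future interactions from different contexts.

## The leading eight and generosity

`leading_eight(1)` … `leading_eight(8)` return the eight deterministic
third-order norms that sustain cooperation under public information.  All
eight agree that cooperation toward a good recipient deserves a good
reputation, that defection against a good recipient deserves a bad one, and
that defection by a good donor against a bad recipient is justified
punishment; their action rules cooperate with good recipients, defect when a
good donor meets a bad recipient, and forgive (a bad donor cooperates with a
good recipient to regain standing).  The eight differ only in the
bad-recipient contexts: `assessment(C, G, B)`, `assessment(C, B, B)`,
`assessment(D, B, B)` and `action(B, B)`.  Within the set, `action(B, B)`
prescribes cooperation exactly where `assessment(C, B, B)` is good, and the
norms come in pairs `(L1, L2)`, `(L3, L4)`, … that differ only in
`assessment(C, G, B)`.  `L3` is Simple Standing, `L6` is Stern Judging, and
`L2` is the consistent-standing norm.  `allc()` and `alld()` are the trivial
norms (all entries 1, respectively 0).

Because the package had to commit to a concrete transcription of the eight
tables, the assignment of indices was validated behaviorally: the `L1` and
`L7` tables reproduce the mixed-population image statistics and
evolutionary responses that identify those norms in the literature on
private assessment (see the acceptance tests), and `L6` is Stern Judging by
construction.

`make_generous(norm, g1, g2)` relaxes a deterministic norm in one direction
only.  Every assessment entry of 0 becomes `g1` (assessment generosity:
occasionally assign a good reputation where the norm says bad) and every
action entry of 0 becomes `g2` (action generosity: occasionally cooperate
where the norm says defect).  Entries of 1 are never touched — players are
forgiving, never spiteful — and one probability applies uniformly to all
applicable contexts ("aligned" generosity).  `g1 = g2 = 0` recovers the
deterministic norm bit for bit.

```{r}
make_generous(leading_eight(6), g1 = 0.05, g2 = 0)
```

## Tunable parameters

| parameter | meaning | default |
|---|---|---|
| `b`, `c` | benefit and cost of cooperation (payoff units) | 5, 1 |
| `q` | per-round observation probability of each non-donor | 0.9 |
| `epsilon` | per-observation misperception probability | 0.05 |
| `g1`, `g2` | assessment / action generosity probabilities | 0 |
| `T` | rounds per reputation simulation | 2e6 |
| `s` | selection strength of the imitation process | 1 |
| `N` | population size | 90 (reputation) / 50 (evolution) |

The defaults are the study conditions used throughout the package's tests
and experiments: mixed-population reputation dynamics use `N = 90` players
in equal thirds (leading-eight norm, ALLC, ALLD) for `T = 2e6` rounds;
evolutionary competitions use `N = 50`, `b = 5`, `c = 1`, `q = 0.9`,
`epsilon = 0.05`, `s = 1`.  "Noisy information" means
`epsilon = 0.05, q = 0.9`; "perfect information" means `epsilon = 0, q = 1`.

## Design decisions in the reputation dynamics

Several details of the round protocol are underdetermined by the verbal
model; the package fixes them as follows and exposes switches where a
different reading is defensible.

* **Donor self-image.**  The action rule consumes the donor's self-image, so
  that entry must be maintained.  The donor updates its own diagonal entry
  `M[donor, donor]` every round, using its own assessment rule applied to
  its *true* action (no misperception).  `sim_config(self_update =)` also
  offers `"with_prob_q"` and `"never"`.
* **The recipient observes like anyone else.**  All `N - 1` non-donors,
  recipient included, observe independently with probability `q` and error
  `epsilon` (`recipient_sees = "always"` is available as the alternative
  reading).
* **Observer context is private.**  An observer judges the donor using its
  *own* current images of donor and recipient, read from the matrix as it
  stood at the start of the round.  Misperception flips only the action,
  never identities or context reputations.
* **Cooperation rates are empirical.**  The pairwise cooperation frequency
  `x_ij` is the realized fraction of cooperations among the interactions the
  ordered pair actually had, not a reconstruction from average images
  through the action rule: the action depends jointly on two correlated
  image entries, so the realized frequency is the unbiased estimator of the
  same quantity.  Pairs that never interacted get `x_ij = 0`; at the default
  `T` every ordered pair interacts hundreds of times, so this convention is
  immaterial.
* **No burn-in by default.**  Time averages run from the first round,
  matching the all-good start of the image matrix; `sim_config(burn_in =)`
  can discard initial rounds.  `exact_stationary_small()` computes the
  expected time average over exactly the same window, so oracle and
  simulator estimate the same quantity even at small `T`.
* **Reproducibility.**  Each run consumes one dedicated random stream
  (xoshiro256++) fully determined by `seed`; the draw order within a round
  is fixed (donor, recipient, action, then per observer in player order:
  observe / misperceive / assess, then the self-update).  Draws whose
  probability is exactly 0 or 1 are resolved without consuming a variate.

## Payoffs and evolutionary dynamics

Payoffs average benefits received and costs paid over co-players,
\deqn{\pi_i = \frac{1}{N-1} \sum_{j \neq i} \left( b\,\hat x_{ji} - c\,\hat x_{ij} \right),}
computed by `payoffs_from_coop()` from the empirical cooperation matrix.

On a much slower time scale players imitate successful norms via a
pairwise-comparison process: a focal player adopts a random role model's
norm with the Fermi probability \eqn{1/(1 + e^{-s(\pi_j - \pi_i)})}.  In the
rare-mutation limit the population is homogeneous almost always, and the
dynamics over the three norms {leading-eight variant, ALLC, ALLD} reduces to
a three-state Markov chain whose transitions are single-mutant fixation
probabilities
\deqn{\rho_{MR} = \Big( 1 + \sum_{i=1}^{N-1} \prod_{k=1}^{i} e^{-s\,(\pi_M(k) - \pi_R(k))} \Big)^{-1},}
where \eqn{\pi_M(k)} and \eqn{\pi_R(k)} are the mean payoffs of mutants and
residents when `k` mutants are present.  The selection strength in this
formula is identified with the `s` of the Fermi rule.  `pairwise_payoffs()`
estimates the profiles by simulating every two-norm composition
`k = 1, …, N-1`; because only two-norm mixtures occur under rare mutations,
the three unordered pairs suffice, and each sweep serves both invasion
directions (the profile of `k` A-mutants among B-residents read backwards is
the profile of `N-k` B-mutants among A-residents).  `transition_matrix()`
embeds the six fixation probabilities into the three-state chain (a mutant
is either of the two other norms with probability 1/2) and
`stationary_distribution()` solves for the selection-mutation equilibrium.
`equilibrium_cooperation()` weights the homogeneous cooperation rates (1 for
ALLC, 0 for ALLD, simulated for the leading-eight norm) by the equilibrium
abundances.

Payoff estimation is the only stochastic ingredient: each composition draws
a child seed derived deterministically from the master seed, and
`replicates` independent runs per composition can be averaged.  Profiles can
be cached to disk (`cache_dir`) keyed by norms, parameters and seed.

## Numerical choices

* The fixation formula is evaluated through cumulative sums of
  \eqn{-s(\pi_M(k) - \pi_R(k))} in log space with a running maximum, so
  strong selection cannot overflow: probabilities like \eqn{10^{-400}} are
  representable as 0 without producing `NaN`.
* The stationary distribution is obtained by a direct linear solve of
  \eqn{\pi W = \pi} with the normalization row substituted in; an
  irreducible chain (all fixation probabilities positive) is required, and a
  reducible one raises an error rather than returning an arbitrary vector.
* `exact_stationary_small()` builds the exact one-round transition matrix of
  the image-matrix chain for `N <= 3` (state space `2^(N^2)`) and obtains
  the limiting distribution from the all-good start by repeated squaring of
  the transition matrix with row renormalization; a final averaging step
  with one extra application of the matrix guards against period-2
  artifacts.  This provides the independent oracle against which the
  simulator is tested.
* The simulator accumulates the time-averaged image matrix lazily (an entry
  contributes to the average only when it flips), so a round costs O(N)
  rather than O(N²) and a full-scale mixed run (N = 90, T = 2e6) takes a few
  seconds.

## What the simulations emulate — and what they do not

The generator reproduces the model's study conditions exactly as configured:
private binary reputations, uniformly random pairing, independent noisy
observation, aligned generosity, and three-norm competition under rare
mutations.  Several features of real reputation systems are deliberately out
of scope: population structure (who interacts with and observes whom),
gossip and any other channel that correlates observers' judgments, apology
or other repair strategies, non-aligned generosity (context-specific
forgiveness probabilities), mirror strategies that invert the meaning of the
labels, and finite mutation rates (which would require simulating the full
three-norm simplex rather than pairwise mixtures).  Passing tests therefore
establish nothing about structured or communicating populations; they
validate the private-assessment model as specified.

## Problem sizes in the test suite

The acceptance tests reproduce mixed-population image statistics at the full
scale above (each such run takes a few seconds thanks to the compiled core).
Evolutionary reproductions run at `rep_T = 2e5` rounds per composition with
2 replicate seeds — enough to estimate equilibrium abundances to a few
percentage points, which is the tolerance those tests use.  The qualitative
generosity-response checks (cooperation maximal at zero generosity for `L1`
and `L2`, an interior optimum in `g2` for `L7`) run at `rep_T = 1e5` with 2
replicates.  The exact-chain oracle comparisons use `N = 2` and `N = 3` with
12–16 independent replicate simulations of `2e4` rounds and a
three-standard-error criterion.

## Known limitations

* Fixation probabilities are exponentially sensitive to payoff-profile noise
  when `s` is large; at the default `s = 1` the reduced-scale estimates are
  stable, but users exploring `s >> 1` should increase `rep_T` and
  `replicates`.
* Equilibrium cooperation attributes a single homogeneous cooperation rate
  to each norm; transient mixed states (which are rare by assumption) are
  ignored.
* The exact oracle is limited to `N <= 3`; beyond that the state space
  (`2^16` at `N = 4`) makes dense enumeration pointless, and only
  statistical checks remain.
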