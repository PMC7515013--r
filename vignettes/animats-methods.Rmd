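---
title: "Markov Brain animats, feedback learning, and integrated information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov Brain animats, feedback learning, and integrated information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(animats)
```

## The model

An *animat* is a simulated organism whose behaviour is controlled by a
Markov Brain: a set of binary nodes updated synchronously by genetically
encoded logic gates. The standard animat has 16 nodes — 4 sensors written by
the environment, 2 motors read as the action, 10 hidden. Each gate reads up
to 4 nodes, looks its input pattern up in a row-stochastic probability
table, samples an output pattern and writes up to 4 nodes. Writes from
several gates combine by OR; nodes no gate writes fall back to 0. A genome
(integers 0–255) encodes the gate list: genes start at the codon pair
(42, 213) and specify type, arities, wiring and the probability payload, so
decoding is a pure function of the genome.

Three gate families matter here:

* **Deterministic** gates: one certain output per input pattern.
* **Decomposable** gates: for each input pattern the genome supplies one
  *factor* per output bit — the bit's independent on-probability — and the
  table row is the outer product of those Bernoulli distributions.
  Factorisability is what makes per-node information quantities
  well-defined; it is the precondition for the integration analysis below.
* **Decomposable feedback** gates: decomposable gates that *learn*. Each
  carries two extra node addresses (positive and negative reinforcement), a
  history of its last 0–3 (input, output) decisions, and per-depth deltas.
  When the reinforcement node is on after an update, every remembered
  decision has its factors moved toward (positive) or away from (negative)
  the emitted bit values by the depth's delta, clamped to
  [`r 0.01`, `r 0.99`], and the affected row is rebuilt from the factors —
  so rows stay decomposable *by construction*, no matter how much learning
  has happened.

Feedback is internal: the reinforcement nodes are ordinary brain nodes that
the evolved network itself must learn to drive. They are read from the
*post-update* state (positive before negative, gates in list order), so a
gate's own consequences can trigger feedback with one step of latency.

Two numerical constants govern learning: the factor clamp `p_min = 0.01`
keeps every table strictly stochastic (a factor pinned at 0 or 1 could
never recover), and deltas are encoded in `[0, 0.5]` — half the probability
scale — so a single reinforcement can never flip a bit's distribution
outright. The probability-table and legacy-feedback variants of these gates
exist behind explicit constructors for comparison, but the default gate
repertoire is deterministic + decomposable + decomposable feedback, because
non-decomposable tables invalidate the per-node terms of the measure below.

## The learning task

The environment is a 2D lattice (64×64 at full scale) with an exterior wall
ring and a few interior obstacles. A goal cell is drawn uniformly among
open cells; every open cell gets its shortest-path distance to the goal and
an arrow pointing at the next cell of a shortest path (unit-weight
4-neighbour graph; neighbour ties broken in fixed N, E, S, W order).
Sensors encode the arrow *relative to the agent's heading* as a one-hot:
idle-signal, turn-right, go-forward, turn-left (a 180° arrow is resolved as
a right turn; the idle signal fires only where no arrow is defined). The
agent is placed 32 steps from the goal with a random heading, gets 512
timesteps, and is respawned 32 steps away each time it reaches the goal.

Crucially, the animat cannot choose movements directly. It chooses one of
four *actions* (the four motor patterns), and a hidden bijection maps
actions to the four *results* (turn left, turn right, idle, forward). There
are 4! = 24 such mappings, enumerated lexicographically; fitness sums goals
over mappings (`Gtotal`), with the brain fully reset before each mapping so
every variant is learned from a naive state. A fixed policy can only
exploit the mappings that happen to suit it; consistently high `Gtotal`
requires learning the current mapping by trial and error within a lifetime.

## Evolution and the line of descent

A generational GA evolves populations (size 100 at full scale) by
tournament selection (size 2, ties uniform) and mutation: per-locus point
mutations (redrawing binomially-many distinct loci uniformly), and
whole-gene duplication/deletion at per-offspring rates, with genome length
bounded to [1000, 20000]. Defaults (point 0.005, duplication 0.05, deletion
0.05) are package choices declared in `mutation_rates()` — the original
experiments do not specify them — and initial genomes are 5000 uniform loci
with 4 planted start codons so founding brains are rarely empty.

Every individual's id, parent, fitness and genome hash are archived; the
*line of descent* (LoD) is the parent chain from a random final individual
back to generation 0, and the most recent common ancestor of the final
population marks the point behind which mutations have fixed. An evolved
animat is an *elite performer* if it reaches goals at least twice as often
with its feedback mechanism enabled as with it disabled (and scores at
all); both evaluations run from the same RNG state so spawn draws match.

## Measuring integration

Atomic phi compares what the whole system carries across one time step with
what its nodes carry individually. With `X_t` the joint state and `X_t^(i)`
node `i`, the package computes, in bits (0·log 0 = 0 throughout):

* the conditional-entropy assembly
  `Φ = Σ_i H(X_t^(i) | X_{t+1}^(i)) − H(X_t | X_{t+1})`, and
* the mutual-information assembly
  `Φ = I(X_t : X_{t+1}) − Σ_i I(X_t^(i) : X_{t+1}^(i)) + Ī`, where
  `Ī = Σ_i H(X_t^(i)) − H(X_t)` is the nonindependence of the node
  variables.

The two are algebraically identical; they are implemented as separate code
paths and compared to 1e-9 in the test suite as a permanent cross-check.
Φ is not sign-constrained in general, but any system whose transition
matrix factorises over nodes has exactly zero Φ, which the tests assert on
independent-coin and copy systems. Closed-form anchors: the 2-node swap
system has Φ = 2 bits, the 2-node XOR-broadcast 1 bit.

Two estimation routes exist:

* **From traces** (`phi_atomic_from_trace`): plug-in (maximum-likelihood)
  empirical distribution over observed consecutive state pairs. No bias
  correction is applied; short traces underestimate entropies, and a trace
  confined to one orbit of a deterministic system reflects that orbit, not
  the full state space.
* **From transition matrices** (`phi_max_h`): the per-time-point variant.
  The brain's tables at one lifetime instant define a TPM over all 2^n
  states; taking the current state as *uniform* (maximum entropy) gives an
  integration measure that needs no environment observation, so it can be
  evaluated before, during and after learning. A brain without feedback
  gates has the same TPM at every instant — its trajectory is exactly flat,
  which the suite asserts to 1e-12.

TPMs are exact (full enumeration of the joint gate outcome space) up to 12
nodes and 20 total gate-output bits; above that they are Monte-Carlo
estimates with a default 64 one-step samples per start state, converging at
the usual `1/sqrt(k)` rate (checked between k = 100 and 10⁴). Sampling
always runs with learning disabled so measurement does not perturb the
gates being measured. Lifetime trajectories snapshot gate tables every 50
timesteps (checkpoints 0, 50, …) and summarise change by the slope of an
ordinary least-squares line with free intercept.

Φ is computed over the brain's full node set by default. Sensors are
clamped by the environment during behaviour but are free variables under
the uniform-state construction; excluding them is possible by building a
smaller brain for analysis, and is deliberately an explicit choice rather
than a hidden default.

## Design choices where the design was open

* **Feedback timing**: reinforcement nodes are read from the new state
  within the same update, letting a gate's consequences reinforce the
  decision that produced them with one-step latency.
* **Both signs firing**: positive feedback is applied before negative, in
  fixed gate order, so outcomes are reproducible.
* **Per-depth deltas**: the genome encodes separate deltas for each history
  depth (three positive, three negative).
* **Genome layout**: fixed-width gene fields (4 input and 4 output address
  loci regardless of arity) so point mutations and duplications rarely
  shift downstream field boundaries.
* **Forward into a wall** is a no-op; the agent keeps its cell and heading.
* **Worlds** default to one world per replicate, reused across generations.
* **Deterministic gates consume no randomness**, so a deterministic brain's
  TPM is recovered exactly from a single sample per state.

## What the synthetic conditions do and do not show

The full study conditions (`paper_profile()`: 64×64 world, lifetime 512,
population 100, 200000 generations, 200 replicates, all 24 mappings per
evaluation) are cluster-scale. The package's working configuration is
`desk_profile()`: 16×16 world with spawn distance 8 (the world's diameter
cannot accommodate 32), lifetime 256, population 50, 2000 generations, 10
replicates, fitness on 6 of the 24 mappings with all 24 retained for final
evaluation and the elite test. These sizes were chosen once, as the largest
round numbers a single workstation CPU handles comfortably, and the test
suite runs them as stated.

At desk scale, evolution reliably lifts line-of-descent performance, but
2000 generations is far too short for the strong within-lifetime learners
the full-scale experiments select; most desk-scale champions are fixed
policies that exploit the subset of mappings suiting them, and elite
performers (the 2× criterion) are rare — the published experiments
themselves found only 13 elites in 200 cluster-scale replicates, so no
elite count is asserted at desk scale. One consequence of training on a
6-mapping subset is that an evolved feedback mechanism specialises to the
trained mappings: it can help substantially there while misfiring on
never-seen mappings. The suite therefore checks "learning does not hurt
the champion" on the mappings the champion was selected on — the
generalisation question belongs to the full-scale conditions, where
fitness covers all 24. Consequently the desk runs
demonstrate the machinery (directional fitness gain, learning never
hurting the final champion, reproducibility) rather than the full-scale
learning phenomenology. The fixtures carry the closed-form physics: the
swap/XOR/copy systems anchor Φ, the corridor world anchors navigation (an
informed policy scores exactly lifetime/32 goals per episode), and the
feedback probe demonstrates that reinforcement-driven sharpening moves
both gate mutual information and Φ.

Real nervous systems differ from all of this in the obvious ways: nodes are
binary, updates are synchronous, learning is a probability-table update
rather than any biophysical plasticity, and the environment is a toy.
The value of the model is that every state is observable and every
information quantity is exactly computable — the properties that make the
integration analysis possible at all.

## Reproducibility

All randomness — gate sampling, spawn draws, selection, mutation — flows
through R's RNG, so `set.seed()` makes every entry point bit-reproducible;
identical config and seed give byte-identical archives and analysis tables.
Archives are newline-delimited JSON stamped with a config hash; worlds,
genomes and lines of descent serialise to plain text.
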