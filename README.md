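# animats

Evolvable Markov Brain animats with lifetime feedback learning and
integrated-information analysis.

## What this is for

How does learning change a nervous system's ability to *integrate*
information? Measuring that in a real brain is out of reach, so this
package provides the standard computational surrogate: **animats** —
virtual organisms controlled by **Markov Brains**, networks of genetically
encoded logic gates over 16 binary nodes (4 sensors, 2 motors, 10 hidden).
Its gate repertoire includes **decomposable feedback gates**, probabilistic
gates whose per-input output distributions factorise into independent
per-bit probabilities *and* whose probabilities change during a lifetime in
response to internally generated reinforcement — a minimal model of
neuroplasticity that keeps every information quantity exactly computable.

The package implements the full experimental stack for researchers in
artificial life / computational neuroscience:

* **Gates**: deterministic, probabilistic, decomposable, and feedback
  variants; factor ↔ row conversions; gate-level mutual information.
* **Genome → brain**: integer genomes with start-codon genes, pure-function
  decoding, point/duplication/deletion mutation.
* **The learning task**: a lattice world with shortest-path arrow fields,
  where the agent picks among four *actions* that a hidden bijection maps
  to movement *results* (left, right, idle, forward). All 24 bijections are
  evaluated per individual; consistent success requires trial-and-error
  learning of each mapping within a lifetime.
* **Evolution**: a generational GA (tournament selection, size 2) with full
  ancestry archiving, line-of-descent reconstruction, and the
  elite-performer criterion (twice the goals with feedback vs without).
* **Integrated information**: atomic phi

  ```
  Φ = Σᵢ H(Xₜ⁽ⁱ⁾ | Xₜ₊₁⁽ⁱ⁾) − H(Xₜ | Xₜ₊₁)
    = I(Xₜ : Xₜ₊₁) − Σᵢ I(Xₜ⁽ⁱ⁾ : Xₜ₊₁⁽ⁱ⁾) + Ī
  ```

  from observed state traces or from transition probability matrices, and
  its per-time-point maximum-entropy variant **Φ_maxH** (uniform current
  state, exact or Monte-Carlo TPM), which quantifies integration before,
  during and after learning, with OLS slopes summarising lifetime change.

The episode and evolution engines are C++ (Rcpp); all randomness flows
through R's RNG, so every result is reproducible from a seed.

## A worked example

```r
library(animats)
set.seed(1)

# Closed-form anchors: a 2-node swap system integrates 2 bits,
# an XOR-broadcast 1 bit, independent copies 0.
phi_atomic_from_tpm(analytic_tpm(make_fixture("swap_brain")))$phi_atomic
#> [1] 2
phi_atomic_from_tpm(analytic_tpm(make_fixture("xor_brain")))$phi_atomic
#> [1] 1
phi_atomic_from_tpm(analytic_tpm(make_fixture("copy_brain")))$phi_atomic
#> [1] 0

# An informed policy on the corridor world walks the 32-cell spawn
# distance over and over: 512 / 32 = 16 goals per episode.
w <- make_fixture("corridor_world")
m <- action_mappings()             # the 24 action-to-result bijections
run_episode(oracle_brain(m[1, ]), w, m[1, ], lifetime = 512)
#> <episode_result> 16 goals in 512 timesteps
#>   actions: left=0 right=0 idle=0 forward=512

# Desk-scale evolution (16x16 world, pop 50, 2000 generations, ~30 s).
set.seed(101)
arch <- run_evolution(desk_profile())
arch
#> <evolution_archive> 2000 generations, population 50
#>   final fitness: mean 36.6, best 46
lod <- line_of_descent(arch)
mean(head(lod$members$fitness, 100)); mean(tail(lod$members$fitness, 100))
#> [1] 23.9
#> [1] 42.03
```

The fitness numbers are `Gtotal` summed over the 6 fitness mappings of the
desk profile; the line-of-descent means show the adaptive gain from the
first to the last 100 ancestors of a random final individual.

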