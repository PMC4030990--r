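---
title: "Methods: firefly-inspired population annealing on protein lattices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: firefly-inspired population annealing on protein lattices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fireflyfold)
```

## The model

A protein of length $n$ is a residue string embedded as a self-avoiding
walk on a three-dimensional lattice: coordinates are pairwise distinct and
consecutive residues occupy adjacent lattice nodes. Two lattices are
supported.

* **Cubic**: the integer grid $\mathbb{Z}^3$; nodes $v_i, v_j$ are
  adjacent when $|x_i-x_j|+|y_i-y_j|+|z_i-z_j| = 1$, so every node has 6
  neighbours.
* **FCC** (face-centred cubic): represented as the integer points with
  even coordinate sum; nodes are adjacent when every coordinate delta is
  at most 1 in absolute value and the deltas sum to 2, i.e. the 12 offsets
  that are permutations of $(\pm 1, \pm 1, 0)$. This keeps all adjacency
  arithmetic integral — a floating-point basis representation would make
  adjacency tests fragile. The unit-length primitive basis is retained
  only for Cartesian export (`fcc_to_cartesian()`), where nearest
  neighbours come out at Euclidean distance 1.

A **contact** is a pair of residues on adjacent nodes that are not
consecutive in the chain. Two energy functions score a conformation
$\tilde\alpha_S$:

* **HP100**: residues are hydrophobic (h) or polar (p) and
  $E = -\mathrm{HH}_c$, minus the number of h–h contacts;
* **contact matrix**: $E = \sum_{i>j} e_{AT(i),AT(j)}\, D(r_i - r_j)$,
  with $e$ a symmetric $20\times 20$ matrix of pairwise contact energies
  and $D = 1$ exactly for non-covalent lattice contacts.

The packaged matrix (`mj_matrix()`) is a transcription of the
Miyazawa–Jernigan (1996) Table 5 contact energies (the solvent-expulsion
variant, units of RT). A second packaged file,
`contact_fcc_synthetic.txt`, is a clearly labelled *synthetic*
hydrophobicity-structured matrix used to exercise the FCC contact-model
pipeline; it reproduces no published potential (see *Limitations*).

## The pull-move neighbourhood

Conformations are explored with pull moves. A move relocates an anchor
residue to a free target site $L$; when the chain bond cannot be kept by
that single relocation, the adjacent residue in the pull direction moves
to a free auxiliary site $C$ (adjacent to both $L$ and the anchor's old
site) and the remaining residues are pulled along previously occupied
sites. Both chain ends may additionally initiate *end drags*: the end
residue jumps to any free site $L$ reachable through a free bridge site
$C$ adjacent to its old position, dragging the chain after it.

One design point deserves emphasis. The classic formulation stops the
pull at the *first* index where the chain reconnects. Exhaustive testing
during development showed that rule is not reversible: after a full-chain
slide, the reverse pull can reconnect *early* (when the vacated end site
happens to be adjacent to the partially restored chain) and therefore
never restores the original conformation. This package instead records
the **propagation extent** in the move itself and enumerates one move
variant per valid stopping point, from the first reconnection up to the
full slide. With the extent part of the move, the exact reverse of every
move is itself an enumerated move. The test suite verifies, exhaustively
over all self-avoiding walks of up to 6 nodes on both lattices, that
every enumerated move (i) yields a valid conformation, (ii) changes no
residue outside its affected range, and (iii) has an enumerated reverse
restoring the original exactly; and that breadth-first search over pull
moves from a straight cubic 5-mer reaches all 726 five-node
conformations. Those checks — not a citation — are the package's evidence
of reversibility and (spot-checked) completeness.

Within the search, a proposal is drawn uniformly from the enumerated
legal move list, so the few geometrically duplicated records (a
two-residue relocation can be described from either direction) weight the
proposal distribution accordingly; enumeration order is deterministic
(sorted), which makes seeded runs exactly reproducible.

## The search

The optimiser is a population-based simulated-annealing hybrid guided by
a firefly-style attraction rule:

1. **Initialisation.** $N$ random self-avoiding walks are grown from the
   origin (uniform choice among free neighbour sites, restart on
   dead-end, retry budget 1000) and each is descended greedily: every
   legal move is evaluated and one strictly improving move is taken
   uniformly at random until none exists. Descent terminates because the
   energy strictly decreases on a finite set.
2. **Election.** The minimum-energy member becomes the *best* member
   (ties broken uniformly at random); a frozen snapshot of its
   conformation anchors the interval.
3. **Steps.** For each of $T$ steps, the best member proposes one pull
   move accepted by the Metropolis rule
   $\exp(-|\Delta E| / T_n)$ with $T_n = t_0\,\theta^{\,n}$
   (defaults $t_0 = 4000$, $\theta = 0.9999$; equal-energy moves are
   always accepted). Every other member proposes one pull move judged by
   the *structural objective*: with $d^t$ the Euclidean distance between
   residue $t$ and the same residue in the snapshot (raw lattice
   coordinates, origin-anchored frame, no superposition), a move
   affecting residues $j..k$ ($m = k - j + 1$) scores
   $\mathrm{sof} = \frac{1}{m}\sum_{t=j}^{k} |d^t_{\text{before}} -
   d^t_{\text{after}}|$. The shared step counter $n$ advances once per
   population step, not once per member.
4. **Re-election.** After $T$ steps all members are energy-evaluated and
   the best member re-elected. The run terminates when an interval sees
   no Metropolis-accepted move for the best member *and* the re-election
   keeps the same member; `max_steps` is a safety cap reported in the
   result, never an error.

### The structural-acceptance ambiguity

The published acceptance rule compares the structural objective at
successive steps, but the objective is defined per move over that move's
affected range, and the intended baseline is not stated. Both defensible
readings are implemented behind `firefly_params(sof_mode = )`:

* `"previous"` (default): a proposal is accepted iff the member's
  previously *accepted* sof value within the interval is at least the
  proposed value; the baseline resets to $+\infty$ at each interval start
  so members are never frozen at a boundary.
* `"monotone"`: a proposal is accepted iff the summed distance to the
  snapshot over the affected range does not increase — a literal
  "move towards the best" reading.

Neither mode is asserted to be the original authors' intent; both are
exercised by the tests and either can be selected per run.

### Evaluation accounting

Cost is measured in objective-function evaluations, not wall time. Each
step costs one energy evaluation (best member) plus $N-1$ structural
evaluations; each of the $k+1$ interval ends costs $N-1$ energy
evaluations (the elected member's energy is already known); greedy
descent of member $i$ costs $\mathrm{Init}_i$ evaluations (its starting
conformation plus every candidate in every sweep). For a run of
$K = kT + T'$ steps,

$$\mathrm{Oval} = \sum_{i=1}^{N}\mathrm{Init}_i + N(kT + T') + (k+1)(N-1),$$

and `run_search()` returns both the raw counters and this closed form;
their exact equality is asserted by the test suite for every run
configuration tried. Two bookkeeping choices close gaps the formula
leaves open: a proposal is counted whether or not it is accepted (and a
step with no legal moves still counts one evaluation per member, a case
unreachable for chains of length at least 2); and termination at an
interval boundary reports $T' = T$ with $k$ one less than the interval
count, while a `max_steps` stop mid-interval reports the partial $T'$.

### Randomness

One integer seed drives everything through R's global RNG (the compiled
loops draw from the same stream), with members updated in a fixed order.
A per-member stream layout would permit parallel member updates; this
implementation is sequential, and the single stream keeps a run exactly
reproducible from `(sequence, lattice, model, parameters, seed)`, which
the tests assert down to byte-identical run summaries.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `N` | 8 | population size; `N = 1` degenerates to plain simulated annealing (zero structural evaluations) |
| `T` | 15 | steps between re-elections; small values keep members from chasing a stale snapshot |
| `t0` | 4000 | initial temperature, in energy units |
| `theta` | 0.9999 | geometric cooling factor per shared step |
| `max_steps` | 5e6 | safety cap on population steps |

The defaults are the study conditions of the method's published
evaluation; they are deliberately not tuned here.

## What the tests do and do not show

Ground truth for small chains comes from exhaustive enumeration
(`enumerate_walks()`, `enumerate_min_energy()`), guarded at 12 nodes
(cubic) / 8 nodes (FCC) because the walk count grows exponentially; the
first step is fixed to quotient the trivial first-bond symmetry (energies
are symmetry-invariant). Oracle tests recompute contacts and both
energies by an independent all-pairs scan over every enumerated
conformation up to 8 nodes (cubic) and 6 (FCC). Toy searches (4–8
residues) recover the enumerated optimum in at least 18 of 20 seeded
runs. Benchmark-scale runs in the tests and the acceptance script are
*step-capped* (800–8,000 steps): they assert progress beyond
initialisation, conformational validity, and exact evaluation
accounting on the real 48-residue inputs — not recovery of the published
minimum energies, which took the original study 35–250 minutes per run.
`run_benchmark_suite()` with a generous `max_steps` is the long-running
path to a full reproduction; `stop_at_reference = TRUE` is a
clearly-flagged deviation (the faithful termination rule never consults
the reference energies).

## Known limitations

* **Contact-matrix provenance.** The packaged Miyazawa–Jernigan matrix is
  a hand transcription; entry-level errors cannot be excluded. More
  importantly, scoring the packaged 48-residue amino-acid benchmarks with
  it yields energies an order of magnitude below the published benchmark
  optima (about $-185$ versus $-26$ for compact conformations), so the
  benchmark source evidently used a differently scaled or normalised
  variant that the available description does not pin down. Contact-model
  results are therefore internally consistent (oracle-checked) but not
  numerically comparable to the published M-J tables. The FCC
  contact-model matrix shipped here is synthetic by construction.
* **Registration of the structural distance.** Conformations live on
  separate lattices and are compared residue-wise in raw origin-anchored
  coordinates with no translational or rotational superposition; no
  alignment procedure is published for this distance, and the
  origin-anchored choice is this package's own.
* **Completeness of the move set** is verified only as a spot-check
  (breadth-first search at 5 nodes, cubic); no proof-level claim is made,
  particularly for FCC.
* Side-chain models, 2D lattices, and off-lattice models are out of
  scope.

## A worked example

```{r example}
res <- run_search("hhhh", "cubic", energy_model("hp"),
                  ff = firefly_params(N = 4, T = 5, max_steps = 500),
                  seed = 1)
res
res$best_energy
res$oval_total == oval_closed_form(res$counters$init_evals,
                                   res$oval$k, res$oval$T,
                                   res$oval$t_prime)
enumerate_min_energy("hhhh", "cubic", energy_model("hp"))$min_energy
```
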