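# fireflyfold

Protein structure prediction on 3D lattices with a firefly-inspired,
population-based simulated-annealing heuristic.

## The problem and who this is for

Predicting a protein's minimum-free-energy conformation is NP-hard even in
heavily simplified settings, so coarse lattice models are the standard
proving ground for new search heuristics: a protein is a self-avoiding walk
on a lattice, scored either by the hydrophobic–polar (H-P) model or by a
20×20 pairwise contact-energy matrix (Miyazawa–Jernigan style). This
package is for researchers in structural bioinformatics and combinatorial
optimisation who want a reproducible, instrumented implementation of a
population-based lattice folder — including exhaustive ground-truth oracles
for small chains and exact evaluation-count accounting for
hardware-independent cost comparisons.

## The method

Conformations live on the 3D **cubic** lattice (6 neighbours,
`|Δx|+|Δy|+|Δz| = 1`) or the **FCC** lattice (12 neighbours, integer points
with even coordinate sum and offsets `(±1, ±1, 0)`). A *contact* is a pair
of residues on adjacent nodes that are not chain neighbours. Energies:

* HP100: `E = −(number of h–h contacts)`;
* contact matrix: `E = Σ_{i>j} e_{AT(i),AT(j)} D(r_i − r_j)` with `D = 1`
  for non-covalent lattice contacts.

The conformational neighbourhood is a reversible **pull-move** set
(single-site pulls, propagating pulls with recorded extent, and end drags;
reversibility is verified exhaustively in the tests). The search keeps a
population of `N` members (default 8). At every step the current best
member (the "brightest firefly") proposes a pull move accepted by the
Metropolis rule `exp(−|ΔE|/T_n)` under the geometric schedule
`T_n = 4000 × 0.9999^n` (the step counter `n` is shared across the
population); every other member proposes a pull move judged by its
structural attraction towards a frozen snapshot of the best conformation —
the mean absolute change, over the move's affected residues, of their
Euclidean distances to the snapshot. Every `T = 15` steps the best member
is re-elected. Cost is reported as the total objective-evaluation count

```
Oval = Σ_i Init_i + N(kT + T′) + (k + 1)(N − 1)
```

which the package recomputes from raw counters and as the closed form, and
asserts equal.

## A worked example

```r
library(fireflyfold)

res <- run_search("hhhh", "cubic", energy_model("hp"),
                  ff = firefly_params(N = 4, T = 5, max_steps = 500),
                  seed = 1)
res
#> <run_result: best energy -1, Oval 2932, max_steps after 100 interval(s)>
res$best_energy
#> [1] -1
enumerate_min_energy("hhhh", "cubic", energy_model("hp"))$min_energy
#> [1] -1
```

The search recovers the exhaustively verified optimum of the toy chain
(−1: one h–h contact, the square conformation), and its total cost — 2932
objective evaluations here — decomposes exactly into the closed form above
(`k = 99` complete 5-step intervals plus `T′ = 5`). Repeated seeded runs
over a problem set come back as a benchmark table:

```r
run_benchmark_suite("hhphph", "cubic", energy_model("hp"),
                    ff = firefly_params(N = 4, T = 5, max_steps = 300),
                    n_runs = 3, seeds = 1:3)
#>       id length Z_min Z_avg Oval_min Oval_avg Oval_max
#> 1 hhphph      6    -2    -2     2361     2528     2632
```

`Z_min`/`Z_avg` are the minimum and mean best energies over runs and the
`Oval` columns the evaluation-count statistics. The twenty standard
benchmark problems (ten length-48 h/p chains, six length-48
Miyazawa–Jernigan chains, four 54–61-residue FCC problems) ship with their
published reference energies:

```r
load_benchmark("HP1")
#> <benchmark HP1: 48 residues (h/p)>
reference_energy("HP1", "cubic", "hp")
#> [1] -32
round(speed_up(74.57e6, 16.02e6), 1)  # published-count ratio utility
#> [1] 4.7
```

A thin command-line wrapper is installed with the package
(`inst/scripts/fireflyfold`): subcommands `fold`, `energy`, `enumerate`
and `benchmark`, with every run summary recording the full effective
configuration and seed.

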