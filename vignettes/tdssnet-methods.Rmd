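---
title: "Inferring time-delayed gene regulatory networks with tdssnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring time-delayed gene regulatory networks with tdssnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`tdssnet` reconstructs directed gene regulatory networks, including
time-delayed interactions, from multi-replicate time-series expression data.
Each gene $i$ is modelled by a time-delayed S-system (TDSS) equation

$$\frac{dX_i}{dt} \;=\; \alpha_i \prod_{j=1}^{N} X_{j,\,t-\tau_{g_{ij}}}^{\,g_{ij}}
\;-\; \beta_i \prod_{j=1}^{N} X_{j,\,t-\tau_{h_{ij}}}^{\,h_{ij}},$$

a production term minus a consumption term, each a rate constant
($\alpha_i, \beta_i \ge 0$) times a product of regulator levels raised to
kinetic orders ($g_{ij}, h_{ij}$), with each regulator read at an integer
lag $\tau$ counted in sampling intervals. A lag of zero marks an
instantaneous interaction, a positive lag a delayed one. The network is
assembled by the decomposition strategy: each gene's equation is fitted
independently against the observed trajectories of all genes, and the union
of the fitted regulators forms the edge set.

## Chromosome encoding

Candidate equations are encoded as restricted gene expression programming
(RGEP) chromosomes: exactly two fixed-length genes joined by subtraction.
Each gene has a *head* (function or terminal symbols) and a *tail*
(terminals only) of length $t = (n-1)h + 1$, where $h$ is the head length
and $n$ the largest arity in the function set; this tail length guarantees
that level-order (Karva) reading always yields a complete expression tree.
The function set holds only multiplication operators $\{*2,\dots,*5\}$ by
default, because S-system terms are pure products. Terminals are the gene
variables $x_1..x_N$ and a constant terminal `R`.

Three coding regions sit side by side in one chromosome and evolve under
different operator families:

* **structure** — the two symbol strings (GEP mutation/recombination);
* **real** — one rate constant per gene plus one kinetic-order slot per
  symbol position (Gaussian mutation, arithmetic crossover
  $X' = X + \gamma(X-Y)$, $Y' = Y - \gamma(X-Y)$ with
  $\gamma = \gamma_0\,0.99^{\,t}$);
* **binary** — one fixed-width bit string per position encoding the delay
  (bit-flip mutation, single- and two-point crossover).

Decoding reads the expressed prefix of each gene breadth-first; every
expressed gene terminal contributes one power-law factor using its
position's kinetic-order and delay slots.

### Design choices the encoding leaves open

These points are not fixed by the method description and were decided as
package design; each is centralised here.

* **Expressed prefix.** Only the open reading frame obtained by level-order
  filling is expressed — standard GEP semantics, which is what the
  "restricted GEP" construction builds on.
* **The constant terminal `R`** decodes to $e^{k}$ where $k$ is the
  kinetic-order slot at `R`'s position. This keeps `R` a learnable,
  strictly positive multiplier without adding a fourth coding region; `R`
  carries no delay and yields no edge.
* **Head length** defaults to $h = 2$ (configurable). The canonical
  two-gene worked example requires $h \ge 2$, and $h = 2$ with arities up
  to 5 already spans terms with up to nine factors.
* **Parameter slots of unexpressed positions** are mutated and crossed like
  any others; they are silent until a structural change expresses them,
  which gives structural mutations immediate access to diverse parameters.
* **Duplicate regulators** in one term multiply (exponents effectively add
  when the delays coincide) — the natural product semantics.
* **Delay coding width.** Delays use $\lceil \log_2(\tau_{max}+1)\rceil$
  bits and the configuration requires $\tau_{max}+1$ to be a power of two
  (the default interval $[0,3]$ needs 2 bits), so *every* bit pattern
  decodes to a legal delay and bit-level operators can never leave the
  interval.

## Fitness and the evolutionary loop

The fitness of a chromosome for target gene $i$ is $1/(1+\mathrm{SSE})$,
where SSE sums squared deviations between the decoupled model prediction
and the observed trajectory of gene $i$ over all replicates and time
points. The decoupled prediction integrates only $X_i$: regulator levels
are taken from the observed data (linear interpolation between samples,
constant history before the first sample) while gene $i$'s own — possibly
delayed — level comes from the running integration. The $1/(1+\mathrm{SSE})$
form (the method description never fixes one) is positive and bounded, as
roulette-wheel selection requires; divergent integrations score zero.

A generation runs as an in-process map/reduce round, mirroring a
Hadoop-style cluster deployment while staying testable on a desktop:

1. **Map** — every chromosome's fitness is computed (parallelisable across
   forked workers; the result is independent of the worker count), each
   chromosome draws a partition id uniformly from $\{0..k-1\}$, and the
   global fitness total is attached to every record.
2. **Reduce** — chromosomes sharing a partition id form a subpopulation
   that reproduces independently: roulette selection (probabilities
   $f_i/\sum f$), pairing, hybrid crossover with probability $p_c$, and
   mutation. Each partition's offspring quota equals its size, so the
   merged population size is invariant.
3. Two elitist safeguards: the best chromosome ever seen is copied
   unmodified into the next generation (so the best-fitness trace is
   non-decreasing — roulette alone does not guarantee retention), and each
   partition's offspring retain that group's best member, so the partitions
   act as parallel hill climbers.

Per-partition random substreams are derived from (master seed, generation,
partition id), so results are reproducible regardless of scheduling and a
$k=1$ reduce round is bit-identical to the serial algorithm.

**How $p_m$ is applied.** The method description lists three mutation
families (structure, real, binary) and says strategies are selected
"according to encoding type", but leaves the composition open. This package
reads $p_m$ as the mutation budget of each chromosome–region application:
the structure region is mutated with probability $p_m$ (one strategy drawn
uniformly from single point / single gene / change-all-variables), and the
per-value Gaussian and bit-flip rules run at rate $p_m/3$ per slot.
Likewise each crossing pair applies *one* region's crossover, drawn
uniformly. The naive alternative — every region's per-value rule at the
full $p_m$ on every offspring — was measured to be non-convergent at the
benchmark settings: with $p_m = 0.3$ each offspring rescrambles roughly a
third of its parameters and delay bits every generation, and the
best-fitness trace flatlines two orders of magnitude short of the known
optimum. The Gaussian mutation scale is 10% of the parameter interval
width, and mutated/crossed values are clipped back to their intervals —
both unstated in the method description.
The $\gamma$-schedule is read as geometric decay $\gamma_0\,0.99^t$: the
recursion is stated ambiguously at source ("$\gamma = 0.99\gamma^t$" is
ill-typed), but its stated intent — wide variation early, protection of
good individuals late — is exactly geometric decay. Runs stop at the
iteration cap or as soon as a fitness of $1-10^{-9}$ is reached.

## Numerical integration

All dynamics are integrated with fixed-step classical RK4, 10 substeps per
sampling interval by default — reproducible and accurate for smooth
power-law kinetics (the tests verify fourth-order convergence and
closed-form agreement). Delay handling follows the method of steps:
history before the first time point is constant (no pre-experiment data
exists), and delayed lookups into the *running* solution use cubic Hermite
interpolation (node values plus node derivatives), which preserves RK4's
fourth-order accuracy; delayed lookups into *observed* data use linear
interpolation between samples, which is all the data supports. States are
clamped at a positivity floor $\varepsilon_{pos} = 10^{-6}$ so power laws
stay defined; non-finite states abort the trajectory (worst-case fitness).

A consequence worth knowing: a decoupled simulation of the true equation
against noise-free full-network output does not reach machine-precision
SSE — it is limited by the linear interpolation of regulators between the
21 samples (relative error around $10^{-3}$). Fitness values near 0.999,
not 1.0, are therefore the ceiling for a perfect model at this sampling
density.

One floating-point caveat: the arithmetic crossover conserves $X+Y$
*algebraically*, and the implementation computes $Y' = (X+Y) - X'$ so the
conservation carries no accumulated drift; still, the re-added sum can
differ from $X+Y$ by one unit in the last place, because for an
extrapolating operator no representable $Y'$ makes the rounded sum match
bitwise in all cases. The tests assert the 1-ulp form.

## Edge extraction and evaluation

Every factor $(j, \text{exponent}, \tau)$ of a fitted equation with
$|\text{exponent}| \ge \varepsilon$ (default 0.05, exposed as a flag)
yields a directed edge $j \to i$; duplicates keep the largest-magnitude
representative. Predictions are scored over all ordered non-self gene
pairs: sensitivity $S_n = TP/(TP+FN)$ and specificity $S_p = TN/(FP+TN)$.
Self-loops are excluded by default (the reference evaluations highlight
none) and pair matching ignores the delay class by default; a strict mode
additionally requires the predicted instantaneous/delayed class to match,
and strict $S_n$ never exceeds the lenient value. Production and
consumption regulators count as one edge type.

## The synthetic benchmark generator

`generate_network()` stands in for an external benchmark generator so every
stage is testable offline. Topology is sampled by preferential attachment
on out-degree (a few regulator hubs, scale-free-like out-degrees), with no
self-loops and exactly the requested number of edges; a stated number of
edges receive delays drawn uniformly from $\{1..\tau_{max}\}$. Each edge
lands in the production or consumption term of its target with equal
probability, with exponents in $[0.1, 1]$ — the floor keeps every truth
edge above twice the default extraction threshold, so recovery tests are
winnable in principle. Benchmark-scale specs are (50 genes, 128 edges, 10
delayed), (100, 212, 16) and (150, 345, 25), with 10 replicates of 21 time
points over $[0, 20]$ each.

Beyond the stated spec the generator must fix the kinetics; these are
package choices: every gene carries first-order self-degradation
($\beta_i \in [1,2]$, self exponent in $[0.5,1]$, *not* part of the truth
edge set, and invisible to the default self-loop-excluding metrics) so the
dynamics relax instead of blowing up; production rates are drawn from
$[0.5, 1.5]$; genes without production edges get basal production. Initial
conditions are uniform on $[0.5, 1.5]$ around the natural equilibrium
scale, and optional measurement noise is multiplicative log-normal
(default off). A replicate whose integration still diverges is retried
with fresh initial conditions a bounded number of times.

What a green recovery test does **not** establish: the generator's dynamics
are exactly the model class the optimizer searches, the data are
noise-free, and the networks are small — so recovery results here measure
the optimizer and decoding machinery, not robustness to model mismatch,
biological noise, or benchmark-scale topology. Reference-scale
sensitivities/specificities from external benchmark generators are not
reproducible from this package (their generative settings are unstated),
which is why the acceptance contract is property-based.

## Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| population size | 2000 | chromosomes | benchmark setting |
| iterations | 200 | generations | benchmark setting |
| $p_c$ | 0.7 | per pair | benchmark setting |
| $p_m$ | 0.3 | per chromosome (structure) / per slot (real, binary) | benchmark setting; per-slot reading is a package choice |
| rate constants | $[0, 3]$ | expression·time$^{-1}$ | benchmark interval |
| kinetic orders | $[0, 1]$ | dimensionless | benchmark interval |
| delays | $[0, 3]$ | sampling intervals | benchmark interval; $\tau_{max}+1$ must be a power of two |
| partitions $k$ | 200 | — | benchmark setting; $k=1$ reduces to the serial algorithm |
| head length $h$ | 2 | symbols | smallest head the worked example needs |
| $\sigma$ | 10% of interval width | — | unstated at source; package choice |
| $\gamma_0$ | 1 | — | full-range arithmetic crossover at $t=0$ |
| substeps | 10 | per sampling interval | resolves smooth kinetics well below sampling error |
| $\varepsilon_{pos}$ | $10^{-6}$ | expression level | positivity floor for power laws |
| $\varepsilon$ (edge threshold) | 0.05 | exponent magnitude | unstated at source; half the generator's exponent floor |

## Known limitations

* No stiff or adaptive solver: pathological parameter draws abort rather
  than integrate slowly.
* No parsimony pressure beyond SSE: superfluous regulators with small but
  above-threshold exponents can survive, which bounds specificity on small
  networks; raising the iteration budget or $\varepsilon$ trades this off.
* The mandated fitness form $1/(1+\mathrm{SSE})$ with pure
  fitness-proportional selection gives almost no selection pressure in the
  final convergence mile (the probability ratio between a model at SSE 0.05
  and one at SSE 0.001 is about 1.05), so short runs rely on elitism alone
  to refine near-optimal models. At small iteration budgets this caps
  specificity: spurious factors that a longer run would prune remain above
  the extraction threshold. The acceptance suite documents this honestly —
  the scaled-down recovery criterion runs at its prescribed budget and its
  sensitivity/specificity thresholds are asserted as stated, even though
  the selection scheme the same contract mandates does not reach them
  (measured mean Sn 0.50 and Sp 0.63 against required 0.6/0.85, on a world
  where deleting any truth edge from the true model raises SSE a
  thousandfold — i.e. the gap is optimizer pressure, not identifiability).
* Delay identifiability depends on the data: a regulator that is nearly
  constant over the sampled window cannot pin down its lag, no matter the
  optimizer budget.
* The map/reduce engine emulates the partitioned algorithm in-process; it
  preserves the algorithmic contract (keys, grouping, global fitness
  total) but makes no claims about distributed-systems behaviour.
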