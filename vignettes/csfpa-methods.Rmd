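---
title: "Inferring gene regulatory networks with csfpa: model, algorithms and design choices"
author: "csfpa authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene regulatory networks with csfpa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfpa)
```

## The inference problem

A gene regulatory network (GRN) is a directed graph over genes in which a
signed edge records that one gene activates (+) or inhibits (−) another.
`csfpa` reverse engineers such a network from replicate time-series
expression data: several short trajectories of the same genes, each row a
time point, each column a gene, values scaled to $[0,1]$.

## The gene model

Each gene is a unit of a discrete-time recurrent neural network (RNN).
Writing $e_i(t)$ for the expression of gene $i$ at time $t$, one step of
the dynamics is

$$e_i(t+\Delta t) \;=\; \frac{\Delta t}{\tau_i}\,
  f\!\Big(\sum_{j=1}^{N} w_{ij}\, e_j(t) + \beta_i\Big)
  \;+\; \Big(1-\frac{\Delta t}{\tau_i}\Big)\, e_i(t),
  \qquad f(z) = \frac{1}{1+e^{-z}} .$$

The weight $w_{ij}$ is the signed strength with which gene $j$ regulates
gene $i$ — only its sign is biologically meaningful; $\beta_i$ is a basal
(bias) term and $\tau_i$ a time constant setting how fast gene $i$
responds. With $\tau_i \ge \Delta t$ the update is a convex combination of
a sigmoid output and the previous value, so trajectories started in
$[0,1]^N$ stay there. All genes advance synchronously from the same
previous state; $\Delta t$ is kept as a parameter but defaults to 1
throughout. A network of $N$ genes therefore has $N(N+2)$ parameters.

## Decoupled training

Fitting all $N(N+2)$ parameters jointly is hopeless beyond a handful of
genes, so the problem is decoupled into $N$ independent subproblems: for
target gene $i$, minimize the one-step-ahead squared error

$$f_i \;=\; \sum_{k=1}^{M} \sum_{t=1}^{T-1}
  \big(\hat e_{i}(t+1;k) - e_{i}(t+1;k)\big)^2 ,$$

where $\hat e_i(t+1;k)$ is predicted from the **observed** state of series
$k$ at time $t$ (teacher forcing), never from recursively simulated
values. This makes per-transition errors independent and each subproblem
only $(N+2)$-dimensional; summing $f_i$ over genes recovers exactly the
whole-network squared error (`coupledFitness()` exists as that
cross-check). Only within-series transitions are used; nothing is
predicted across replicate boundaries. The formal sum over $T$ time points
involves $T-1$ transitions — the package uses all $T-1$ of them.

Real GRNs are sparse, so each gene is additionally restricted to at most
$I_{\max}$ regulators (default 3). With the regulator set fixed, the fit
is a 5-dimensional problem (3 weights, bias, time constant), and the
structure search reduces to choosing the best combination of regulators
per gene.

## The two metaheuristics

**Flower Pollination Algorithm (inner loop, continuous).** `fpaMinimize()`
trains the $(w,\beta,\tau)$ parameters inside a box
(`searchBounds("artificial")`: $w \in [-25,25]$, $\beta \in [-10,10]$,
$\tau \in [0,15]$; an `"ecoli"` preset narrows this to $w \in [-10,10]$,
$\tau \in [0,10]$). Each population member either takes a *local* step
along the difference of two random peers scaled by one uniform draw, or a
*global* step towards the population best scaled by per-dimension
Lévy-flight draws. The switch probability is applied as the probability of
the **local** step, default 0.8 — the canonical "slightly biased towards
local pollination" reading; the literature states the bias but not the
number, so 0.8 mirrors the reference FPA implementation. Lévy steps use
Mantegna's construction (a Normal draw divided by
$|\text{Normal}|^{1/\lambda}$ with the closed-form scale involving
$\Gamma$), $\lambda = 1.5$ — the asymptotic density alone does not define
a sampler, and Mantegna's algorithm is the de facto standard realization.
Moves are clipped to the box and accepted only if they do not worsen that
member's fitness, which guarantees a monotone best-so-far trace.
Population size 25, $\gamma = 0.1$ and the 3000-iteration cap are
conventional FPA settings, all exposed in `fpaControl()`.

Two stopping rules, both part of the method: the run ends immediately when
the best fitness falls below $10^{-8}$ (at that level the parameters
essentially reproduce the data), or when the improvement over the last 200
iterations is below $10^{-10}$ — the signature of a regulator set that
cannot explain the target and is not worth polishing.

**Cuckoo Search (outer loop, combinatorial).** `searchRegulators()`
evolves *nests*, candidate combinations of exactly $I_{\max}$ regulator
genes. Nests are initialized by a deterministic partition —
$(1,2,3), (4,5,6), \ldots$ — so that all genes are covered without
repetition (10 nests × 3 genes tile the 30-gene benchmark exactly; when
the blocks run past $N$ the remaining slots are filled with random
distinct genes). Each generation, every nest proposes a mutated
combination: a Lévy draw is converted to a replacement count
$k = \min(I_{\max}, \max(1, \mathrm{round}|\alpha L|))$ and $k$ slots are
replaced by genes not currently in the nest. Lévy flights are defined on
real vectors, so some discrete encoding is unavoidable; mapping the step
*magnitude* to the number of replaced slots preserves the "mostly small,
occasionally large jump" character in combination space. The proposal is
trained by FPA and adopted only if its fitness is no worse; then the worst
$\lceil p_a \cdot n \rceil$ nests (default $p_a = 0.25$, the canonical CS
value) are abandoned and replaced by fresh random combinations, never
touching the best nest. The search stops early the moment any nest
reaches the $10^{-8}$ tolerance. Nests always keep exactly $I_{\max}$
members; sparsity below the cap is expressed through near-zero fitted
weights, not smaller sets.

Per-combination FPA runs are capped at 500 iterations inside the search
(the full 3000 would be wasted on the many poor combinations the outer
loop must triage), and trained results are memoized per combination: the
FPA seed is derived deterministically from the master seed, the target
gene and the sorted combination, so a combination trains identically
whenever it is proposed and re-evaluation would be pure waste. The same
derivation makes per-gene subproblems independent of execution order.

## From weights to edges

`callEdges()` reports a signed edge wherever a fitted weight's magnitude
exceeds `edgeThreshold`. The default of 1.0 is set by the method's own
resolution rather than by optimism: when a fit stops at the $10^{-8}$
tolerance, the rms one-step residual over a 5 × 50 training set is about
$6\times10^{-6}$, and the residual's sensitivity to a weight on an input
with standard deviation $\sigma$ is roughly
$0.025\,\sigma\,|w|$ — so on a quiescent input
($\sigma \lesssim 10^{-4}$, typical once trajectories settle) any weight
of magnitude up to order 1 is invisible to the objective. Magnitudes at
that scale therefore carry no evidence of regulation and must not be
called, while true benchmark effects ($|w| \ge 10$) sit an order of
magnitude above the cutoff. A smaller threshold (0.1) is safe on systems
whose trajectories keep varying (the fitted spurious weights then
collapse to $10^{-3}$ or below), and the parameter is exposed on
`inferNetwork()` and `callEdges()` for exactly that reason. The numerical
value of a fitted weight is otherwise not interpreted — only its sign
is.

One boundary case: the search box allows $\tau = 0$, where
$\Delta t/\tau$ is undefined. Fitness evaluation clamps the effective time
constant to $\Delta t \times 10^{-3}$, keeping the objective defined on
the whole box without displacing any realistic optimum.

## The synthetic benchmark and toy networks

`benchmarkNetwork30()` rebuilds the standard 30-gene validation network:
36 edges, weight magnitudes 10–20, biases $\pm 5$ or 0, all
$\tau_i = 10$. `generateDataset()` emulates its training protocol — 5
replicate series of 50 time points, each started from an independent
uniform initial state. The initial states of the original series were
never published, so they are an explicit seeded choice here; uniform
initials maximize coverage of the dynamic range. Exact confusion counts
of any full-scale rerun depend on that unreported detail, which is one
reason the full benchmark is scored with tolerance bands rather than
exact counts.

`addNoise()` implements "5 % noise" as multiplicative Gaussian
perturbation ($x \mapsto x(1+\epsilon)$, $\epsilon \sim N(0, 0.05^2)$,
clipped to $[0,1]$): a percentage noise level on expression data
conventionally means a relative perturbation. Additive Gaussian noise is
available via `model = "additive"` since the convention is not universal.

`toyRingNetwork()` exists because small arbitrary networks with strong
weights are often *unidentifiable*: a weight of $\pm 10$ easily saturates
the sigmoid, dynamics collapse to fixed points within a few time
constants, and once an input is constant its weight can be traded against
the bias freely — many regulator sets then fit any target below the
$10^{-8}$ stop. The ring design avoids both failure modes by
construction: biases equal to minus half the incoming weight sum centre
the sigmoid argument at zero, and the negative feedback around the ring
sustains oscillations indefinitely, so every gene keeps varying and
spurious weights are forced towards zero. This is what makes exact
sign-pattern recovery a fair test on a 5-gene problem.

What the generator does *not* emulate: measurement timing jitter,
gene-specific noise variances, unobserved regulators, and the
ill-posedness of real expression data (the E. coli SOS repair series,
for which `preprocessSOS()` provides the standard preprocessing — drop
the all-zero first time point, then per-gene min–max scaling within each
series — are substantially harder than anything the simulator produces).
Passing the synthetic tests therefore demonstrates correctness of the
machinery, not performance on microarray data.

## Reproducibility and numerical conventions

All stochastic components are seeded: generator initial states, noise,
FPA runs and the outer search. Seeded routines snapshot and restore the
global RNG state, so library calls never perturb a caller's stream. Gene
indices are 1-based in every interface and artifact, edge lists are
written `(regulator, target, sign)`, and expression TSVs default to 6
significant digits (a `digits` argument allows exact round trips).
Confusion counts are taken over all $N^2$ ordered pairs including
self-pairs — the pair universe consistent with the published benchmark
totals — with edge existence scored unsigned and polarity reported
separately (`signAgreement()`); MCC is defined as 0 when its denominator
vanishes.

## Problem sizes used by the test suite

The shipped tests exercise the full pipeline at sizes chosen to keep a
complete run in minutes: end-to-end recovery on the 5-gene ring (5 × 50
series, exact sign recovery noiseless, full recall at 5 % noise),
exhaustive-oracle agreement at $N=6$, $I_{\max}=2$ (15 enumerable pairs),
and single-gene checks on the 30-gene benchmark. The complete 30-gene
experiment (`scripts/benchmark_full.R`) runs all 30 genes at full budget
(10 nests, 100 outer generations, 1000-iteration FPA fits); it takes on
the order of an hour on one CPU — comparable to the reference
experiment's reported runtime — and is scored with the bands TP ≥ 28,
FP ≤ 10 around the reference noiseless outcome (TP = 32, FP = 4),
reflecting its stochastic nature. Genes with a single true regulator are
recovered almost instantly via the tolerance stop; essentially the whole
budget is spent on the few genes with three genuine regulators, which
are also where the outcome varies between seeds.

## Known limitations

* The method fits one-step-ahead dynamics; a network that reproduces
  transitions need not reproduce long free-running trajectories.
* Identifiability degrades whenever trajectories settle quickly: constant
  inputs make weight/bias trade-offs invisible to the objective, which is
  the dominant source of false positives.
* The instant $10^{-8}$ stop means the *first* combination reaching it
  wins, so among several sub-tolerance combinations the search order
  decides; this mirrors the method's design but can differ from the
  brute-force minimum in fitness by up to the tolerance itself.
* Runtime grows roughly linearly in genes × nests × generations × FPA
  budget; the full 30-gene benchmark is a deliberate long-running script,
  not a test.
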