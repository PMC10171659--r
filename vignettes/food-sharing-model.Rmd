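---
title: "Modelling starvation risk on food-sharing networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling starvation risk on food-sharing networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sharenet)
```

## The model

`sharenet` implements a normative model of food sharing in small foraging
groups. A group is a loop-free simple directed network $D = (V, E)$ on $N$
agents with a non-empty subset $H \subseteq V$ of *hunters* — the only
agents who produce food. Four parameters govern the dynamics:

* $p_h \in [0, 1]$ — the probability that each hunter hunts in a time step
  (hunts are independent across hunters and steps);
* $F \ge 1$ — the units of food one prey provides (agents fed per hunt,
  the hunter included);
* $n$ — the life span in time steps (default 1000);
* $k$ — the critical fasting window: $k$ consecutive steps without food
  are lethal (default 10; $1 \le k < n$).

A successful hunt gives the hunter $F$ units: the hunter eats one and
passes the remaining $F - 1$ to a uniformly chosen out-neighbour; every
recipient eats one unit and passes the remainder on, until the units are
exhausted or the holder has no out-neighbour (the remainder is then lost).
All transfers happen inside the time step; there is no storage, no mixing
of packages, and no preferential partner choice.

## Probability of eating

The package's central quantity is the *eating profile*: the probability
$p_e(v)$ that node $v$ receives food at least once in one time step. The
food package performs a random walk of exactly $F - 1$ transfer steps
(fewer if it halts at a node without out-neighbours), so for one hunter $h$
the relevant quantity is the *first-visit* probability $q(h, v)$ that the
walk started at $h$ visits $v$ within $F - 1$ steps. Revisits consume food
but do not create a new eating event: eating is a Bernoulli event per step,
not a quantity. `visitProbabilities()` computes $q$ exactly by making the
target absorbing and propagating the walk's occupation distribution step by
step. Independent hunts then combine by inclusion–exclusion:

$$ p_e(v) \;=\; 1 - \prod_{h \in H} \bigl(1 - p_h\, q(h, v)\bigr). $$

Two consequences worth noting: $p_e(h) \ge p_h$ for every hunter (it always
eats from its own prey), and nodes at directed distance greater than
$F - 1$ from every hunter have $p_e = 0$. A Monte-Carlo simulator of the
literal protocol (`simulateEvents()`) provides an independent check; the
test suite requires agreement within three standard errors on randomized
networks.

Three semantic choices close gaps the protocol description leaves open,
and they are validated jointly by the 28-value worked example shipped as
`fixtureSevenNode()`:

* every receipt consumes one unit, revisits included, so the walk makes
  exactly $F - 1$ transfers unless it halts early;
* a walk revisiting its own hunter does not change $p_e(h)$ (the event
  already happened);
* the uniform out-neighbour choice does not exclude the sender — there is
  no non-backtracking rule.

## Starvation risk: the RV function

Fix a node with eating probability $p_e$. Its life is $n$ i.i.d. steps; a
foodless step is a "success" with probability $q = 1 - p_e$, and a run of
$k$ or more consecutive foodless steps is lethal. Let $G_{n,k}$ count the
*maximal* foodless runs of length $\ge k$ (a run of any length $\ge k$
counts once). `runCountDistribution()` computes the exact law of $G_{n,k}$
by a Markov chain embedding over the states (current run length capped at
$k$, runs counted so far): a fed step resets the run, the $k$-th
consecutive foodless step increments the count. The support is
$0, \dots, \lfloor (n+1)/(k+1) \rfloor$ — the largest number of length-$k$
runs that fit in $n$ steps once separated by single fed steps — and the
exact mean agrees with the closed form $q^k\,(1 + (n-k)\,p_e)$, which the
tests assert to $10^{-9}$.

The *reduction-of-variability* score is the normalized sum of mean and
spread,

$$ \mathrm{RV}(p_e) \;=\; \frac{k+1}{n+1}\,
   \bigl( \mathbb{E}[G_{n,k}] + \sigma[G_{n,k}] \bigr), $$

a heuristic normalized risk of dying within the life span (it is a
normalized moment sum, not an exact death probability). It vanishes at
$p_e = 1$, equals $(k+1)/(n+1)$ at $p_e = 0$, and has an interior maximum
at a probability $p_e^\star$ that splits the model's phenomenology in two:
below $p_e^\star$, feeding a node *raises* its risk score (the
every-man-for-himself regime); above it, feeding pays (progressive
cooperation). For the working regime $n = 1000$, $k = 10$,
`rvArgmax()` locates the maximum at $p_e^\star = 0.089992$ (coarse grid
scan plus golden-section refinement of the exact embedding; the E-only
closed-form argmax $(n-2k)/((n-k)(k+1)) = 0.08999$ corroborates the
location). For fixed $n$, $p_e^\star$ decreases as $k$ grows.

The embedding kernel is implemented in C++ (it sits on the optimizer's hot
path) and `rvFunction()` memoizes evaluations on $(n, k, p_e)$ with $p_e$
rounded to $10^{-12}$, which makes repeated network costing cheap.

## The two network criteria

* **WEF** (welfare): the *population* standard deviation (divide by $N$)
  of the eating profile over all nodes, hunters included — an
  egalitarian-access objective, 0 when access is uniform.
* **RV** (individual starvation risk): the mean of
  $\mathrm{RV}(p_e(v))$ over all nodes, hunters included.

Both conventions (population variance; hunters included in both averages)
are forced jointly by the five-node reciprocity-ladder profiles whose
published costs the acceptance tests reproduce; with sample variance or
hunter-exclusive averaging none of the six values comes out right.
`dominates()` and `paretoFilter()` provide the usual minimization
dominance machinery: $u$ dominates $v$ when it is no worse in both
coordinates and strictly better in one.

## Optimization

Networks are optimized by a comma-selection $(\mu, \lambda)$ evolution
strategy: each generation every parent produces `lambdaRatio` offspring by
one *arc toggle* (a uniformly chosen ordered pair is added if absent,
removed if present — the move set also defines local optimality), and the
next generation is drawn from the offspring only. Single-criterion
selection is by size-$t$ tournaments with replacement ($t = 12$ by
default, chosen for selective pressure; ties break toward lower cost, then
insertion order); the multi-objective variant uses NSGA-II environmental
selection (non-dominated rank, then crowding distance, with fully
deterministic tie-breaking — the published NSGA-II refinement for equal
objective values is not reproducible from available sources, so plain
NSGA-II with documented tie-breaks is used instead). All randomness flows
through the seed in `EvolutionConfig`, so runs are bit-reproducible.

A *local minimum* is a network no single toggle improves
(`isLocalMinimum()`, with a $10^{-12}$ strictness guard);
`evolveSingle()` returns the local minima surviving in the final
population, deduplicated. Two devices stand in for the quotient by
cost-preserving equivalence that a full isomorphism treatment would
require:

* `canonicalReduce()` deletes every arc whose source is neither a hunter
  nor within $F - 2$ steps of one — such a source can never hold two
  units, so the arc lies on no feasible food walk and the cost vector is
  provably unchanged (tests check equality to $10^{-12}$);
* the deduplication signature is the reduced network's eating profile
  split by role (sorted within hunters and non-hunters) plus the cost
  pair rounded to $10^{-9}$. This is an approximation: it identifies
  networks a relabelling-based equivalence would keep distinct only when
  they also price identically.

`bruteForceOptima()` enumerates all $2^{N(N-1)}$ digraphs at $N \le 5$ and
is the oracle for the optimizer's correctness tests.

### Study sizes for the oracle comparisons

The oracle-equivalence studies run at $N = 4$, one hunter (4096 digraphs).
The single-criterion runs use $\mu = 100$, $\lambda/\mu = 8$, 100
generations, ten seeds. This budget is sized to the landscape, not
arbitrary: at $p_h = 0.3$, $F = 3$ the WEF criterion has 229 single-toggle
local minima in six value classes, and only 3 of the 4096 networks attain
the global value against a 66-network second-best class, so a comma
strategy needs both population and generations to escape the larger basin
reliably; the RV landscape is far more benign. The multi-objective study
uses $\mu = 100$, $\lambda/\mu = 8$, 60 generations: the exact Pareto
front at $p_h = 0.08$, $F = 4$ has 32 distinct cost points, and NSGA-II
needs the population to hold the front with a comfortable margin
(roughly $3\times$ its cardinality here, in line with the full-scale
default $\mu = 1000$).

The full-scale defaults (`EvolutionConfig()`: $\mu = 1000$,
$\lambda/\mu = 8$, $t = 12$, $N = 12$) reflect the model's published
working regime and are what `runSweep()` uses unless told otherwise; the
package's tests deliberately run far smaller configurations.

## Descriptive features

`networkFeatures()` computes the battery used to characterize optima.
Choices where conventions diverge:

* *local clustering* and *average intra-partition clustering* (AIC) are
  computed on the undirected simple projection; nodes of degree below two
  contribute 0. AIC averages the per-block mean clustering across blocks
  (not pooled over nodes) of the modularity-maximizing partition.
* *reciprocity* is pair-based: bidirectionally connected unordered pairs
  over connected unordered pairs, `NA` on an arcless network.
* *assortativity* is the Pearson correlation across arcs of the
  endpoints' in-degrees (in-assortativity) resp. out-degrees
  (out-assortativity), `NA` when either side has zero variance, which is
  common on degenerate optima.
* *modularity* is directed Newman–Leicht modularity; `modularitySearch()`
  maximizes it by seeded greedy agglomeration plus single-node-move
  refinement over shuffled restarts. This is a deliberate replacement for
  an MCMC sampler whose settings are not reproducible from available
  sources; its defence is exact-oracle equivalence (exhaustive partition
  enumeration) at small $N$ in the test suite, not sampler fidelity.
  Degree standard deviations are population standard deviations, matching
  the WEF convention.

## The random-network generator

`randomNetwork(N, arcProb, nh, seed)` draws every ordered pair
independently with probability `arcProb` and picks hunters by a seeded
label shuffle. With `arcProb = 0.5` the draw is uniform over all loop-free
simple digraphs, which is what the regime-shift checks use (100 networks
per condition at $N = 12$, two hunters, $F = 4$). The generator emulates
the *null* background against which optima are contrasted; it does not
emulate degree heterogeneity, spatial structure, kinship bias or temporal
rewiring of real sharing networks, so tests passing on it say nothing
about fit to field data — only about the internal consistency of the
model's machinery.

## Numerical choices and degenerate inputs

* Visit probabilities are exact linear-algebra propagations; no sampling
  error enters the analytic path.
* The run-count pmf conserves probability mass by construction; tests
  assert normalization to $10^{-12}$.
* `rvArgmax()` refines a $10^{-3}$ grid with `optimize()` at a tolerance
  one-tenth of the requested resolution.
* Strictness guards of $10^{-12}$ decide cost improvements and
  tie-breaks; dominance uses exact comparisons.
* Degenerate inputs: a network must have at least one hunter (an empty
  hunter set makes both criteria meaningless and is rejected rather than
  priced as all-zero); $F = 1$ means no sharing at all, so canonical
  reduction empties the arc set; `pe = 0` or `1` hit the closed-form ends
  of the RV function; arcless networks give `NA` reciprocity and
  modularity rather than an arbitrary number.

## Known limitations

* The criteria depend on the network only through the eating profile, so
  the signature-based deduplication cannot distinguish structurally
  different networks with identical profiles; the optimizer reports one
  representative per cost-equivalence class.
* The RV interpretation as a death probability is heuristic; only the
  moments of the run count enter the score.
* Trials are i.i.d. within a node's life; correlated food supply is out
  of scope.
* At desk scale the evolutionary searches are validated against
  exhaustive oracles only for $N \le 4$; at the working size $N = 12$
  the package checks qualitative structure (regime shift, cost
  correlations), not global optimality.
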