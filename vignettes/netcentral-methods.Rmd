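---
title: "Methods: edge-parallel shortest-path centrality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: edge-parallel shortest-path centrality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcentral)
```

## The problem

In systems biology, molecular networks — protein–protein interaction maps,
gene co-expression graphs, metabolic networks — are analysed by ranking nodes
with *centrality* measures. The family implemented here is built entirely on
unweighted shortest paths (geodesics). With $\sigma_{st}$ the number of
geodesics between nodes $s$ and $t$, $\sigma_{st}(u)$ those passing through an
interior node $u$, and $d(u,v)$ the hop distance:

* **Betweenness** $BC(u) = \sum_{\{s,t\},\, s \ne u \ne t} \sigma_{st}(u) / \sigma_{st}$
* **Stress** $SC(u) = \sum_{\{s,t\},\, s \ne u \ne t} \sigma_{st}(u)$
* **Closeness** $CC(u) = |R(u)| \big/ \sum_{v \in R(u)} d(u,v)$, the reciprocal
  of the mean distance to the set $R(u)$ of nodes reachable from $u$
* **Eccentricity** $EC(u) = 1 \big/ \max_{v \in R(u)} d(u,v)$

Sums over $\{s,t\}$ run over unordered pairs. All four reduce to one all-pairs
shortest-path (APSP) computation: a breadth-first search (BFS) from every
source, plus, for BC and SC, Brandes-style accumulation over the
shortest-path DAG of each source.

## The edge-parallel APSP formulation

The package's computational core is a *frontier-synchronous, edge-parallel*
BFS. The graph is held as two parallel arrays `head`/`tail` of length
$l = 2m$ — every undirected edge appears once per direction as an "edge slot".
The data-parallel contract, designed for one work item per edge slot, is:

1. At level $t$, **every** slot $(u, v)$ is examined; slots with $d(u) = t$
   and $d(v)$ unset settle $v$ at $t + 1$.
2. A second sweep over the same level accumulates
   $\sigma(v) \mathrel{+}= \sigma(u)$ over all slots with
   $d(v) = d(u) + 1 = t + 1$ and raises a per-slot boolean flag marking the
   slot as lying on a geodesic.
3. The loop stops at the first level that produces no update; the number of
   productive levels equals the eccentricity of the source.

Because a node's distance is written at most once and always with the same
value, the result is independent of the order in which slots are scanned —
whole-array vectorized execution, a literal sequential loop, and a
one-thread-per-edge parallel execution are all equivalent. Edge-parallel
decomposition (as opposed to node-parallel) is the right unit for scale-free
biological networks, whose heavy-tailed degree distributions make per-node
work wildly unbalanced.

Back-propagation processes levels in decreasing distance. For every flagged
slot $(u, v)$:

$$\delta(u) \mathrel{+}= \frac{\sigma(u)}{\sigma(v)}\bigl(1 + \delta(v)\bigr),$$

the classic Brandes dependency recursion; after the sweep, $\delta(v)$ is the
source's betweenness dependency $\sum_t \sigma_{st}(v)/\sigma_{st}$. The same
sweep maintains $f(u) \mathrel{+}= 1 + f(v)$, the number of geodesic
continuations below $u$, from which the source's stress contribution is
$\sigma(u) \cdot f(u)$. Summing per-source contributions over all sources and
halving (each unordered pair is seen from both endpoints) gives BC and SC;
closeness and eccentricity need only the distance vector of each source.

### Predecessor storage

A dense $n \times n$ predecessor matrix makes per-source back-propagation
possible but caps the processable graph size at the memory wall. Since
back-propagation is strictly per-source, the predecessor set of one source is
fully described by one boolean per edge slot ($l = 2m$ bits): slot $k$ is
flagged iff $d(\mathrm{tail}_k) = d(\mathrm{head}_k) + 1$. This is
semantically identical for the recursion and reduces memory from $O(n^2)$ to
$O(n + l)$ per source, which is what lets `apsp()` stream sources.

### Two engines, one contract

The engine exists twice, deliberately:

* `engine = "vec"` — a compiled C kernel scanning all $l$ slots per level
  (the production path; this is where packages of this kind keep their inner
  loops).
* `engine = "ref"` — a line-by-line R transliteration of the per-edge kernel,
  one interpreted iteration per slot.

Both are exported and the test suite requires them to agree — bit-for-bit on
distances, path counts, flags and level counts (the floating-point operations
occur in the same order), and within $10^{-12}$ on dependencies. This encodes
the parallel-semantics claim as a testable contract without GPU hardware. The
reference engine is interpreter-bound (roughly $10^4\times$ slower), so the
full-graph equivalence checks run on small inputs and the large scale-free
instance is spot-checked per source.

### Numerical choices

* Distances are doubles with `Inf` as the unreachable sentinel — strictly
  larger than any attainable hop count, and rendered naturally in output.
* Path counts $\sigma$ (and therefore stress) are doubles: exact for integer
  values below $2^{53}$, documented as approximate beyond. Geodesic counts
  grow combinatorially, and this matches standard Brandes implementations.
* The dependency accumulated at the source itself is meaningless by
  construction; `compute_all()` zeroes it before summing.
* `accumulate_dependencies()` refuses a result whose `delta` is not all zero,
  turning an easy double-accumulation bug into an immediate contract error.

### Conventions pinned here (the underlying description is silent)

* **Pair counting** is over unordered pairs, realized as directed per-source
  accumulation halved at the end — the standard undirected convention.
* **Betweenness is unnormalized by default**; `normalize = TRUE` divides by
  $(n-1)(n-2)/2$. Output headers state the choice.
* **Closeness/eccentricity on disconnected graphs** average/maximize over
  reachable nodes only; isolated nodes score 0. This keeps every score finite
  without inventing penalty terms, and is stated in the function
  documentation rather than hidden.
* **Node labels** are arbitrary strings mapped to contiguous 1-based indices
  in first-seen file order (0-based in the array formulation's original
  habitat; 1-based is the R idiom). Output tables restore original labels.
* Self-loops are a hard error (shortest-path semantics are undefined on
  them); duplicate edge lines collapse silently; graphs are simple,
  undirected, unweighted throughout.

## The synthetic-network generator

`generate_ba(n, beta, seed)` implements Barabási–Albert preferential
attachment, the model used to benchmark this class of algorithms: new nodes
arrive one at a time and connect to `beta` distinct existing nodes with
probability proportional to current degree, via the repeated-endpoints pool
(a node appears once per incident edge endpoint; duplicate draws for one new
node are rejected). The initial condition — `beta` isolated seed nodes, with
the first arrival attaching to all of them — is the common convention and
fixes the edge count at exactly $\beta(n-\beta)$, which the tests assert. The
generator is deterministic given `seed` (R's Mersenne-Twister, caller's RNG
state preserved); bit-identity with other implementations of the model is not
promised, only the structural invariants (edge count, simplicity,
connectivity, hub formation).

What the generator emulates: the heavy-tailed degree distribution, hubs, and
short diameters of real interactomes, at sizes the test budget allows
(hundreds to thousands of nodes versus the $10^4$–$5\times10^4$ of the
original benchmarks). What it does not: degree correlations, modularity,
clustering, and annotation biases of curated biological networks. A green
test therefore establishes algorithmic correctness and scalability shape, not
biological realism of any ranking.

## Validation strategy

* **Worked examples** (3-path, star, 4-cycle, $K_4$) with hand-derived exact
  values for all four metrics.
* **A brute-force oracle**, `oracle_centrality()`, independent of the engine:
  distances from adjacency-matrix powers, every geodesic of every pair
  enumerated explicitly (guarded to $n \le 14$), metrics computed as literal
  sums over enumerated paths.
* **Property tests**: distances versus a textbook queue-based BFS on 100
  seeded random graphs; $\sigma$ versus exhaustive enumeration; the
  dependency identity $\sum_{v \ne s}\delta_s(v) = \sum_t (d(s,t) - 1)$;
  conservation $\sum_u BC(u) = \sum_{\{s,t\}}(d_{st}-1)$ and
  $\sum_u SC(u) = \sum_{\{s,t\}}\sigma_{st}(d_{st}-1)$ on connected graphs;
  dominance $SC \ge BC$; uniform scores on vertex-transitive graphs;
  radius–diameter bounds; engine equivalence; byte-identical CLI reruns.
* A cross-check of betweenness against igraph on connected random graphs.

## Known limitations

* Unweighted, undirected, simple graphs only — weighted geodesics
  (Dijkstra/Δ-stepping), directed variants and multigraphs are out of scope.
* The APSP pass is $O(n \cdot D \cdot l)$ with $D$ the diameter; fine for
  sparse scale-free networks ($D$ small), quadratic-ish in dense pathological
  cases. No approximate/sampled betweenness is offered.
* Stress inherits the $2^{53}$ exactness bound of double-precision path
  counts.
* Single-threaded: the edge-parallel contract is *expressed and tested*, not
  executed on parallel hardware here.
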