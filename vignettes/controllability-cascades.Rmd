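---
title: "Driver nodes under cascading edge failures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driver nodes under cascading edge failures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctrlcascade)
```

This vignette documents the models implemented in `ctrlcascade`, the
conventions and numerical choices behind them, and what the synthetic
experiments can and cannot say about real networks.

## Structural controllability by maximum matching

For linear time-invariant dynamics $\dot{x} = Ax + Bu$ on a directed
network of $N$ nodes, controllability is decided by the Kalman rank
condition on the controllability matrix. For almost every choice of edge
weights, the minimum number of independent inputs follows from the graph
structure alone: take a maximum matching $M^*$ — a largest set of directed
edges in which no two share a source and no two share a target, found as a
maximum bipartite matching on the out-copy/in-copy representation — and
attach one input to each node that has no inbound matched edge. Hence

$$N_D = \max(N - |M^*|, 1).$$

The package never integrates the dynamics or forms the Kalman matrix
(numerically hopeless and unnecessary); only the matching criterion and,
as a cross-check, the eigenvalue rank condition below are computed.

Conventions worth stating:

* **Perfect matchings.** When $|M^*| = N$ (e.g. a cycle), zero unmatched
  nodes remain, but a system still needs at least one input. We report
  $N_D = 1$ and attach the input to the lowest-id node; with a perfect
  matching every node lies on a matched cycle, so the choice is a pure
  tie-break.
* **Driver sets are not unique.** Different maximum matchings leave
  different node sets unmatched; only the *count* is invariant. The
  package returns one deterministic representative and tests only assert
  the count.
* **Edge categories.** An edge is *critical* if removing it raises $N_D$,
  *redundant* if it lies in no maximum matching, *ordinary* otherwise.
  Rather than re-matching per edge, `classify_edges()` builds the
  flow-residual digraph of one maximum matching (unmatched bipartite edge
  $u^+ \to v^-$, matched edge $v^- \to u^+$, a source/sink pair joined to
  free copies) and reads both properties off its strongly connected
  components: a matched edge whose copies share a component can be
  rerouted around (ordinary), otherwise it is in every maximum matching
  (critical); an unmatched edge whose copies share a component is in some
  maximum matching (ordinary), otherwise in none (redundant). Under a
  perfect matching no edge can be critical — $N_D$ sits at its floor of 1
  — so matched edges that cannot be rerouted are reported ordinary. The
  whole classification is two linear-time passes, and it is validated
  against exhaustive matching enumeration in the tests.

## Exact controllability

For a *specific* weighted adjacency matrix $A$, the minimum input count is
$\max_\lambda (N - \mathrm{rank}(\lambda I - A))$ over distinct
eigenvalues — the largest geometric multiplicity. `exact_driver_count()`
supports identical weights (all ones) and random weights (uniform on
$(0,1]$, seeded). Numerical choices, stated because they define
reproducibility:

* eigenvalues are grouped as equal by absolute tolerance $10^{-8}$;
* rank is the number of singular values above
  $\max(\mathrm{dim}) \cdot \varepsilon \cdot \sigma_1$;
* groups of algebraic multiplicity 1 are skipped (geometric $\le$
  algebraic), **except** $\lambda = 0$, which is always evaluated exactly:
  defective zero eigenvalues of nilpotent blocks scatter numerically over
  a radius $\sim \varepsilon^{1/k}$, far beyond any fixed grouping
  tolerance, while $\mathrm{rank}(A)$ at $\lambda = 0$ itself is computed
  reliably.

With random weights the exact count coincides with the structural count
(asserted over ER and SF samples in the acceptance tests); with identical
weights degenerate spectra may demand extra inputs, which is reported but
deliberately not asserted.

## Loads, capacities, cascades

The load of an edge is the **raw count** of shortest directed paths
through it, summed over all ordered pairs; equal-length alternatives each
count fully. This follows the load model's plain reading; the
Brandes-fractional variant (each pair contributes 1 split across its
shortest paths) is available via `compute_loads(g, fractional = TRUE)` for
sensitivity analysis but is not used by the experiments. The raw count is
computed in C++ by per-source BFS with path-count accumulation
($O(NM)$ per graph), against a brute-force path-enumeration oracle in the
tests.

Capacities are fixed once on the intact graph, $C_e = (1+\alpha)L_e(0)$,
and never updated. A cascade then iterates: remove the current failure
set, recompute all loads on the residual graph, fail **all** edges with
$L_e > C_e$ simultaneously, record the stage, stop when nothing is
overloaded. Further conventions:

* **Strict inequality.** Capacity is the maximum load an edge can handle,
  so $L_e = C_e$ survives; with $\alpha = 0$ an edge whose load does not
  increase never fails.
* **Stage 0** is the state right after the attack, before any overload;
  `total_failed` excludes the attacked edges, which are tracked
  separately.
* **Monotone instrumentation.** Edges are only ever deleted, so matchings
  only shrink and the per-stage driver count is non-decreasing along any
  single cascade — asserted as an invariant.
* Termination within $M$ stages is guaranteed (each stage removes at
  least one edge).

The SCC statistic recorded per stage is the number of edges inside
strongly connected components of size $\ge 2$. Whether the source text of
this statistic means the largest component only is ambiguous; after heavy
cascades "the largest" is ambiguous under ties, so the default counts all
nontrivial components (stable under ties) and `largest_only = TRUE` (with
a lowest-node-id tie-break) gives the other convention.

## Attacks

* **RA** removes a uniform random sample of $\mathrm{round}(f M)$ edges.
* **IA** removes the $\mathrm{round}(f M)$ edges of highest **initial**
  load. Ranking by initial loads fixes the basis: all edges are removed in
  one batch before the cascade, with no sequential re-ranking. Ties at the
  cutoff load are broken uniformly at random under the given seed, so the
  result cannot depend on edge input order.
* Rounding is half-away-from-zero with a minimum of one edge whenever
  $f > 0$; the single highest-load-edge trigger is IA sized to one edge.

## Synthetic networks

The generators stand in for real directed networks (internet overlays,
neural wiring, food webs) whose degree heterogeneity and strongly
connected cores drive the phenomena:

* `generate_er(n, k, seed)`: each ordered pair independently with
  $p = \langle k\rangle/(N-1)$. Degree convention throughout:
  $\langle k\rangle := M/N$, i.e. mean out-degree = mean in-degree, which
  makes both $p$ and the SF edge budget unambiguous.
* `generate_sf(n, k, gamma, seed)`: **static model** — node $i$ carries
  weight $i^{-1/(\gamma-1)}$, and $M = \mathrm{round}(N\langle k\rangle)$
  distinct edges are drawn with both endpoints sampled proportionally to
  the weights (self-loops and duplicates rejected, with a bounded number
  of rounds). This was chosen because it controls $\gamma$ and
  $\langle k\rangle$ independently for *directed* graphs; growth-type
  (preferential-attachment) constructions tie them together. In- and
  out-degrees are sampled independently, an assumption real networks can
  violate (degree correlations); the tests verify the tail exponent
  recovers $\gamma \in \{2.2, 2.5, 3.0\}$ within $\pm 0.6$ on pooled
  degree sequences.
* Generators are pure functions of their parameters and seed; sparse
  settings may produce disconnected graphs, intentionally — the sparse
  regime of the experiments depends on it.

What passing tests on these generators do **not** show: behaviour under
degree correlations, community structure, or weighted/temporal edges, none
of which the generators emulate. The pipeline accepts arbitrary edge lists
(`read_edge_list()`, 0-based pairs with an optional `#nodes N` header) so
real networks can be run through the identical experiments.

## Experiment design and study conditions

Experiments are driven by `experiment_config()`: model, $N$,
$\langle k\rangle$, $\gamma$, $\alpha$, strategies, $f$-grid, realization
count, master seed. All per-realization and per-cell seeds derive from the
master seed in one stream, so every table is byte-reproducible.

Defaults, chosen once as desk-scale study conditions: $N = 500$,
$\alpha = 0.3$, 50 realizations, $f$ from 0 in steps of 0.05,
$\langle k\rangle \in \{1.5, 3, 6, 10\}$ (sparse / moderate-sparse /
moderate-dense / dense), $\gamma \in \{2.2, 2.5, 3.0\}$. The sparse SF
experiments use $\langle k\rangle = 1.5$ — the same sparse value as the
ER runs, which is exactly the contrast of interest: at that density ER
networks barely cascade while SF hubs keep a strongly connected core that
does. The `analysis/` scripts use $N = 300$ with 20 realizations so each
runs in about a minute; the acceptance checks use the full conditions.

Stage-wise averages across realizations align traces by stage index and
pad shorter traces with their terminal value. Failed-edge censuses are
taken against the **intact-graph** classification: categories recomputed
on the shrinking residual would conflate what the attack destroyed with
what the destruction reclassified. Cells with no failed edge have an
undefined census; they are flagged and excluded from census averages with
a recorded count.

Qualitative claims (damage peaking at moderate $\langle k\rangle$; RA vs
IA driver-count orderings by $f$-region; census contrasts) are asserted as
one-sided $t$-tests on realization means at the 0.05 level — paired by
realization where both strategies share a graph — never as point-value
curve matching. The removal-fraction scan for the quenching analysis runs
to $f = 1$: with $\alpha = 0.3$ and $\langle k\rangle = 6$ the intentional
attack stops triggering cascades near $f \approx 0.45$ but the random
attack keeps overloading survivors well past $f = 0.8$, quenching only
around $f \approx 0.9$ — the scan must cover the full range to locate the
critical fraction for *both* strategies.

## Known limitations

* Loads are unweighted hop-count shortest-path counts; flow-based or
  weighted load models are out of scope.
* IA is non-adaptive (initial-load ranking); recalculated-load attacks
  and node-removal attacks are not implemented.
* The exact-controllability computation is dense ($O(N^3)$ per candidate
  eigenvalue) and guarded at $N \le 5000$.
* Identical-weight exact counts depend on the stated numerical tolerances;
  pathological near-degenerate spectra between the grouping tolerance and
  machine precision can be mis-grouped.
* The static-model SF generator fixes independent in/out sampling; driver
  increments in networks with correlated degrees may differ systematically
  from its predictions.
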