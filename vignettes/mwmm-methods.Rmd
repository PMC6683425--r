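---
title: "Clustering sign-inverting miRNA-mRNA pairs with the maximum weighted merger method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering sign-inverting miRNA-mRNA pairs with the maximum weighted merger method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwmm)
```

## The problem

MicroRNAs regulate mRNAs, and that regulation can reorganise in cancer: a
miRNA-mRNA pair whose expression is positively correlated across normal
tissue samples may become negatively correlated across tumor samples, or
vice versa. Pairs showing such *sign inversion* (tumor correlation `T_CC`
and normal correlation `N_CC` with `T_CC * N_CC < 0`) are candidates for
regulation that the disease rewires. Given a table of such pairs, the task
is to group the miRNAs and mRNAs into clusters with strong internal
connection and weak connection to the rest of the network, so that each
cluster is a candidate co-regulated module.

The package takes the correlation table as its input format: one row per
pair, columns `mRNA`, `microRNA`, `T_CC`, `N_CC`. How those correlations
were obtained (expression processing, FDR filtering, target-prediction
support) is upstream of this package and out of its scope.

## Edge weights

Each sign-inverting pair becomes an edge of a bipartite graph (miRNAs on
one side, mRNAs on the other) and needs a single non-negative weight
combining `T_CC` and `N_CC`. Six formulas are implemented; writing `t` and
`n` for the two correlations:

| formula | weight |
|---|---|
| integrated mean value | `l1*t + (1-l1)*|n|` if `t > 0`; `l2*|t| + (1-l2)*n` if `t < 0` |
| all negative value | `|n|` if `t > 0`, else `|t|` |
| all positive value | `t` if `t > 0`, else `n` |
| arithmetic mean value | `(|t| + |n|) / 2` |
| geometric mean value | `sqrt(|t| * |n|)` |
| maximum absolute value | `max(|t|, |n|)` |

The integrated mean value weight is the interesting one: its coefficients
are dataset-level statistics. Split `T_CC` into its positive part and the
absolute values of its negative part and average each subset (`m_t_plus`,
`m_t_minus`), and likewise for `N_CC` (`m_n_plus`, `m_n_minus`). Then

    l1 = m_t_plus  / (m_t_plus  + m_n_minus)
    l2 = m_t_minus / (m_t_minus + m_n_plus)

so the two branches weigh the two inversion directions by how strong each
side of the inversion is on average in the whole table. The lambdas are
computed once per dataset - not per cluster, not per round - and
`build_weighted_edges()` does this automatically:

```{r}
tbl <- tibble::tribble(
  ~mrna, ~mirna, ~t_cc, ~n_cc,
  "OBFC1", "hsa-mir-383", -0.092, 0.271,
  "GABBR2", "hsa-mir-452", 0.142, -0.376,
  "MICALL1", "hsa-mir-375", -0.269, 0.305
)
edges <- build_weighted_edges(tbl, "integrated_mean")
attr(edges, "lambdas")
```

Three properties are useful to keep in mind (all property-tested):
the chain `geometric <= arithmetic <= maximum` holds for every record; the
integrated weight is a convex combination, so it always lies between
`min(|t|, |n|)` and `max(|t|, |n|)`; and on a *symmetric* record
(`t = -w`, `n = +w`) all six formulas return exactly `w`.

Records with `T_CC = 0` are rejected by the piecewise formulas rather than
assigned to a branch: the branch conditions cover only `t > 0` and
`t < 0`, and a zero tumor correlation is not an inversion. Strict
filtering (`filter_sign_inversion()`) therefore also drops zero
coefficients (`t * n < 0` fails at zero).

## Comparing the formulas: top-n edge accretion

To rank formulas without committing to a clustering, the package uses
plain edge accretion: sort a formula's edges by weight, add the top `n` to
an empty graph, and count the disjoint connected clusters. A formula
whose strongest edges coalesce into fewer clusters concentrates the
strongest interactions better. `formula_evaluation_curve()` sweeps `n`
over a grid for all six formulas and flags the per-step minimum;
`autoplot()` draws the curves. Ties in edge weight are broken by
(miRNA name, mRNA name) ascending - the ordering is not specified by the
procedure itself, and a fixed rule makes every run reproducible. The
cluster count at step `n` counts only vertices incident to selected edges,
since the graph starts empty.

This accretion procedure is deliberately not used for the final
clustering: it only ever clusters the top-weighted edges and ignores the
rest of the network.

## Stage one: star graphs by iterated bipartite matching

The clustering proper starts from the miRNA x mRNA weight matrix
(`matrix_from_edges()`; zero entries mean "no interaction"). Each round
solves a maximum-weight bipartite matching (rectangular assignment) on the
current matrix, so every miRNA is matched to at most one mRNA and total
matched weight is maximal. The bookkeeping after each round:

1. matched pairs with weight zero are discarded - they are artifacts of
   rectangular assignment, and both their endpoints stay in the matrix so
   they can find real partners later;
2. the columns of mRNAs matched at positive weight are removed;
3. any miRNA row left with all-zero entries is removed.

Rounds repeat until the matrix is exhausted. Each miRNA thereby accretes
leaves one per round, growing a star graph K(1,k) with the miRNA as
internal node; the stars are the atomic clusters. Two structural facts
hold and are tested: the leaf sets partition the mRNAs that had at least
one positive entry, and no mRNA is ever assigned twice. Note that a miRNA
whose only positive mRNAs are all claimed by competitors (the matching
prefers heavier edges elsewhere) can end up with no star at all; the
bookkeeping does not guarantee one star per positive miRNA, although with
realistic many-target data every miRNA typically retains at least one
leaf.

The bipartite solver is delegated to igraph's weighted bipartite matching;
the solver contract (total weight equals the exhaustive-enumeration
optimum) is what the tests pin down, on hundreds of random matrices.

## Stage two: merging clusters by blossom matching

Stars are merged pairwise, round by round. For the current clustering,
every pair of clusters gets a *cross weight*: the summed weight of all
edges connecting them (miRNAs of one to mRNAs of the other, both
directions) divided by the total vertex count of the two clusters. The
divisor is the size-bias control: without it, large clusters would attract
mergers merely by having many vertices. Pairs with zero cross weight are
dropped, and the remaining pairs form an auxiliary graph whose vertices
are clusters.

Each merge round finds a maximum-weight matching on the auxiliary graph -
a general graph, so this is the blossom problem, not the bipartite one -
and fuses every matched pair into one cluster. Unmatched clusters are
carried over unchanged and re-enter the auxiliary graph in all later
rounds; they are only excluded from merging *within* the round in which
they found no partner. (The alternative reading - freezing unmatched
clusters permanently - cannot reach a single final cluster, which the
method demonstrably does on connected data.) Merged cluster ids join the
parent ids with `+`, so the full merge tree is auditable from the id
strings alone.

Rounds repeat until no positive cross weight remains, only one cluster is
left, or `max_rounds` is hit. Every round's clustering is retained in the
returned history: the final single cluster is rarely the useful answer,
and the intended workflow is to inspect the trajectory and pick the round
with the preferred balance of cluster size and count.

No R package in this stack provides maximum-weight matching on general
graphs, so the package implements the classic primal-dual blossom
algorithm (O(n^3) stage structure) directly, in `blossom_matching()`. Its
correctness is established in the test suite by exhaustive-enumeration
oracles on hundreds of random graphs (including tie-heavy integer weights
that force blossom formation) and by agreement with the independent
bipartite solver on bipartite instances. Weights are handled in floating
point; dual updates only ever add and subtract input weights, so slacks
stay exact for terminating decimals and the `<= 0` slack test tolerates
the residual error of general doubles.

## Cluster validity metrics

For a cluster C within a clustering, three sums over the raw edge list:

* `IW` (inner weight): edges with both endpoints in C;
* `E2MROW`: edges from C's miRNAs (emitters) to mRNAs outside C;
* `R2MEOW`: edges from C's mRNAs (receivers) to miRNAs outside C.

Condition one is `IW > E2MROW` (miRNA side only); condition two is
`2 * IW > E2MROW + R2MEOW` - the inner weight is doubled because the
right-hand side counts both outward directions, so the internal connection
is counted once per direction as well. The inequalities are strict, per
their definitions; `non_strict = TRUE` switches both to `>=` for the
degenerate all-zero case that strict comparison fails. Accounting
identities pin the implementation down: summed over all clusters,
`IW + E2MROW` equals the total edge weight, and the global `E2MROW` and
`R2MEOW` totals are equal (each cross-cluster edge is an emitter edge for
exactly one cluster and a receiver edge for exactly one other).

`summarize_rounds()` applies this per round; on connected data the
trajectory ends at one cluster with zero outer weights and both condition
percentages at 100 - the plateau visible in `autoplot()` of a history.

Clusterings are compared with the standard pair-counting adjusted Rand
index (`adjusted_rand_index()`), computed over the intersection of the two
vertex sets. When the chance-correction denominator vanishes (both
partitions trivial in the same way) the index is defined as 1. The
implementation is cross-checked against mclust's to 1e-12 in the tests.

## The synthetic generator

`generate_planted_table()` provides ground-truth data: `n_blocks` blocks,
each owning its miRNAs and mRNAs; dense strong within-block edges
(probability `within_edge_prob`, weights in `within_weight_range`), sparse
weak cross-block edges (probability `cross_edge_prob`, weights in
`cross_weight_range`, required to lie strictly below the within range).
Every sampled edge of target weight `w` becomes a symmetric sign-inverting
record (`t = -w, n = +w` or the mirror, per `direction_prob`), so every
record passes strict filtering and - by the collapse property - all six
formulas reproduce `w` exactly. Pipeline tests are therefore independent
of the formula choice; `asymmetric_variant()` perturbs the records
(preserving signs) when a test needs the formulas to disagree. Defaults
(6 blocks of 2 miRNAs and 10 mRNAs, within probability 0.9, cross
probability 0.02) give a small, clearly separated regime in which the
planted blocks are recoverable: `recovery_score()` reports the adjusted
Rand index of every round against the planted labels, and under the
default configuration the median best-round index across 20 replicate
seeds is at the ceiling of 1.0.

What the generator does *not* emulate: sampling noise in the correlations
themselves, non-inverting pairs, the FDR and target-prediction filters
that shape real tables, and the heavy-tailed target counts of real miRNAs
(real data has a few hundred miRNAs against thousands of mRNAs). Passing
the planted-recovery tests shows the machinery merges what it should merge
when block structure is present and separated; it does not certify
recovery on real tumor data, where no ground truth exists.

## Numerical and design choices

* **Determinism.** All ties are broken by sorted label order; all
  randomness (generator only) flows from one integer seed. Tests assert
  matching *totals*, never one particular optimal matching, since any
  optimum is acceptable.
* **Zero weights.** `T_CC = 0` is rejected by the piecewise formulas;
  zero-weight matched pairs are discarded without removing vertices;
  zero cross weights never enter the auxiliary graph.
* **Printed precision.** Weights are carried at full double precision
  internally; comparisons against 3-decimal printed values use an
  absolute tolerance of 5e-4. Edge-list files render 10 decimals so they
  round-trip.
* **Termination.** The star stage terminates because every round with a
  positive entry removes at least one column, and a round with none
  removes all-zero rows or clears the matrix. The merge stage terminates
  because every retained round performs at least one merge, and the
  cluster count strictly decreases.
* **Problem sizes in the test suite.** Solver oracles use hundreds of
  graphs up to 8 vertices (exhaustive enumeration grows quickly beyond
  that); property tests use 10^4 random records; pipeline and recovery
  tests use the default generator configuration and a larger
  ~2,700-pair, 60-miRNA table for the scale check. These sizes were
  chosen to exercise every code path while keeping the default test run
  fast; the pipeline itself scales to tables with tens of thousands of
  pairs.

## Limitations

* The method emits a partition per round but no rule for choosing the
  round; that choice is left to the user (validity metrics and the
  trajectory plot are the intended aids).
* Clusters are hard: no overlap, no soft membership.
* The integrated weight's lambdas are global statistics; subsetting a
  table changes the weights of untouched rows.
* A miRNA can fail to found a star when all its targets are claimed by
  heavier edges (see stage one); its mRNAs are still clustered.
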