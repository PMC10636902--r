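---
title: "Continuous symmetry and chirality measures: model, algorithms, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous symmetry and chirality measures: model, algorithms, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molsym)
```

## The model

A molecule is a set of N atoms with element symbols, Cartesian coordinates
$Q = \{Q_k\}$ (Å), and an undirected bond graph. The symmetry content with
respect to a cyclic point group $G$ — generated by a single proper rotation
$C_n$ ($n \ge 2$) or improper rotation $S_n$ ($n = 1$ or even; $S_1 = C_s$,
$S_2 = C_i$) — is

$$S(G) = 100\,\frac{M(G)}{D}, \qquad
  M(G) = \min \sum_k |Q_k - P_k|^2, \qquad
  D = \sum_k |Q_k - Q_0|^2,$$

with $Q_0$ the unweighted geometric center and the minimum taken over all
$T$-invariant structures $P$ and all unit axes. $S$ is translation-, rotation-
and scale-invariant, 0 exactly at perfect symmetry, and at most 100 (the value
when the nearest symmetric structure collapses to the center, as it does for,
say, inversion symmetry of a structure whose only admissible permutation is
the identity).

The equivalent permutation form averages the powers of the generator over the
group (order $g$):

$$M(G) = \frac{1}{2g} \min_{\pi,\ \mathrm{axis}}
  \sum_{i=1}^{g} \sum_k |T^i Q_k - Q_{\pi^i(k)}|^2,$$

where $\pi$ ranges over permutations that preserve atom types and the bond
graph ($\pi(i) \sim \pi(j) \iff i \sim j$) and whose cycle lengths are 1 or
$n$, with 2 additionally allowed for $S_n$ and $C_2$. For a fixed admissible
$(\pi, T)$ the inner minimum has the closed form orbit average
$P_k = \frac{1}{g}\sum_{i=0}^{g-1} T^{-i} Q_{\pi^i(k)}$, which is exactly
$T$-invariant and reproduces the objective value; both facts are asserted by
the test suite to $10^{-9}$.

The chirality measure is $\mathrm{CCM} = \min_G S(G)$ over achiral groups,
default $\{C_s, C_i\}$ (extensible to $S_4, S_6, \dots$); in most chiral
topologies the reflection term attains the minimum.

### The single-operation surrogate

The approximate engines minimize a single-operation objective
$\widehat{M} = c \sum_k |T Q_k - Q_{\pi(k)}|^2$ instead of the full group
average, because only it reduces to a linear assignment problem. The
prefactor is a deliberate numerical choice: for order-2 groups ($C_2$, $C_s$,
$C_i$) we take $c = \tfrac14$, which makes $\widehat{M} = M$ *exactly*
whenever $\pi$ is an involution — this is the identity that lets the
Fibonacci+Hungarian minimum act as a true lower bound on the measure for
$C_s$/$C_i$ and keeps approximate and exact values on one scale. For
$n > 2$ we use the conventional $c = \tfrac12$ and report $\widehat{M}$ as an
approximation only. Since a constant prefactor never changes an argmin, the
search itself is unaffected by this convention.

### Reporting convention

Every result carries both numbers. The headline $S$ uses the full
group-averaged $M$ whenever the found permutation is cycle-valid (then the
nearest symmetric structure is exactly $T$-invariant), and falls back to
$\widehat{M}$ with `cycle_valid = FALSE` otherwise — greedy/Hungarian
assignments are not forced to respect cycle structure, and for such
permutations the orbit average is still emitted but without the invariance
guarantee.

## Engines

- **exact** — recursive enumeration of all structure-preserving permutations.
  The recursion always branches on an atom with the fewest remaining options
  (ties to the lowest index), tracks partial chains so the cycle rules prune
  early, and force-closes a chain the moment it reaches the maximal allowed
  length. The identity permutation is admitted (its cycles are all 1); the
  measure stays non-trivial because the operation itself is never the
  identity. Per permutation the optimal axis is solved for the *full*
  objective. A node cap (default $10^7$) aborts with guidance to the
  approximate engines. No automorphism-group factorization is attempted:
  pruning rests on class and bond constraints only, which is already enough
  to cut the $2.73\times10^{43}$ unconstrained involutions of a C60 cage to
  its 32 structure-preserving ones in seconds.
- **greedy / hungarian** — alternate: build the distance matrix
  $A_{ij} = |T Q_i - Q_j|^2$ at the current axis (entries across different
  equivalence classes masked to $\infty$, so assignments never swap
  distinguishable atoms), propose $\pi$ (greedy: repeatedly take the globally
  smallest entry, ties to lowest row then column; Hungarian: an exact
  assignment minimizer, solved block-per-class by a Jonker–Volgenant
  shortest-augmenting-path routine), then re-optimize the axis analytically.
  Convergence: permutation repeat, $\Delta\widehat{M} < 10^{-10}$, or 50
  iterations. With the Hungarian assigner both steps are exact minimizations,
  so $\widehat{M}$ is monotone automatically; greedy is not a minimizer, so a
  proposal that would raise $\widehat{M}$ terminates the iteration instead of
  being accepted — the logged trajectory is non-increasing either way.
- **fibonacci** — the iteration restarted from every vector of a Fibonacci
  sphere lattice (default 100 directions, a good accuracy/time compromise;
  500 gives only minor gains at several times the cost) plus the educated
  guesses; the minimum-$\widehat{M}$ run wins, ties to the lowest start index.
- **sp** — the same iteration, but the assignment step is a branch-and-bound
  over structure-preserving permutations: candidate values $\pi(i) = j$ are
  tried in ascending $A_{ij}$, and a partial permutation whose partial cost
  exceeds the best complete cost is abandoned. Bond preservation is 100% by
  construction; a wall-clock budget (default 300 s) bounds the search and the
  result carries a completeness flag.

`compute_csm(..., algorithm = "auto")` probes the exact enumeration under the
node cap and falls back to the Hungarian engine when it refuses — so a
60-atom cage under $C_2$ still goes exact, while a large single-class cloud
does not.

### Axis optimization

For fixed $\pi$, each power term of the objective is a linear-plus-quadratic
function of the unit axis: maximizing $w^\top v + v^\top B v$ on the sphere.
The stationarity condition is solved in the eigenbasis of $B$ (a secular
equation in the Lagrange multiplier on $(\lambda_{\max}(B), \infty)$, with the
standard hard-case fallback when $w$ has no component along the top
eigenvector), and the analytic candidates are polished by BFGS on the
normalized vector. Because the full objective is also of this form (each
power of the generator is a rotation, improper on odd powers), the exact
engine optimizes the *full* objective per permutation, not the surrogate.
Tests require the result to match a dense-grid + refinement oracle within
$10^{-8}$. The axis sign is canonicalized (first non-zero component positive)
only for order-2 generators, where the operation is even in the axis; for
$n > 2$ a sign flip would invert the rotation sense at fixed permutation.

### Educated initial directions

Starting axes are fitted to the equivalence-class centroids: best line and
best plane by SVD, each with its two perpendicular complements, deduplicated
up to sign. Outlying centroids are removed first — iteratively drop the
largest plane-fit residual while it exceeds twice the median residual, never
more than 20% of the centroids (the rule is our choice; some such guard is
needed because a single far-off centroid can tilt the fitted normal
arbitrarily). With fewer than two distinct centroids (e.g. a single-class
ring) the coordinate axes serve as fallback.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `tolerance` (bond inference) | 0.4 | Å | slack over covalent radii sum; the common heuristic. Changing it changes the graph, hence classes and admissible permutations |
| `n_dirs` | 100 | — | Fibonacci lattice size; denser lattices tighten the lower bound |
| `time_limit` | 300 | s | wall budget for the sp branch-and-bound |
| `cap` | 1e7 (1e6 in auto) | nodes | enumeration guard |
| `max_iter` / `tol` | 50 / 1e-10 | — / Å² | iteration convergence |

## Synthetic fixtures: what they do and do not show

The generators produce desk-scale analogues of the benchmark families: rings
and prisms (exact $C_n$ hosts, standing in for macrocycles), the C60
truncated icosahedron (a single-equivalence-class cage built from the
$(0, \pm1, \pm3\varphi)$ vertex orbit at 1.4 Å edge), a two-element bonded
pair (the minimal structure whose inversion measure is exactly 100), and a
four-distinct-element chiral tetrahedron. `distort()` adds seeded isotropic
Gaussian coordinate noise. All generators are pure functions of their
arguments.

Gaussian noise on an ideal skeleton emulates *conformational* distortion
well, and the cage fixtures exercise *topological* asymmetry, but the
fixtures have no torsional correlations, no guest-host folding, no force-field
relaxation, and at most 120 atoms. Passing tests therefore demonstrate
correctness of the measures and the engine contracts (bounds bracketing,
monotonicity, oracle equality), not accuracy claims for any particular
experimental system; on strongly distorted real structures the approximate
engines can converge to permutations that break many bonds, exactly the
regime where their values are 3D-shape descriptors rather than bond-faithful
symmetry measures.

Test problem sizes are chosen so the whole suite runs in well under an hour
on one core: brute-force oracle comparisons use 20 molecules of 4–6 atoms
(the full $N!$ space with dense axis grids), bound-bracketing uses 20
distorted 5–6 rings, and monotonicity is checked on 1000 random assignment
matrices of size 3–8 plus the structured fixtures.

## Degenerate inputs and tie-breaking

All-coincident atoms make $D = 0$ and the measure undefined (an error).
A single atom at the center is $T$-fixed under any operation. The inversion
group has no axis; the convention $(0,0,1)$ is reported. Exact ties between
permutations resolve to the first in deterministic enumeration order; greedy
ties to the lowest row, then column; multistart ties to the lowest start
index. Results are thus bit-reproducible for fixed inputs, independent of
any internal scheduling.

## Known limitations

- Only cyclic generators $C_n$/$S_n$ are measured — no composite $D_n$, $T$,
  $O$, $I$ groups, and no continuous shape measure.
- Connectivity for XYZ input must be inferred; the radii table covers the
  common ~70 elements and errs on exotic species.
- The exact engine's feasibility depends on the bond graph's rigidity, not
  just $N$: highly symmetric graphs with large classes can explode.
- For $n > 2$ the Fibonacci+Hungarian value bounds only the surrogate
  $\widehat{M}$-based quantity, and is labeled accordingly
  (`brackets_exact = FALSE`).
- Protein-chain machinery (sequence-restricted classes, chain-level
  assignment) is out of scope.
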