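---
title: "External and internal activity indices: conventions, model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{External and internal activity indices: conventions, model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molactivity)
```

This vignette records the scientific and numerical decisions behind the
package: the graph conventions the two activity indices depend on, how an
ambiguous definition was resolved, how the severely ill-conditioned
nine-coefficient interpolation is solved, what the bundled reference data
can and cannot reproduce, and what the synthetic-graph tests do and do not
demonstrate.

## The indices

For a connected graph $G$ on $n \ge 2$ vertices, with $S$ the degree-one
("external") vertices and $Q$ the rest ("internal"), every vertex gets a
score

$$s(v) = \begin{cases}\sum_{u \in S} d(u,v) & v \in S\\[2pt]
\dfrac{t(v)}{\deg v}\,\mathrm{ec}(v) & v \in Q\end{cases}$$

and the graph-level indices are $D(G) = \sum_{v\in S} s(v)/n^3$ (external
activity) and $\zeta(G) = \sum_{v\in Q} s(v)/n^2$ (internal activity).
The external sum counts every unordered pair of end vertices twice, so
it is always an even integer — a fact worth stating because it makes some
tabulated reference values provably irreproducible (below). Graphs with
at most one end vertex have $D = 0$ (cycles), and $P_2$, with no internal
vertex, has $\zeta = 0$; both are returned as zeros rather than errors,
and whether such graphs are sensible model inputs is left to the caller.

## Graph conventions

The index definitions say nothing about hydrogens or bond orders, so the
package fixes both conventions from the worked taxifolin example and two
screening-table rows, and applies them uniformly:

* **Hydrogen suppression is mandatory.** Taxifolin is C15H12O7; the
  worked example divides by $22^3$, and 22 is exactly its heavy-atom
  count. One vertex per non-hydrogen atom, explicit hydrogens removed.
* **Bond order and aromaticity are discarded.** Tropolone's two
  oxygens — one in a C=O double bond — are both degree-one vertices at
  graph distance 3, giving the tabulated $D = 6/9^3$; treating the double
  bond as two edges would break this. Every bond is one edge.
* **Charges, isotopes and stereochemistry are ignored**; the indices are
  functions of 2-D connectivity only.
* **Disconnected inputs are a hard error**, not reduced to their largest
  fragment: the invariants are defined for connected graphs, and a salt
  or mixture should be resolved by the user, not silently truncated.
* Vertices are relabelled to contiguous integers `1..n` (the natural
  indexing for R matrices); all results are invariant to relabelling,
  which the test suite checks with random permutations.

## The irregularity index ambiguity

"The number of neighbours of $v$ with distinct degrees" admits two
readings: (A) the number of *distinct degree values* among the
neighbours, or (B) the number of neighbours whose degree *differs from*
$\deg v$. The two disagree already on a star centre (A gives 1, B gives
$k$). The package implements both; the worked example decides the
default. On taxifolin, reading A gives an internal sum of 85.8333 —
exactly the published value — while B gives 79.5. Reading A also
reproduces tropolone's $\zeta = 0.222222222$. The default is therefore
`"distinct-values"`, with `"differing-degree"` available as an explicit
option on every function that computes scores.

## The IC50 model and its numerics

The model is a nine-term bivariate cubic in $(D, \zeta)$ with the fixed
feature order $[1, D, \zeta, D^2, D\zeta, \zeta^2, D^2\zeta, D\zeta^2,
\zeta^3]$; the $D^3$ monomial is not part of the family. With exactly
nine training compounds the fit is an interpolation: a square linear
solve.

That solve is numerically nasty on purpose-built data: $D \sim 10^{-2}$,
$\zeta \sim 2\times10^{-1}$, both on narrow ranges, so the design matrix
is Vandermonde-like with condition number around $10^{12}$. A plain
double-precision solve leaves only a few accurate digits in the
coefficients. The package therefore refines the QR solution iteratively
against residuals accumulated in double-double arithmetic (error-free
transformations; roughly 32 significant digits in the residual), which
restores the solution to working accuracy in a handful of iterations.
The refit coefficients then reproduce all nine published constants when
rounded to their printed 4 significant figures, the training residuals
sit at the $10^{-11}$ scale, and $R^2 = 1$ to far beyond 9 decimals.
With more than nine records the fit falls back to ordinary least
squares. Rank-deficient designs (e.g. duplicated descriptor pairs with
conflicting IC50) and under-determined inputs raise classed errors.

## Printed versus refit coefficients

Two coefficient sets coexist, and they are *not* interchangeable:

* `printed_model()` carries the published constants, rounded to 4
  significant figures.
* `fit_ic50(load_training_table())` recomputes the exact interpolation
  ("refit").

Because the model is ill-conditioned, the 4-figure rounding perturbs
predictions by orders of magnitude more than the fit residuals: at
quercetin's training point the printed set predicts 409 rather than the
observed 96. Working through the screening table shows that only the
**refit** set reproduces it: the 26 tabulated compounds sort into
exactly the tabulated rank order, and the chrysin:tropolone magnitude
ratio is 33.91, matching the published "34-fold" claim (the printed set
gives a different order and a 64-fold ratio). The refit set is therefore
the default wherever a coefficient source is implicit; the printed set
remains available for comparison.

The screening table's *numerical* predictions occupy an odd middle
ground: they are close to, but not equal to, the refit predictions
(quercetin: tabulated 93.34 vs interpolated 96). No coefficient set can
produce them — any interpolant of the training table predicts the
observed 96 at quercetin's training point exactly. They appear to stem
from a slightly perturbed coefficient vector used in the original
analysis, and the package records them as a known inconsistency rather
than attempting to match them. The test suite asserts precisely this:
kojic acid within 1 % under the printed set, exact interpolation under
the refit set, and the tabulated quercetin value reproducible under
neither.

## Bundled reference data and its known defects

The package ships three fixtures, transcribed digit-for-digit and
checksummed: the nine-compound training table, the 26-compound screening
table, and curated structures (SMILES) for all 26 named compounds, each
encoded from the compound's standard published structure.

Computing the indices from those structures reproduces the tabulated
$(D, \zeta)$ for 19 of the 26 compounds exactly. The remainder are
flagged per-compound in `load_structures()`:

* Four tabulated $D$ values (dihydroquercetin-4′-methylether,
  dihydroquercetin-7,4′-dimethylether, blumeatin, rosmarinic acid) imply
  *odd* external sums (205, 215, 143, 355). The external sum is twice a
  pair-distance sum, hence always even; no structure whatsoever can
  produce them. The computed values differ by exactly one in each case.
* Four tabulated $\zeta$ values (kojic acid, xanthoxylin, tamarixetin,
  luteolin-7-methyl ether) differ from the computed ones by small
  amounts (1, 0.5, 3.5 and 2.5 in the internal sum). Exhaustive
  enumeration of the plausible positional isomers of each scaffold finds
  no structure reproducing them either. A fifth,
  3,7,4′-trihydroxyflavone's 0.2352, implies an internal sum of 94.08,
  which no sum of sixths can equal (computed: 94.0).
* Quercetin-3-rutinoside's tabulated descriptors duplicate quercetin's;
  the true 43-heavy-atom rutinoside has different ones. The fixture
  carries the true structure and the flag.
* Taxifolin's tabulated $\zeta$ (0.177341529) divides the 4-decimal
  rounded internal sum 85.8333 by $n^2$, while quercetin's (0.177341598)
  uses the exact sum $515/6$ — the two molecules have identical
  hydrogen-suppressed graphs, so their computed indices are identical.
  The quercetin value is treated as canonical.

None of the flagged entries participates in the quantitative acceptance
checks; they are retained, flagged, because the screening reproduction
uses the tabulated descriptor pairs as published.

## Synthetic graphs and the brute-force oracle

`generate_graph()` produces deterministic seeded graphs from six
families (paths, cycles, stars, barbells, uniform random labelled trees
via Prüfer sequences, and random trees with extra edges). These are
abstract graphs chosen to exercise the index implementations — end-vertex
heavy trees, end-vertex-free cycles, high-degree hubs — not chemically
realistic molecules; they make no attempt to emulate valence limits,
ring-size distributions or atom typing. Passing the property tests
therefore demonstrates correctness of the graph algorithms on arbitrary
connected simple graphs, and says nothing further about chemistry; the
chemical conventions are pinned separately by the 26 curated structures.

`oracle_activity()` recomputes both indices for graphs with $n \le 30$
using Floyd–Warshall distances and naive loops, sharing no code with the
production path (igraph BFS distances, vectorised scoring). The suite
compares the two on 200 seeded random graphs, requiring bit-identical
external numerators and $|\Delta\zeta| < 10^{-12}$, alongside closed
forms derived by hand for stars ($D = 2k(k-1)/(k+1)^3$, $\zeta =
(1/k)/(k+1)^2$) and cycles ($D = 0$, $\zeta = \lfloor n/2\rfloor/2n$)
for all sizes up to 12.

## Reported precision

Descriptors are written to CSV at 9 decimal places and predictions at 7,
mirroring the reference tables so diffs are mechanical; full precision
is kept in memory. The worked example's published $\zeta = 0.1773415$
reflects its rounded numerator (85.8333/484); the full-precision value
is 0.17734160, one unit higher in the 7th decimal — the package reports
the full-precision value and the tests assert agreement at the printed
precision.

## Limitations

* The model is an exact interpolation of nine compounds, not a validated
  regression: no cross-validation, uncertainty or applicability-domain
  quantification is provided, because none exists for the source model.
  Predictions outside the narrow training descriptor box (D roughly
  0.013–0.018, ζ roughly 0.16–0.20) are extrapolations of a cubic and
  can be wildly negative; only relative order is interpretable there,
  and the package warns accordingly.
* Only the two indices implemented here are supported; no other
  topological descriptors, and no bounds or extremal-graph analysis.
* Structure handling is deliberately 2-D: no conformers, tautomers or
  protonation states.
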