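---
title: "Degree-based topological indices and QSPR regression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-based topological indices and QSPR regression: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topoqspr)
```

## The model

A drug molecule is reduced to its hydrogen-suppressed molecular graph
$G(V, E)$: vertices are heavy atoms, edges are covalent bonds, bond order is
ignored, hydrogens are dropped.  This convention is forced by the dataset the
package reproduces — a carbonyl oxygen has degree 1 and thalidomide has 19
vertices and 21 edges only under it.

Six vertex-degree descriptors are computed per graph, writing $d_s, d_t$ for
the endpoint degrees of an edge:

* $\mathrm{ABC\!-\!R}(G) = \sum_{st \in E} \frac{\sqrt{d_s + d_t - 2} - 1}{\sqrt{d_s d_t}}$ —
  the difference between the atom-bond-connectivity and Randić indices.  It
  can be negative on very small graphs (a two-vertex molecule gives $-1$).
* $\mathrm{GA}(G) = \sum_{st \in E} \frac{2\sqrt{d_s d_t}}{d_s + d_t}$ —
  each term is the ratio of geometric to arithmetic mean of the endpoint
  degrees, so lies in $(0, 1]$ with equality iff $d_s = d_t$; hence
  $0 < \mathrm{GA} \le |E|$, with equality on regular graphs.
* $\mathrm{SDD}(G) = \sum_{st \in E} \frac{d_s^2 + d_t^2}{d_s d_t}$ —
  by AM–GM every term is $\ge 2$, so $\mathrm{SDD} \ge 2|E|$.
* $E\Pi_1(G) = \prod_{v \in V} e^{d_v^2} = \exp\!\big(\sum_v d_v^2\big)$ and
  $E\Pi_2(G) = \exp\!\big(\sum_{st \in E} d_s d_t\big)$ — the multiplicative
  exponential Zagreb indices.  ($E\Pi_2$ is sometimes written as a product
  "over vertices", but its term involves both endpoint degrees; the
  edge-product reading is the one consistent with the reproduced dataset's
  own computations.)
* $\mathrm{GA\Pi}(G)$ — the multiplicative geometric-arithmetic index; see
  "The two readings of GAΠ" below.

All of them are functions of the **edge partition** — the multiset of
unordered degree pairs $(d_s, d_t)$ with frequencies — which is the
computational intermediate this package exposes (`edge_partition()`).
Even $\sum_v d_v^2$ is available from it, since
$\sum_v d_v^2 = \sum_{st \in E} (d_s + d_t)$.
Class-wise evaluation over the partition is algebraically identical to the
per-edge sum; the test suite verifies this equivalence against a brute-force
per-edge oracle on hundreds of random graphs at $10^{-12}$ relative
tolerance.

The QSPR stage regresses each of six physicochemical properties (melting
point, boiling point, water solubility, density, vapour pressure, molecular
weight) on each index under three families,

$$P = A + b\,TI, \qquad P = A + b\,TI + c\,TI^2, \qquad P = A + b \ln TI,$$

by ordinary least squares, reporting $N$, $A$, $b$, $c$, $r$, $r^2$, $F$ and
the $F$-test p-value per model — $6 \times 6 \times 3 = 108$ fits
(`qspr_table()`), or single fits through the `qspr(MW ~ SDD, data, family)`
interface.

## Log-domain arithmetic for the exponential indices

On drug-sized graphs $E\Pi_1$ and $E\Pi_2$ reach $10^{114}$; naive products
of $e^{d^2}$ factors are unusable.  The package therefore treats the exact
integer $\ln$ value ($\sum d_v^2$ or $\sum d_s d_t$) as the primary
representation.  The linear value is materialised only while representable
in double precision (ln below about 709), and a base-10
mantissa/exponent rendering is derived from the log value:
$\log_{10} = \ln / \ln 10$, exponent $= \lfloor \log_{10} \rfloor$, mantissa
$= 10^{\log_{10} - \lfloor \log_{10} \rfloor}$.

The renderer *truncates* the mantissa at six significant digits instead of
rounding.  This matches the tabulation convention of the reproduced dataset:
$e^{127}$ has mantissa $1.4302079\ldots$, printed there as
$1.43020 \times 10^{55}$ (truncated), while rounding would give $1.43021$.
Truncation reproduces both worked-example renderings and never differs from
rounding by more than one unit in the last place.

## The two readings of GAΠ

The displayed formula for the multiplicative geometric-arithmetic index is a
per-edge product $\prod_{st \in E} 2\sqrt{d_s d_t}/(d_s + d_t)$, which is
necessarily $\le 1$.  The dataset's own computations instead multiply, over
the *distinct classes* of the edge partition, the class contribution
$f_{(d_s,d_t)} \cdot 2\sqrt{d_s d_t}/(d_s+d_t)$ — for thalidomide
$3.4641 \times 4 \times 5.8788 \times 7 = 570.213$.  Both are implemented
(`ga_pi(method = "classwise")`, the default, and `method = "edgewise"`); the
class-wise form is the default because it is the quantity the study's tables
and regressions actually use.  The two definitions disagree by construction;
this is a property of the source material, not a bug, and the edge-wise
variant is kept available and bounds-tested ($\in (0,1]$).

A second tabulation detail: the class contributions are rounded to four
decimal places before the product is taken (`contribution_digits = 4`).
That is how $570.213$ arises; the full-precision product is $570.2111$.
`contribution_digits = NULL` gives the full-precision product.  The
convention matters only in the fourth decimal of GAΠ and nowhere else.

## The packaged dataset and its errata layer

The 15 drug graphs were transcribed from the drugs' standard 2D structures
and validated against the descriptor columns that withstand independent
verification.  The published descriptor table is shipped verbatim
(`published_index_table()`), because reproduction requires the exact inputs
the original regressions consumed — including its defects.  Every cell is
classified against the structure-derived value (`discrepancy_report()`):
*match* within $5 \times 10^{-4}$ relative, *rounding* within
$2 \times 10^{-3}$, *erratum* beyond.

A printed exponential-index cell pins down an exact integer: a mantissa of
$4.6754$ forces $\sum d_v^2 = 142$ because $\ln(4.6754 \times 10^{61}) = 142.00$
to five digits.  Together with ABC-R, GA, SDD and GAΠ this over-determines
the edge partition, which lets each fixture be checked (and, where the
drawing used by the study differs from the canonical structure, uniquely
reconstructed).  Three fixtures follow the study's drawings rather than the
canonical structures, each carrying a `depiction_note`:

* **Minocycline** — canonical structure plus hydroxyls on the C4a and C5a
  ring-fusion carbons; this is the unique single interpretation reproducing
  ABC-R, SDD, GA and both exponential integers exactly.
* **Simvastatin** — canonical structure plus one hydroxyl on the C8a
  ring-fusion carbon (again the unique small edit matching all five
  verifiable cells).
* **Wortmannin** — the edge list realises the unique degree partition
  consistent with all six printed values; it differs from the canonical
  natural-product skeleton in the arrangement of the two quaternary
  ring-fusion carbons.

**Noscapine** is the one row no graph can satisfy: an exhaustive search over
all degree-$\le 4$ partitions shows ABC-R, SDD and GA as printed are mutually
inconsistent.  The fixture is the canonical structure and the whole row is
flagged as errata.

Corrections (`Corrected` column) are supplied *only* where the study's own
material identifies the intended value: the thalidomide worked example
(GA $= 20.3429$, $E\Pi_1 = 1.46766\times10^{45}$,
$E\Pi_2 = 1.43020\times10^{55}$) and exponential cells whose printed mantissa
matches the structure-derived one while the power of ten was dropped or
mistyped (aspirin, valproic acid, celecoxib).  Cells that are wrong but were
evidently fed into the original regressions as printed (e.g. the zoledronic
acid GA value, low by exactly 1) stay verbatim even under
`source = "published_with_corrections"`, so that reproduction sees the same
inputs the study used.  With that source, the molecular-weight model on GA
returns $A = 57.02$, $b = 11.468$, $r = 0.978$ — against the study's printed
$56.994 / 11.469 / 0.978$ — and the log-scale $E\Pi_1$ model returns
$b = 2.176$, $r = 0.977$ against printed $2.177 / 0.977$, confirming the
correction policy recovers the original regression inputs.

## Regression details

* Degrees of freedom: $(1, n-2)$ for linear and logarithmic, $(2, n-3)$ for
  quadratic; $F = \frac{r^2/k}{(1-r^2)/(n-k-1)}$ holds to $10^{-6}$ for every
  fitted row, and every single-predictor fit passes through the mean point
  $(\bar{x}, \bar{y})$ to $10^{-9}$ — these identities are asserted in the
  test suite.
* $r$ carries the sign of $b$ for the single-predictor families and is the
  (non-negative) multiple correlation for the quadratic family.
* For the logarithmic family on $E\Pi_1/E\Pi_2$ with structure-derived
  inputs, the exact integer $\ln$ values are used directly rather than
  `log(exp(ln))`, avoiding any round trip through the linear scale.
* **Degenerate-fit screen.**  Before fitting, raw design entries must be
  finite and non-constant, and the standardized (centered/scaled) design
  must have condition number $\le 10^8$ — about half of double precision's
  significant digits, the conventional point beyond which least-squares
  estimates lose all trustworthy figures.  The screen matters in exactly one
  place: quadratic fits on raw exponential-index values, where the columns
  $TI$ and $TI^2$ (magnitudes $10^{114}$ and $10^{228}$) are numerically
  collinear (scaled condition $= \infty$, since one molecule dominates every
  moment).  Those 12 of the 108 models are reported as degenerate rows
  carrying the diagnostic, never as silent zero coefficients.  The
  stand-alone `condition_check()` reports the condition of whatever design
  it is given, so a raw $[1, x, x^2]$ design at $x \sim 10^{50}$ fails while
  its centered/scaled variant passes.
* The default input source for reproduction runs is `"published"`: the
  tabulated descriptor columns are what the original regressions consumed,
  and the two strongest anchors (molecular weight on ABC-R and on SDD)
  reproduce from them to three decimals in $b$, $r$, $r^2$ and within one
  unit in $F$.
* No multiple-testing correction is applied across the 108 models, mirroring
  the reproduced analysis; with 36 models per family and no adjustment,
  nominal p-values must not be read as family-wise error rates.

### A reproduction limit worth recording

With the published descriptor columns and property table, OLS for molecular
weight on ABC-R gives $A = 50.645$, $b = 38.809$ ($r = 0.975$,
$F = 249.27$).  The printed row is $A = 50.608$, $b = 38.815$,
$F = 249.667$.  The printed $(A, b)$ pair *is* mean-point consistent
($\bar{y} - 38.815\,\bar{x} = 50.602$), so the original slope was computed
from slightly different inputs than the printed columns; no single-cell
perturbation of the printed table explains it.  $b$, $r$ and $F$ agree with
our fit within $0.006$, $0.0001$ and $0.4$ respectively, but the intercept
disagrees by $0.037$ — slope error amplified by $\bar{x} \approx 7.2$.  The
package reports its own OLS solution; the discrepancy is documented here and
asserted (and visible) in the test suite rather than patched.

Similarly, the boiling-point rows of the published model tables fail a
mean-point audit against the tabulated inputs at about 2%, so they are
reported but not used as anchors; and the all-zero/$r = 1.000$ quadratic
block for $E\Pi_2$ is replaced by the degenerate-fit diagnostic rather than
imitated.

## The synthetic-data generator

`random_molecular_graph()` draws a random spanning tree (each new vertex
attaches to a uniformly chosen existing vertex with spare valence — this
guarantees connectivity by construction), then adds ring-forming extra edges
subject to the degree cap.  Defaults emulate the study's molecules:
degree cap 4 (the heavy-atom valence proxy), 5–40 vertices (the fixture
range is 9–39).  `simulate_property_table()` computes a chosen index on each
graph and draws the property as the family curve plus Gaussian noise.  Its
defaults are the study's strongest model re-cast as a generator:
$n = 15$ molecules, linear family with $A = 50.608$, $b = 38.815$ on ABC-R,
and `noise_sd = 30` — the residual standard deviation implied by that
model's $r^2 \approx 0.95$ over the observed molecular-weight spread.  All
randomness flows from a single required seed; generation is a pure function
of it.

What the generator does **not** emulate: element identities and per-element
valence rules, realistic ring statistics, aromaticity, or correlated
measurement error across properties.  Passing parameter-recovery tests
therefore demonstrates the statistical machinery (unbiased slope recovery,
exact noiseless recovery, correct standard errors) on graphs with the right
degree structure — not that real physicochemical data follow these curves.

Validation problem sizes, chosen to make the checks sharp while keeping the
default test run quick: 200 random graphs (5–40 vertices) for the
class-wise/brute-force equivalence and integer-log identities; 100 graphs
for relabelling invariance; 1000 seeded replicates at $n = 15$,
$\sigma = 30$ for slope-recovery bias (the observed $|$bias$|$ must stay
below twice the Monte-Carlo standard error; at $\sigma = 0$ recovery is
exact to $10^{-9}$).

## Numerical choices, edge cases, limitations

* Vertex order is first-appearance order from the edge list; all outputs are
  invariant under relabelling (property-tested), so this only fixes
  serialization.
* Disconnected input is refused by default with the offending component
  named; `allow_disconnected = TRUE` exists for deliberately fragmentary
  input.  Self-loops and duplicate edges are always errors — a double bond
  is one edge.
* The logarithmic family refuses non-positive index values (ABC-R is $-1$
  on a two-vertex molecule), as does the logarithmic generating family in
  the simulator.
* `qspr_fit()` requires $n \ge k + 2$ so that the $F$ statistic has at least
  one denominator degree of freedom.
* Reported tables round to the study's precision (three decimals; p-values
  below $5 \times 10^{-4}$ print as `0.000`); internal values keep full
  precision.
* Limitations: single-predictor families only (no multi-index models, no
  robust or weighted variants, no cross-validation); no aromaticity or
  stereochemistry — the graph is the whole molecular representation; the
  drug set is small ($n = 15$) and the regressions inherit every caveat of
  fitting 108 models to 15 points.
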