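---
title: "Exact topological indices of Fuchsine sheets: model, arithmetic, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact topological indices of Fuchsine sheets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuchsine)
```

## The model

A molecular graph represents atoms as vertices and bonds as edges. A
degree-based topological index is a sum over edges of a symmetric function
of the endpoint degrees,

$$ I(G) = \sum_{uv \in E(G)} f(d_u, d_v), $$

and serves as a structure descriptor in quantitative structure–property
work. This package studies one two-parameter family: the supramolecular
Fuchsine sheet $F[m,n]$, built from an $m \times n$ grid of identical
40-vertex units, each pair of grid neighbours joined by identifying one
pendant (degree-1) vertex of each unit into a single shared linker vertex of
degree 2.

Two facts drive the whole design.

1. **The fusion is a vertex identification, not a bridge edge.** The
   family's counts are $38mn + m + n$ vertices and $42mn$ edges. A single
   unit has 40 vertices and 42 edges; a grid has $2mn - m - n$ junctions.
   Edges stay at $42mn$ and vertices drop by exactly one per junction —
   which is what identification gives ($40mn - (2mn - m - n) = 38mn + m + n$)
   and edge insertion would not.
2. **Degree-based indices see only the edge partition.** $F[m,n]$ has three
   edge types, tallied by canonical degree pair:
   (3,3): $24mn$; (1,3): $14mn + 2(m+n)$; (2,3): $4mn - 2m - 2n$. Any two
   graphs with this partition have identical values for *every* degree-based
   index.

## The unit template

The true atom-level adjacency of the Fuchsine unit is not recoverable from
degree data alone, and it does not need to be: by fact 2, any 40-vertex unit
whose partition is $\{(3,3){:}\,24,\ (1,3){:}\,18\}$ generates the right
family. The canonical template is the minimal construction that provably
realises it: a 22-cycle `c0..c21` (22 core–core edges), two chords
`c0–c11` and `c5–c16` (completing $24$ core–core edges and raising those four
vertices to degree 3), and one pendant on each of the other 18 core
vertices (raising them to degree 3 and giving the 18 (1,3) edges). Four
pendants are designated W/E/N/S ports; their choice among the pendants is
arbitrary and fixed only for reproducibility.

Both arbitrary choices are tested, not assumed: the suite rebuilds sheets
from an alternative template (different chords) and checks that the edge
partition — hence every index value — is unchanged for several $(m,n)$.
What passing these tests does *not* show is anything about the chemistry of
real Fuchsine beyond its degree sequence: distance-based descriptors, for
instance, would differ between templates.

`build_sheet()` addresses units 1-based as (column $i$, row $j$), fuses E–W
within rows and S–N across rows, and relabels vertices deterministically,
so identical calls yield byte-identical exports.

## Exact arithmetic in $\mathbb{Q}[\sqrt2, \sqrt3, \sqrt6]$

On the three sheet degree pairs the per-edge values of all supported
indices lie in the ring $a + b\sqrt2 + c\sqrt3 + d\sqrt6$ with rational
coefficients (e.g. ABC at (1,3) is $\sqrt{2/3} = \sqrt6/3$; GA at (2,3) is
$2\sqrt6/5$). The `surd` class implements this ring with reduced-fraction
coefficients, so index values, closed-form coefficients, and the equalities
between computation routes are exact. Numerators and denominators stay far
below $2^{53}$ for every computation in scope, so double-precision integer
arithmetic is exact throughout.

For arbitrary graphs or exponents the radical can leave the ring
($\sqrt5$, say); the exact path then falls back to floating point with a
warning, and float comparisons use a relative tolerance of $10^{-9}$ —
generous for sums of a few thousand well-conditioned terms. Degenerate
cases are defined, not errors: ABC at a (1,1) pair is 0 (zero numerator),
the empty partition sums to 0, and the empty graph is valid input for the
plumbing operations while sheet constructors reject $m < 1$ or $n < 1$.

## Three routes, two oracles

Every index value can be computed three ways, and the suite requires exact
agreement among them:

* **Direct edge summation** (`compute_index`) — definitional; the truth.
* **Partition evaluation** (`compute_from_partition`) — three terms; must
  equal the direct route exactly, and is additionally checked against it on
  50 random simple connected graphs (fixed seed) where the partition is
  computed from scratch.
* **Closed form** (`derive_closed_form`) — symbolic: partition polynomials
  times exact per-edge values, summed in the surd ring. Checked exactly
  against direct summation at every $m, n \in 1..6$.

A fourth, purely numeric route (`fit_bilinear`) solves for the four
bilinear coefficients from direct computations at $(1,1), (1,2), (2,1),
(2,2)$ and predicts held-out sheets; it never touches the symbolic
partition, so coefficient-wise agreement with the derivation (within
$10^{-9}$) is an independent confirmation rather than a tautology.

## Auditing published values

Published closed forms and a published ten-column comparison table exist
for this family. They are stored verbatim as fixtures — including
known-defective entries — and *audited*, never silently corrected:

* The hyper-Zagreb statement reads $118mn - 18m - 18n$ while its own proof
  line and the derivation give $1188mn - 18m - 18n$: MISMATCH against the
  statement, MATCH against the proof.
* The ABC statement's term "$14\frac{\sqrt2}{3}$" is ambiguous. Read
  literally as $(14/3)\sqrt2$ the statement is wrong; read as
  $14\sqrt{2/3} = (14/3)\sqrt6$ it is exactly right. Both readings are
  recorded and compared; no correction is applied.
* The $\lambda = -\tfrac12$ Randić statement's $(m{+}n)$ coefficient is
  printed $(2 - \sqrt2)$; the derivation gives $(2 - \sqrt2)/\sqrt3$.
* Table cells are compared after integer rounding (nearest, halves away
  from zero — the convention consistent with every reproducible cell; no
  half-integer case arises on the audited rows). The audit flags each
  inconsistent cell with the computed value, and records the
  discussion-level claim that the $\lambda=-\tfrac12$ Randić index is the
  largest tabulated index (computation puts hyper-Zagreb first at every
  size, and the package asserts only the computed ordering). Several
  mid-table cells — most of the ABC column, scattered GA and
  $R_{\pm 1/2}$ cells — are irreconcilable with *any* closed-form variant;
  they are flagged and left unexplained rather than rationalised.

```{r audit}
compare_published()
```

## Parameters, sizes, and limitations

The tunable surface is small: the sheet dimensions $m, n \ge 1$
(dimensionless unit counts), the Randić exponent $\lambda$ (dimensionless;
$\lambda = -\tfrac12$ is the classical branching index), and the optional
unit-template file. Exhaustive sweeps use $m, n \in 1..6$ (1296 sheet/index
exact-equality checks; the largest sheet there has 1512 edges) and the
audited table runs to $F[10,10]$ (4200 edges) — desk-scale sizes chosen
because the bilinear closed forms make larger graphs informationally
redundant: four sample points already determine every coefficient.

Known limitations: only the degree structure of Fuchsine is modelled, so
nothing here bears on 3D geometry, bond types, or distance-based and
resistance-distance indices; the surd ring covers exactly the radicals this
family produces, so exact closed forms for other families would need a
wider coefficient field; and the audit can establish that a published cell
disagrees with every formula variant, but not how it was produced.
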