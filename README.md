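# fuchsine

Exact degree-based topological indices of supramolecular Fuchsine sheet
graphs.

Fuchsine is a magenta triarylmethane dye whose molecules self-assemble into
supramolecular sheets. Modelling each molecule as a graph (atoms as
vertices, bonds as edges) and joining an m × n grid of unit copies on shared
linker atoms gives a two-parameter graph family **F[m, n]** with
38mn + m + n vertices and 42mn edges. Degree-based topological indices of
such molecular graphs — numbers of the form

    I(G) = Σ_{uv ∈ E(G)} f(d_u, d_v)

for a symmetric function f of the endpoint degrees — are standard structure
descriptors in QSPR/QSAR work. This package is for anyone who wants those
indices for the Fuchsine sheet family *exactly*: it generates the graphs,
computes the indices three independent ways, and audits published values
for the family against direct computation.

Supported indices: first and second Zagreb (M1 = Σ(d_u+d_v),
M2 = Σ d_u d_v), hyper-Zagreb (HM = Σ(d_u+d_v)²), forgotten
(F = Σ(d_u²+d_v²)), harmonic (H = Σ 2/(d_u+d_v)), atom-bond connectivity
(ABC = Σ √((d_u+d_v−2)/(d_u d_v))), geometric–arithmetic
(GA = Σ 2√(d_u d_v)/(d_u+d_v)), and the general Randić index
R_λ = Σ(d_u d_v)^λ.

The key computational devices are:

* **Edge partition.** F[m, n] has only three kinds of edges, counted by the
  degree pair of their endpoints: 24mn edges (3,3), 14mn + 2(m+n) edges
  (1,3), and 4mn − 2m − 2n edges (2,3). The partition is a sufficient
  statistic for every degree-based index.
* **Exact surd arithmetic.** Every per-edge value on those three pairs lies
  in the ring ℚ + ℚ√2 + ℚ√3 + ℚ√6, so index values and closed forms are
  computed exactly, and "the closed form equals the direct sum" is a
  decidable equality rather than a tolerance check.
* **Bilinear closed forms.** Each index equals
  c_mn·mn + c_m·m + c_n·n + c_1 with surd coefficients; the package derives
  the coefficients symbolically from the partition, re-derives them by a
  numeric least-squares fit to generated sheets, and checks both against
  direct edge summation.

## Worked example

```r
library(fuchsine)

s <- build_sheet(2, 2)
summary(s)
#> Fuchsine sheet F[2, 2]
#>   vertices: 156   edges: 168   connector (degree-2) vertices: 4
#> Edge partition (168 edges):
#>   (1, 3): 64
#>   (2, 3): 8
#>   (3, 3): 96

compute_index(s, index_spec("HM"))
#> [1] 4680

compute_index(s, index_spec("ABC"), exact = TRUE)
#> <surd> 64 + 4*sqrt(2) + 64/3*sqrt(6)  (= 121.912635429)

derive_closed_form(index_spec("GA"))
#> <bilinear> (24 + 7*sqrt(3) + 8/5*sqrt(6))*mn + (1*sqrt(3) - 4/5*sqrt(6))*m + (1*sqrt(3) - 4/5*sqrt(6))*n
```

The 2 × 2 sheet fuses four 40-vertex units at 4 shared linker vertices
(hence 156 = 4·40 − 4 vertices, each linker of degree 2), its hyper-Zagreb
index is exactly 4680, and its ABC index is the exact surd shown, ≈ 121.91.
The GA closed form evaluates to the index of any F[m, n] exactly.

`compare_published()` classifies each published closed form for this family
as MATCH or MISMATCH against the derivation, and `audit_errata()` does the
same cell-by-cell for the published comparison table — both report the
defective hyper-Zagreb header, the ABC radical misprint, the λ = −1/2
Randić coefficient, and every irreconcilable table cell, with the computed
correction alongside.

A command-line interface over the same functions ships in
`inst/cli/fuchsine-cli.R`:

```sh
Rscript inst/cli/fuchsine-cli.R indices --m 1 --n 1 --index M1   # 216
Rscript inst/cli/fuchsine-cli.R generate --m 2 --n 2 --format graphml --out sheet.graphml
Rscript inst/cli/fuchsine-cli.R closed-form --compare-published
Rscript inst/cli/fuchsine-cli.R table --rows 1:10
```

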